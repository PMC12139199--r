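Package: riceshift
Title: Gene Duplication, Molecular Evolution and Heterosis Expression
    Analysis for Rice Phylogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for phylogenomic analysis of gene duplication and
    heterosis in rice. Detects gene-duplication events by rooting gene
    trees against a rooted species tree and mapping nodes by
    last-common-ancestor reconciliation under bootstrap-support and
    shared-species thresholds; classifies duplication events at a focal
    ancestral node into ABAB/ABAX/ABXB topology types to test hybrid
    versus independent subspecies origins; computes Nei-Gojobori (1986)
    Ka/Ks with Jukes-Cantor correction and Ks density summaries;
    detects tandem duplications by gene-order proximity and tests
    transposable-element association; classifies trio (F1/parent)
    variant sites into inherited/shared/de-novo categories after
    hard filtering and depth-band filtering; and classifies
    F1-versus-parent expression into seven inheritance modes (additive,
    dominance, partial dominance, overdominance). Every stage has a
    matched synthetic-data generator that plants known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
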