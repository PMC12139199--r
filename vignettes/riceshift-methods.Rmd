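---
title: "riceshift: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riceshift: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riceshift)
```

This vignette is the package's own account of what it computes, which
knobs matter, what the synthetic-data generators do and do not emulate,
and where the design was genuinely open.

## Gene-duplication detection by reconciliation

The substrate is a rooted species tree with bare taxon labels and a set
of gene-family trees whose leaves encode `taxon|gene` (the delimiter is
configurable; no published convention exists for these labels, so the
schema is ours). Internal node labels are read as bootstrap supports on
a 0–100 scale; labels in [0, 1] are rescaled by 100 with a warning, and
absent labels stay *missing* — they are never coerced to 0, and missing
supports pass every threshold, on the view that absence of a bootstrap
is absence of evidence against a clade.

Internally a support belongs to an *edge* (a bipartition), not a node.
This matters because gene trees are re-rooted: the package stores, for
every node, the support of the edge above it, which is invariant under
re-rooting, where naive node-label bookkeeping is not.

**LCA mapping.** Each gene-tree node maps to the lowest species-tree
node whose leaf set contains every taxon below it. A node is a
duplication under the classical criterion (its mapping equals a
child's mapping) for the purpose of counting, and losses on an edge
from node *v* to child *c* are `depth(M(c)) − depth(M(v)) − 1`, plus
one when *v* is a duplication.

**Rooting.** Published reconciliation tools root gene trees with an
undocumented "MAX_MIX" criterion. We use a stated stand-in: evaluate
every branch of the unrooted tree and keep the rooting minimizing
duplications + losses, with a fully deterministic tie-break (fewer
duplications, then the rooting whose outgroup-side clade maps deepest
in the species tree, then the lexicographically smallest outgroup leaf
label). On real trees this may differ from the original tool; on
synthetic congruent or cleanly duplicated trees both recover the
species rooting.

**Event calling.** A node is reported as a duplication event when its
two child clades share at least `minShared = 2` taxa (taxa are genomes,
not subspecies groups) and the node and both child supports pass
`bp = 70` / `subBp = 70`. These defaults are the thresholds the study
pipeline used. Raising any threshold can only shrink the event list, a
property the tests assert. For the rare non-binary node the child pair
with maximal species overlap is evaluated.

## ABAB / ABAX / ABXB typing

At a focal ancestor whose two child lineages have taxon sets A and B,
each event's two copy clades are intersected with A∪B (extraneous
lineages — taxa outside A∪B that ended up inside a duplicate clade —
are ignored; the source analyses are silent on them, and intersection
is the least-committal choice). Both copies containing A- and B-taxa is
ABAB; one full copy plus an A-only copy is ABAX; plus a B-only copy is
ABXB; anything else (a copy with no A/B taxa at all) is OTHER. "ABA"
and "ABB" in some summaries are the same classes as ABAX/ABXB. Every
detected event is typed; whether the original tool re-checked child
supports before typing is unknown, and we do not.

## Nei–Gojobori Ka/Ks

Site counts: for each codon position, the fraction of the three
single-nucleotide changes that preserve the amino acid is the
synonymous site weight (changes to stop codons count as
nonsynonymous), so s + n = 3 per codon. S and N for a pair are the
mean of the two sequences' sums over retained codons; codon columns
with gaps, ambiguity codes or stop codons in either sequence are
dropped entirely.

Differences: a codon pair differing at k positions is decomposed into
all k! orderings of single steps, each step classified
synonymous/nonsynonymous, and the (Sd, Nd) contribution is the
unweighted mean over orderings — the original method's equal
weighting. Orderings passing through a stop codon are excluded, the
common implementation choice; if every ordering does, all are used.
Published calculators do not document their exact gap/stop handling,
so small numeric differences against them are expected; our
implementation is instead checked against an independent
pathway-enumeration oracle to 1e-9.

Correction: `jcCorrect()` applies d = −(3/4)·ln(1 − 4p/3) and returns
`NA` for p ≥ 3/4 (saturation is reported, never an abort; on very short
alignments p can exceed 1 and is treated the same way). Ka/Ks is `NA`
when Ks is 0 or undefined. Only the standard genetic code ships
(nuclear CDS), but the code table is injectable for testing.

`ksDistribution()` summarizes a cohort: Gaussian kernel density over
the finite Ks values on a 512-point grid from 0 to the maximum, global
mode plus all local maxima, with saturated values excluded and
counted. A zero-variance sample short-circuits to its constant.
`selectClockGenes()` applies the inclusive 900–1200 bp length window
(and optionally a taxa-coverage floor) used to pick clock genes.

## Tandem duplication and TE context

Gene order is a dense per-chromosome ordinal over *all* annotated genes
(the gene universe for "intervening genes" is unspecified in the source
analyses; all annotated genes is the conservative reading). A pair is
tandem when both genes share a chromosome and `|Δordinal| − 1 ≤ 10`.
TE association uses the gene *body* ± 2000 bp (1-based inclusive;
whether the original rule used gene body or CDS is unstated), overlap
meaning ≥ 1 shared base. The 2×2 association test is the plain Pearson
chi-square (no Yates correction unless requested — the source names
only "chi-square test"). The asymptotic p-value is cross-checked in
tests against a Monte-Carlo conditional (permutation) p-value at
counts where the asymptotic law is accurate; at very small counts the
exact conditional distribution genuinely departs from the asymptotic
one, which is a property of the test, not of the implementation.

## Trio variant classification

Hard filtering fails a site when **any** of QD < 10, FS > 60, MQ < 40,
SOR > 3, MQRankSum < −12.5, ReadPosRankSum < −8 holds on a *present*
field; absent INFO fields never fail (the GATK VariantFiltration
convention), and every violated predicate is reported. The depth band
fails a sample below mean/3 or above 3·mean with strict inequalities —
boundary depths pass — and a site fails when any trio member fails; the
same band is applied to all three members (whether the original de novo
calling depth-checked the parents too is unstated). The two filters
commute, which the tests assert.

Classification is **full-genotype multiset matching** as the source
describes it: F1 equal to both parents is shared, to exactly one is
inherited from that parent, to neither is de novo, and any missing
genotype is unclassified. This is deliberately *not*
Mendelian-transmission consistency — a het F1 from hom-ref × hom-alt
parents is de novo under this rule although it is perfectly Mendelian —
so every classified site also carries a `mendelian_consistent` flag.
Genotypes are normalized to unordered multisets (1/0 ≡ 0/1 ≡ 0|1) and
multiallelic records are decomposed per alternate allele, with
genotypes carrying a different alternate set missing for that
decomposed row.

## Heterosis expression modes

For each gene the high parent (HP) and low parent (LP) are fixed by the
parental means, and the mid-parent (MP) is a pseudo-sample of
per-replicate-index parental averages (equal replicate numbers; a
seed-controlled bootstrap equalizes unequal ones). The source analyses
do not state their significance machinery; ours is a Welch two-sided
t-test on log2(TPM+1) at α = 0.05 (configurable), direction from the
mean difference, with a deterministic fallback for constant groups.
Genes with mean TPM below 1 in all three groups are excluded before
testing (noise floor; the sources are silent).

The decision table runs with overdominance first — POD (above HP), NOD
(below LP), then PD (above MP, ns vs HP), ND (below MP, ns vs LP), PPD
(above MP, below HP), NPD (below MP, above LP), A (ns vs MP, between
the parents), else NC — because a POD gene also satisfies the PD
premise and the published rule list leads with overdominance. All 27
call combinations map to exactly one mode; combinations inconsistent
with LP ≤ MP ≤ HP still resolve deterministically by the same
precedence. Swapping the parent labels cannot change a mode (HP/LP/MP
are label-free), asserted as a property test. The DE-retention
prefilter keeps genes significant against *either* parent
(Benjamini–Hochberg within each comparison, fold-change floor), the
retention rule used upstream of clustering.

## Synthetic-data generators

The generators define the test conditions; their defaults are fixed
once and the tests are written against them.

* Class counts always use deterministic **largest-remainder
  allocation**, never multinomial draws, so planted compositions are
  exact (a 10,000-site trio at 0.4/0.3/0.2/0.1 has exactly
  4000/3000/2000/1000 sites).
* `simulateGeneTrees()` copies the species-tree subtree at the planted
  node (full/A-only/B-only second copy for ABAB/ABAX/ABXB), supports
  100 everywhere, then drops tips independently with `lossProb`,
  always retaining at least two tips. The truth table records the
  surviving taxa of each copy, whether the event is still detectable
  (≥ 2 shared taxa) and where the survivors place it. Under loss the
  *emitted rooted trees* are the ground truth for replay comparisons:
  minimum-(dup+loss) re-rooting can legitimately place an event lower
  than planted when one copy loses an entire lineage (the shallower
  duplication costs fewer losses), so the loss-replay test runs
  detection on the generator's rooting, while re-rooting itself is
  validated loss-free and against an exhaustive oracle.
* `simulateCodonPair()` introduces at most one substitution per codon
  and never creates a stop, so the planted counts are recovered
  exactly; multi-hit pathway averaging is exercised separately with
  hand-built codon pairs in the unit tests.
* `simulateExpression()` separates parental means by `fold` and places
  the F1 mean per mode: A at MP, PD at HP, ND at LP, POD at HP·fold,
  NOD at LP/fold, and PPD/NPD at the **geometric** midpoints
  √(MP·HP) and √(LP·MP). The noise model is lognormal
  (mean-preserving, coefficient of variation `cv`; no noise model is
  published) and the classifier tests on the log scale, so the
  geometric midpoint splits the planted effect evenly on the scale
  where power is decided; the arithmetic midpoint sits log-close to
  HP and leaves PPD under-powered (~0.88 recovery at fold 4, six
  replicates, cv 0.1) relative to every other mode (~0.92+).
* None of the generators emulate read-level error, alignment error,
  mapping bias, expression count overdispersion beyond lognormal, or
  linked loci. Passing tests therefore demonstrate correctness of the
  classification and counting machinery under its stated model, not
  robustness to upstream artefacts in real data.

## Problem sizes and numerical choices

The test suite validates the reconciliation stack exhaustively over
every unrooted gene-tree topology with up to four leaves against a
four-taxon species tree (all taxon assignments) plus 150 seeded random
five-to-seven-leaf trees, each compared with a brute-force oracle that
enumerates every rooting and scans every species node for mappings.
The Ka/Ks engine is compared with an independent pathway-enumeration
oracle on hundreds of random pairs at divergences that make multi-hit
codons common. Recovery properties use cohorts sized so that the rate
being bounded is resolved well inside the bound (e.g. 700 genes per
expression mode gives a binomial standard error near 1% against the
90% recovery requirement). The acceptance script mirrors the study
shape at 1383 gene families and 10,000 trio sites and runs in about a
minute.

Floating-point ties in the density grid, rooting score ties and
allocation ties all break deterministically (grid index, the rooting
tie-break above, earlier class), so identical inputs and seeds give
byte-identical outputs everywhere.

## Known limitations

* The min-(dup+loss) rooting is a documented stand-in for an
  undocumented published criterion; event placements on real trees may
  differ near the root.
* Ka/Ks is the original counting method only — no
  transition/transversion weighting, no codon-frequency models, no
  maximum-likelihood estimators.
* Trio classification assumes genotypes are called; it performs no
  joint genotyping and no structural-variant handling.
* The expression classifier's significance machinery is a stand-in for
  unpublished criteria; with other tests (or DE-package calls) the
  mode proportions on real data would shift.
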