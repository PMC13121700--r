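---
title: "Models and design choices in algkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in algkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(algkit)
```

This vignette documents the statistical models behind each analysis arm,
the tunable parameters and their defaults, what the synthetic-data
generators do and do not emulate, and the places where a genuinely open
design choice was made.

## Chromosome–ALG correspondence

Modern chromosomes descend from a small set of bilaterian ancestral linkage
groups (ALGs); macrosynteny analysis asks which ALGs a chromosome contains,
irrespective of gene order. `algkit` propagates ALG labels to a study
species through single-copy orthologues of a labelled reference
(`assign_alg_labels()`): a gene is labelled *L* exactly when its family maps
to *L*, and genes of unlabelled or non-single-copy families are omitted.
Label propagation is deterministic and invariant to input row order.

Correspondence calls use a one-sided hypergeometric test per (chromosome,
ALG) pair against the genome-wide label totals, BH-adjusted within species.
Published ALG studies delegate this step to external pipelines whose exact
rule is rarely stated; the hypergeometric/BH construction used here is the
standard choice in the ALG literature, and is flagged as such in the run
manifest so downstream users know it is this package's rule, not a
reimplementation of any specific pipeline. Two thresholds matter:

* `q_threshold` (default 0.05) — BH-adjusted significance;
* `min_genes` (default 5) — minimum genes per significant pair. This guards
  against calling enrichment from a handful of translocated strays on small
  chromosomes; whether published fusion calls used such a floor is
  generally unstated, so it is exposed in the configuration.

A chromosome with one significant ALG is `single_alg`, with two or more a
`fusion`; chromosomes with none are reported `unclassified` and excluded
from event tallies rather than being forced into a class, which avoids
overcalling on sparse chromosomes. An ALG significant on two or more
chromosomes of a species yields a fission call.

## The mixing test

A fused chromosome may retain its ancestral blocks (recent fusion) or have
interleaved them through intrachromosomal rearrangement (fusion-with-
mixing). The test statistic is the number of maximal same-ALG runs along
start-sorted gene order, with ties in start position broken by gene id so
the order is total and results are reproducible. Strand is ignored
throughout, as synteny statistics depend only on gene membership and order.
The null distribution is obtained by shuffling the labels along the
chromosome (`n_perm` draws, default 999, seeded); the one-sided add-one
p-value `p = (1 + #{runs_perm <= runs_obs}) / (1 + n_perm)` tests "fewer
runs than expected", and `p < 0.05` yields `blockwise`, otherwise `mixed`.
A constituent ALG with fewer than two genes makes the verdict
`indeterminate`. The permutation p matches exhaustive enumeration over all
label arrangements on small chromosomes (checked for n = 8 in the test
suite), and the runs statistic is always between the number of constituent
ALGs and the number of labelled genes.

## Linkage conservation against a randomized background

A family's host set in species *s* is the significant ALG set of the
chromosome carrying its gene. Under the default `shared_alg` mode the
family is conserved when the intersection of host sets over all required
species is non-empty — a fused chromosome can legitimately carry more than
one ALG, and a family consistently sitting on, say, {H, Q} chromosomes in
every species is conserved but flagged `ambiguous`. The strict
`single_alg` mode demands a singleton intersection; strict conservation
implies shared conservation, never the reverse. Families hosted on
chromosomes with no called profile or no significant ALG are
`unevaluable` and dropped from both numerator and denominator (with the
count reported), so sparse assemblies are not penalized as "not
conserved".

The conservation rate of a focal set is compared with a uniform random
sample of single-copy families (default n = 100, seeded; focal families
excluded by default to avoid contamination, toggleable) using the Pearson
chi-square statistic on the 2×2 table with df = 1 and no continuity
correction — the most common default, and directly checkable against the
textbook Σ(O−E)²/E sum. A permutation p-value over relabellings of the
pooled Bernoulli outcomes (add-one corrected) is available via `mc_reps`.

Two numerical facts about the permutation p are worth knowing. First, its
null is discrete: the estimator converges to the *inclusive* exact
probability P(χ²_perm ≥ χ²_obs), which exceeds the asymptotic p by the mass
of the observed atom. For tables with tens of observations per group that
gap can reach 0.1; it shrinks like the reciprocal square root of the table
size and is below 0.01 only for thousands of observations per group. The
permutation p is therefore deliberately conservative for small tables — it
is the recommended p-value whenever any expected cell is below 5 (the
result flags this) — and agreement with the asymptotic p should only be
expected, and is only asserted in the acceptance tests, in the large-table
regime. Second, with the statistic compared at tolerance 1e-12, equal
proportions give χ² = 0 and p = 1 exactly.

## The fixed-dispersion exact test

Perturbation contrasts use a conditional negative-binomial exact test with
the dispersion fixed at φ = 0.1, a deliberately conservative choice for
designs where a common dispersion cannot be estimated reliably. Replicated
samples are handled by library equalization and group summation: each
sample is scaled to the geometric-mean library size, rounded half-to-even,
and summed within its group. The sum of *n* i.i.d. NB(m, φ) variables is
NB(nm, φ/n), so group sums keep a closed NB form; conditional on the total
*t*, the success probability cancels between groups and the split follows a
negative hypergeometric law that depends only on the group sizes and φ.
The two-sided p-value sums the probabilities of all splits whose
probability does not exceed the observed one, with a 1e-10 relative
tolerance so floating-point ties at symmetric splits are counted. At φ = 0
the law degenerates to Binomial(t, n_a/(n_a+n_b)), i.e. the exact binomial
test. This construction was chosen over reimplementing a mean–variance
modelling pipeline for replicated data: a single, fully specified test that
an independent enumeration oracle can verify end to end, applied uniformly
to all contrasts, was judged more valuable for a reusable package than
mimicking a heavier model whose fitted weights cannot be checked without
the original software. The test matches an established exact-test
implementation to 1e-10 on shared ground (equal library sizes, fixed
dispersion), which the suite verifies.

Thresholding follows the two-preset convention: discovery (linear FC > 2,
raw p < 0.01) and stringent (FC > 4, p < 0.001), both combined with BH
FDR < 0.05. "Fold-change > 4" is read as linear fold change (|log2FC| > 2);
log2 fold changes are computed from mean CPM with a 0.5 pseudo-count so
zero-count genes have finite, stable values. The three gates are recorded
separately in the output, so either reading of a raw-p versus adjusted-p
gate can be recovered after the fact. High and low doses of the same agent
are pooled into one condition before summation.

A gene is classified `BMP_up` when significantly down in *both* inhibitor
contrasts and significantly up in the ligand contrast (mirror for
`BMP_down`); requiring both independent inhibitors protects against
off-target effects of a single molecule, and an `either` mode is available.
Cross-stage restriction keeps genes called in the same direction at both
stages; genes called in opposite directions are excluded and reported as
conflicts rather than silently dropped.

For the clustering summaries, expression is log2(x+1)-transformed and
row-mean-subtracted (row SD scaling optional), distances are 1 − Pearson
correlation, and linkage is average by default. Tie handling is that of
`stats::hclust()` — the lowest-index pair among equidistant candidates is
merged first — so leaf order is deterministic given input order. Constant
rows have no defined correlation distance and raise an error naming the
row.

## Transcriptome age index

TAI is the expression-weighted mean phylostratum, computed on linear
expression (TPM) by default — the convention of the phylostratigraphy
literature; a log-scale variant can be had by transforming the input, but
changes the weighting and is not the default. TAI is a convex combination
of strata, hence bounded by the youngest and oldest stratum present, and
invariant to rescaling any sample. Contrasts between conditions use
two-sided Welch t-tests on per-batch TAI values (one value per biological
batch, n = 3 by default); Welch was chosen over the pooled-variance test as
the safer default under unequal variances, and both are trivially available
since the per-batch TAI values are returned. Degenerate inputs follow a
fixed convention: zero variance in both groups with equal means gives
t = 0, p = 1, flagged; unequal constant groups give p = 0, flagged. With
n = 3 the Welch test on TAI means is conservative under the generator's
noise model — its null rejection rate sits well below the nominal 0.05,
which the suite asserts as an upper bound only.

## What the generators emulate — and what they do not

`simulate_clade_genomes()` builds each species from one chromosome per ALG
with uniformly placed genes, then applies planted fusions, fissions and
per-gene random translocations, emitting the orthology, reference and truth
needed to score every downstream call. Two deliberate choices:

* *Mixed fusions interleave round-robin*, the fully mixed end state. A
  uniformly random interleave would be declared blockwise by a correctly
  calibrated α = 0.05 test about 5% of the time — by construction, not by
  error — so planted mixing labels would not be exactly recoverable. The
  round-robin limit makes "mixed" unambiguous while leaving the test's
  calibration checked separately on null shuffles.
* *Fissions keep at least 10 genes per fragment* (configurable), so both
  fragments remain callable at the default `min_genes = 5`; an
  unconstrained split point would routinely produce fragments too small to
  call, which tests a different property (sparse-chromosome behaviour)
  than fission recovery.

`simulate_perturbation_counts()` draws NB counts with log-normal baseline
means (meanlog = log 50, sdlog = 1), ±20% uniform library factors, and
multiplies planted genes by 2^±effect in the appropriate arms — the
direction structure of an inhibitor/inhibitor/ligand design with three
replicates. `simulate_phylostrata()` draws strata from a geometrically
decaying distribution (16 strata, ratio 0.8), emulating old-heavy real age
catalogues, and `simulate_tai_dataset()` multiplies the youngest-stratum
decile by a factor (default 4) in affected conditions with log-normal batch
noise (sdlog = 0.2, a realistic between-replicate coefficient of variation
for bulk expression).

None of the generators emulate sequence evolution, gene family birth and
death, unequal chromosome sizes, GC or mappability biases, isoform
switching, or count quantification error. Passing the planted-truth tests
therefore shows the *statistical machinery* is correct and calibrated under
its stated model; it does not show that real genomes satisfy that model,
and real-data analyses should treat the thresholds as starting points, not
guarantees.

## Problem sizes and runtime choices

The test suite runs its calibration and recovery studies at sizes chosen to
keep the full suite around two minutes on one CPU while leaving comfortable
statistical margins: 500 null-enrichment simulations at 480 genes, 2000
conservation type-I draws, 50 null DE simulations at 800 genes, 20 seeded
clade replicates at 50 genes/ALG for synteny recovery, 10 seeded
two-stage experiments at 2000 genes for regulation recovery, and 200 TAI
experiments. The acceptance script uses the same generators at slightly
smaller replicate counts and finishes in well under a minute.

## Known limitations

* The enrichment rule is a stand-in for unpublished pipeline internals;
  concordance with any specific external tool is not claimed.
* The conservation test is not phylogenetically corrected; closely related
  species inflate the effective sample.
* The exact test assumes a common fixed dispersion; genes with much larger
  true dispersion will be anti-conservative, which the FDR gate only
  partially absorbs.
* The permutation p of the conservation test is conservative for small
  tables (discreteness), as discussed above.
* TAI inherits the biases of its input phylostrata; the package does not
  estimate gene ages.
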