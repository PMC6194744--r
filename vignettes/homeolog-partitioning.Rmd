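---
title: "Scoring homeolog expression partitioning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring homeolog expression partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeoTSS)
```

## The measurement and its classification

Each observation is an allele-specific expression measurement of one gene in
one individual and tissue: two signal intensities, one per homeolog (N, the
japonica copy; 9, the indica copy), reduced to the N-fraction
N/(N+9) x 100%. The analysis is categorical by design — the platform
produces a bounded ratio per SNP assay, not read counts, so count-based
allelic-imbalance models do not apply. The N-fraction is binned into seven
bias categories plus a separate no-expression state (both signals below
detection).

Three numerical conventions matter:

* **Boundary membership.** The published category bands (0-5, 5-20, 20-40,
  40-60, 60-80, 80-95, 95-100) do not state which band owns a boundary
  value. We use left-closed half-open intervals ascending with the top
  interval closed (`[95, 100]`), so the seven bands exactly partition
  [0, 100] and classification is total and deterministic. Under continuous
  measurement noise a boundary value has probability zero, so the choice
  does not affect results in expectation; it is documented so that discrete
  inputs behave predictably (80 is strongly N-biased; 100 is completely
  N-biased).
* **Detection limit.** No threshold for "no expression" is published. The
  reader takes a configurable `detection_limit` (default 0) on raw signals;
  only measurements with *both* alleles below it (or exactly 0/0) become
  undefined and classify as `NO_EXPRESSION`.
* **Silencing.** A homeolog is *silenced* in a tissue only under complete
  bias against it (< 5% or >= 95%). `NO_EXPRESSION` sets neither
  allele-specific silencing flag: silencing of both copies is a distinct
  state, and treating it as silencing of each copy would double-count a
  property that is not homeolog-specific.

## Calibration QC

Assay genome-specificity is checked with parental DNA mixed at known ratios
(1:3, 1:2, 1:1, 2:1, 3:1). `fit_calibration()` regresses observed on
expected N-fractions and reports the squared Pearson correlation, which for
a simple linear regression equals the regression R²; the pass rule is the
strict inequality R² > 0.9. We regress in fraction space rather than ratio
space because fractions are bounded and symmetric in the two alleles,
whereas ratios are unbounded and asymmetric. Degenerate designs (fewer than
two points, or a single expected value) are errors, and a constant observed
vector has R² = 0 by convention (no linear association is recoverable).

## TSS, reciprocal TSS and nonfunctionalization

Within a tissue set, per gene x individual and homeolog:

* **TSS**: silenced in >= 1 measured tissue of the set and expressed in
  >= 1 other.
* **Nonfunctionalization**: silenced in *all* measured tissues of the set.
  The two are mutually exclusive by construction.
* **Reciprocal TSS**: both homeologs of the gene have TSS events in the
  same set; counted once per gene x individual x set, matching the notion
  of discrete subfunctionalization "cases".
* No-expression tissues are neutral: they are measured (they enter
  denominators) but are evidence neither of homeolog-specific silencing nor
  of expression, so a homeolog silenced in one tissue with every other
  tissue dark yields no event.
* Gene x individual pairs with fewer than two measured tissues in the set
  are excluded entirely — TSS is undefined without a contrast.

The standard sets are the two tillering tissues, the four booting tissues,
all six tissues, and the two development sets (L1 vs L2, R1 vs R2) that
contrast the same organ across growth stages; development sets isolate
silencing attributable to development because genotype and organ are held
fixed while stage varies (the same individual is sampled at both stages).

**The TSS percentage.** The published unit "(gene x tissue)" is ambiguous
about the denominator. Default: an individual's score counts (gene,
homeolog, tissue) triples — numerator: triples silenced as part of a TSS
event; denominator: all measured triples of qualifying genes. This is the
only reading that yields a per-individual percentage spanning both
homeologs; the alternative gene x tissue convention (a cell counts once,
and is positive when either homeolog is TSS-silenced there) is available
via `denominator = "gene_tissue"`. Group summaries report the mean of
individual percentages with standard error SD/sqrt(n), and a group with one
individual gets an `NA` standard error rather than a fabricated zero.

**Locus patterns.** Statements like "x% of loci expressed the two alleles
unequally" need a locus-level rule. A gene x individual locus is *equal*
when strictly more than half of its defined-fraction calls are
`EQUIVALENT` (40-60%), else *unequal*; loci with no defined calls are
excluded. Majority was chosen over "all tissues equivalent" so that a
single noisy tissue cannot flip a locus; ties count as unequal since half
the tissues deviating is positive evidence of bias.

## Group statistics

Contrasts use the Mann-Whitney rank-sum test (between groups; root vs leaf
development-TSS within a group) and the Wilcoxon matched-pairs signed-rank
test (tillering vs booting within individuals), two-sided throughout. With
n1 + n2 <= 12 and no ties the rank-sum p-value is exact; otherwise the
normal approximation with tie and continuity corrections is used (likewise
for <= 12 nonzero tie-free pairs in the signed-rank test). At the study's
group sizes (6-7) the corrected approximation is mildly conservative — its
null rejection rate at alpha = 0.05 is about 0.04 — and it tracks the exact
test to within ~0.005 in the decision-relevant tail (exact p < 0.2); in the
mid-range (p around 0.5) the two can differ by up to ~0.012, which affects
no decisions. Zero differences are dropped from the paired test, and an
all-zero contrast returns a flagged degenerate p = 1. No multiplicity
adjustment is applied by default, matching the original analysis; a
Holm-adjusted column is emitted alongside for modern use.

## The synthetic-data generator

Raw per-assay values for this design exist only as figure images, so the
package validates itself on simulated data with known truth. The generator
mirrors the study structure: 30 genes drawn from eight key pathways, six
tissues over two stages, four plant groups — the in vitro parental RNA mix
(MIX, n = 6), pooled reciprocal F1 hybrids (n = 6), and the reciprocal
synthetic tetraploids NN99 and 99NN (n = 7 each) — with every individual
measured in every tissue.

Per gene x individual x tissue x homeolog, silencing is Bernoulli at a rate
indexed by plant group and tissue class (leaf, root, flag leaf, spike);
nonfunctionalization (a homeolog off in all tissues) and reciprocal-TSS
injection (the two homeologs forced off in two different tissues) are
additional per-gene-x-individual events. True N-fractions are the gene's
baseline (Beta-distributed across genes, mean 50%, concentration 4.5, then
shrunk toward 50% by a group-specific attenuation emulating trans-regulator
equalization in hybrids), or `eps` / `100 - eps` under single-homeolog
silencing with a leak of `eps = 1%` — silenced states deliberately emit
near-boundary rather than exact 0/100 values so the 5%/95% classification
bands are genuinely exercised. Observed fractions add Beta noise
re-parameterized by (mean, concentration); the default concentration 300
gives a standard deviation of ~2.9 percentage points at 50%, a plausible
scale for ratio measurements on this platform (no dispersion estimate is
published; the parameter is user-tunable). Both-silenced states emit zero
signals and surface as no-expression measurements.

The `paper_like` preset fixes the group/tissue silencing rates to the
study's qualitative findings — MIX highest (pre-existing cultivar
differences), F1 lowest, tetraploids intermediate with 99NN > NN99, and
roots well above leaves (root 0.16-0.25 vs leaf 0.01-0.10 across groups) —
and attenuations (MIX 1.0, F1 0.3, NN99 0.6, 99NN 0.75) chosen so that most
MIX loci are unequal while most F1 loci are equivalent. Reciprocal injection
rates (0.003-0.035) put a handful to a few dozen reciprocal cases in a full
dataset. These values were set once, from the qualitative description, as
the package's standing definition of "study-like" data.

**What the generator does not emulate:** instrument-level signal artifacts,
probe-specific amplification bias (calibration slopes differing from 1),
correlated silencing across genes in a pathway, within-individual tissue
correlations beyond the shared gene baseline, and segregation differences
between reciprocal cross directions. Passing recovery tests on this model
therefore demonstrates that the scoring machinery is correct under the
stated stochastic model — not that the biological conclusions of any real
dataset are reproduced.

**Closed-form validation.** `expected_tss_percent()` computes the exact
expected TSS percentage under the generator: it enumerates the
nonfunctionalization/reciprocal modes and per-tissue silencing states, folds
in the Beta-noise misclassification probabilities (the chance an expressed
measurement strays below 5% or above 95%, and the chance a silenced one
escapes its band), and integrates over the gene-baseline distribution on an
equal-probability quantile grid (401 points). It shares no code with the
detection path, so recovered-vs-nominal comparisons are a genuine
cross-check. It assumes the complete design (`detection_dropout = 0`, the
default), under which the score denominator is constant and the estimator
is unbiased for the closed form.

## Problem sizes used in the validation suite

The test suite exercises: a dense 0.01-step grid over [0, 100] for the
classification partition; 100 simulated calibration sets against a
normal-equations oracle; 10,000 random category assignments (2 genes x 4
tissues) against a brute-force reimplementation of the event definitions;
200 replicates of the full study-sized design (30 genes, 26 individuals)
for parameter recovery and ordering; exhaustive enumeration of rank-sum
labelings (n1 + n2 <= 10) and sign assignments (<= 10 pairs); and 5,000
null simulations for test size. These sizes give Monte-Carlo errors
comfortably below the effects being verified while keeping the suite fast
to run routinely.

## Known limitations

* The bias scheme is categorical; the package deliberately does not model
  continuous allelic imbalance (e.g. beta-binomial tests), which the
  measurement design does not support.
* Silencing calls inherit the hard 5%/95% bands: a homeolog hovering at 6%
  is never "silenced", however consistently. Sensitivity to the bands can
  be probed through the generator's `silent_leak` and noise parameters.
* TSS percentages from different denominator conventions are not
  comparable; outputs carry the convention only implicitly, so mixed-mode
  comparisons are the user's responsibility.
* With heavy dropout, per-individual denominators become random and small;
  scores remain valid ratios but group standard errors understate the
  additional design variance.
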