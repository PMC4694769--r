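---
title: "Methods and design of polycis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of polycis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polycis)
```

# The model behind the sign test

In an interspecific hybrid, both parental alleles of a gene share one
nucleus and one *trans* environment, so allelic expression imbalance
isolates *cis*-acting divergence. `polycis` quantifies that imbalance per
gene as the ratio of allele-A to allele-B read counts, with replicates
pooled by summation before the ratio is formed (one ASE value per gene
per condition — summing is also the maximum-likelihood pooling under the
binomial model used for testing).

The evolutionary null is that the *direction* of cis-divergence is
independent across genes and symmetric: any individual gene may drift up
or down, but a functionally coherent gene set should be neither
concentrated in one tail of the ranked ASE distribution nor directionally
concordant. Two exact tests probe this:

* **Stratum enrichment.** Rank the `N`-gene universe by pooled
  log~2~ ASE and take the top fraction `f` in one direction
  (`K = round(f * N)` genes, half-up). For a testable set of size `n`
  with `k` members inside the stratum, the statistic is the upper
  hypergeometric tail `P(X >= k)`. Half-up rounding matters at the 1%
  stratum of a 4394-gene universe: `K = 44`, giving
  `hypergeom_tail(4394, 44, 11, 4) = 2.7e-6`, whereas truncation to 43
  gives a slightly different value.
* **Directionality.** Count the set members whose log~2~ ASE points in
  the tested direction at all (`n_up`; genes at exactly 0 count for
  neither direction) and score `P(X >= n_up)` under
  Binomial(`n`, 0.5).

Both tests assume the set members evolved independently — linked genes
share *cis* haplotypes. `evaluate_set()` therefore warns (but does not
exclude) when supplied gene positions reveal genomically adjacent
members.

Collection scans multiply the hypergeometric p by the full number of
tests performed, (sets) × (fractions) × (directions) — the most
conservative reading of Bonferroni correction, chosen because the
default scan already reuses each set six times (three fractions × two
directions). The scan is direction-symmetric by construction; a
repressed-gene set showing no bias is an ordinary negative result, not a
special case.

Because both statistics are exact and discrete, their null p-values are
*super-uniform*: the probability of p < α is at most α and typically far
below it. At the default configuration (N = 4394, K = 44, n = 11) the
achievable level nearest 0.05 requires an overlap of 2 and has
probability ≈ 0.005, so empirical type-I error sits well under the
nominal level. The calibration utilities (`calibrate_null()`, and the
corresponding tests) therefore check the one-sided property — rejection
never *exceeds* the nominal level beyond Monte-Carlo noise — rather than
a two-sided envelope no exact test could satisfy.

# Exact tests and multiplicity

Two-sided binomial p-values use the minimum-likelihood convention: the
sum of probabilities of all outcomes no more probable than the one
observed. This is the standard exact two-sided definition, symmetric in
the two counts at p~0~ = 0.5, and matches full pmf enumeration to
1e-12 (property-tested). The treatment-response test compares a gene's
treated count against the null proportion implied by the two library
sizes, `lib_t / (lib_t + lib_u)` — the exact analogue of a
library-size-normalised fold change. Tail probabilities for both the
hypergeometric and binomial statistics are evaluated in log space to
stay accurate below 1e-300.

False-discovery control is Benjamini–Hochberg over exactly the filtered
gene universe; q-values are only meaningful relative to the universe the
filter defines, so `bh_fdr()` refuses missing values rather than
silently dropping them.

# Filtering and candidate selection

The coverage filter retains genes with ≥ 20 replicate-summed reads on
*each* allele in the analysis condition (boundary inclusive). Pooling
before filtering matches the one-ASE-value-per-gene design; it also
guarantees `ase_ratios()` never sees a zero denominator, which is why
pseudocounts default to off everywhere and must be opted into
explicitly.

Candidate adaptation genes must jointly show: pooled ASE ratio ≥ 4
toward allele A; an allele-minimum response fold ≥ 4 (per-allele folds
are geometric means across replicates, and taking the *minimum* of the
two alleles means both must respond); and a response p ≤ 1e-5 in every
biological replicate of every required allele. All fold thresholds are
inclusive. The quadrant census classifies fold-passing genes by
(A/B bias) × (induced/repressed), using the allele-maximum fold for
repression so that "repressed" also means both alleles. A near-miss
report lists genes failing exactly one fold criterion by ≤ 10%; these
are never auto-promoted, since rescuing a near-miss is a judgement call
that should stay manual.

# Growth kinetics

The maximum growth rate is the largest OLS slope of log~10~(OD) over
every window of 20 consecutive time points — 4 hours at the nominal
12-minute reading interval. Windows are defined by point count, not
elapsed time; under irregular sampling the regression still uses the
actual times. The implementation computes all window slopes in one
vectorised pass over rolling sums and is property-tested for exact
equality against a naive per-window `lm()` loop.

Readings at or below a blank floor (default 0.01 OD) are dropped before
the log transform; plate readers produce near-blank noise that would
otherwise dominate the early windows. Blank subtraction itself is not
applied by default.

One numerical subtlety is documented rather than hidden: on a *logistic*
curve the best 4-hour window spans rising density, so its log-slope sits
a few percent below the instantaneous low-density slope
`r * log10(e) * 60` (at the default simulation parameters, about 3.4%
below). On an exact exponential the estimator recovers the analytic
slope to 1e-10 relative error; the attenuation is a property of
windowed estimation on saturating curves, not an estimator bias.

Toxin effects are expressed as `log2` ratios of fold-reductions,
`log2((rate_u/rate_t) / (ref_u/ref_t))`: a strain whose rate is reduced
2-fold more than the reference scores +1, a 4-fold smaller reduction
scores −2, and the measure is antisymmetric under swapping strain and
reference. The additive-difference alternative is incompatible with
this 2-fold → +1 convention, which is why the ratio definition is
hard-wired.

# Competition fitness

Barcode counting is deliberately strict: a read counts for a barcode
only on a perfect match of flank + 6-base barcode + flank, anywhere in
the read, and reads matching no pattern — or more than one — are
tallied as unmatched. Maps are validated at load: unique barcodes of the
stated length, pairwise Hamming distance ≥ 2 (one sequencing error
cannot convert barcodes into each other), and no collisions after flank
concatenation.

The selection coefficient is defined on the natural-log scale per
doubling: with `R` the strain/control frequency ratio,
`s = ln(R_T / R_0) / T`. This is the only definition consistent with
both of the published anchor pairs — `ln(0.80)/40 = -0.56%` ("0.6%
disadvantage, 20% lower after 40 generations") and
`ln(1.37)/40 = +0.79%` ("0.8% advantage, 37% higher") — whereas the
discrete `(1+s)^T` form does not reproduce them. Generation counts for
serial-dilution schemes follow
`log2(od_trigger/od_start) + n * log2((v_t+v_w)/v_t)`; the study's
scheme evaluates to 39.7 ≈ 40 doublings.

Barcode-level coefficients are averaged within a replicate (unweighted,
since the three barcodes per strain are exchangeable tags), then
summarised across replicates by mean and standard error. Zero final
counts get a 0.5 continuity correction with a warning; condition
contrasts use Welch's t-test, the safer default when only "t-test" is
specified and variances may differ between conditions.

# Trait parsimony

`fitch_min_changes()` implements small parsimony as a Sankoff-style
dynamic program with a 2×2 cost matrix: on bifurcating trees with unit
costs it reduces exactly to the Fitch union/intersection rule, and it
generalises cleanly to polytomies and to asymmetric gain/loss weights
(default 1:1; the asymmetric option exists because loss of a metabolic
trait is often easier than gain, but any weighting beyond 1:1 is the
user's modelling decision). A second, upward pass yields for every node
the set of states realised in at least one minimal reconstruction, and
`enumerate_mprs()` backtracks through the same tables to list every
minimal history with its per-branch gain/loss events — ambiguity such
as "one deep loss versus several shallow ones" appears as multiple
reconstructions of equal cost. The tree is used rooted as given, and
branch lengths are ignored. Correctness is property-tested against
exhaustive enumeration of all internal-state assignments on random
trees, and against an independent established implementation.

`binarize_resistance()` turns a continuous effect measure into the
binary trait by thresholding; the `"auto"` rule places the threshold at
the midpoint of the largest gap in the sorted values — the natural 1-D
two-cluster split, which errors rather than guessing when no gap exists
or fewer than three strains are supplied. By default *lower* effect
log-ratios mean resistance, matching the fold-reduction convention in
which less-impaired strains score negative.

# What the simulations emulate — and what they do not

`gen_ase_counts()` draws per-gene totals from a gamma-Poisson (negative
binomial) with mean 500 and dispersion 0.1, splits alleles binomially
around each gene's true ASE proportion, places background true log~2~
ASE symmetrically around 0 with SD 0.3, and shifts an embedded 11-gene
set by +2 log~2~ units toward allele A in a 4394-gene universe — the
scale of the motivating experiment. The background SD is a realism
choice, not an estimate: 0.3 puts the top ~1% of background genes near
|log~2~| ≈ 0.9, comfortably below the embedded effect, so detection
power is high but not tautological. Because the allele split is exactly
binomial given the total, calibration tests of the binomial machinery
are fair; the dispersion knob exists to probe robustness, not to model
any particular library. The generators do **not** emulate mapping bias,
reference bias, isoform structure, or correlated expression between
neighbouring genes — so passing tests demonstrate correctness of the
statistics under their own assumptions, not robustness to those
artefacts.

`gen_growth_curves()` produces lagged logistic curves (K = 1.5 OD,
r = 0.006/min, 120-min lag, inoculum 0.025 OD, 12-min readings over
48 h) with additive Gaussian noise floored at 0.001; it does not model
plate spatial effects, evaporation, or multiplicative noise.
`gen_competition()` updates equal starting frequencies deterministically
by `f * exp(s*T)` and samples reads multinomially at depth 1e5 per
sample — sequencing noise only, no drift during growth and no PCR
jackpotting. `gen_trait_tree()` propagates a trait down a random
topology applying specified gain/loss events, rejecting inconsistent
histories (a loss before any gain).

# Problem sizes and reproducibility

Every generator takes an explicit seed and is bit-reproducible. The
test suite exercises the statistics at the scales the analyses use:
study-size ASE universes (4394 genes) for power and calibration, 200
seeded replicates for power/recovery properties, 1000 permutations for
calibration, 100 random curves for the growth oracle, and 200 random
trees (≤ 8 leaves, where exhaustive enumeration is feasible) for
parsimony. These sizes were chosen so each property is measured with
useful Monte-Carlo precision while the full suite stays fast enough to
run routinely.

# Known limitations

* The sign test treats the ranked universe as fixed; it does not model
  uncertainty in each gene's ASE estimate, so very low-coverage genes
  just above the filter contribute rank noise.
* Per-replicate response tests inherit the usual caveat of exact
  binomial tests on deeply sequenced libraries: tiny fold changes can be
  statistically significant, which is why candidate selection couples
  the p criterion to a 4-fold effect threshold.
* Fitness estimation assumes the control strain's frequency is large
  enough that its sampling noise is negligible relative to the focal
  strain's; with a rare control, barcode-level ratios become noisy and
  the replicate SE widens accordingly.
* Parsimony reconstructions are reported exhaustively but weighted
  equally; no attempt is made to integrate over histories or rates.
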