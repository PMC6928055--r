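---
title: "Methods: comparing gut microbial communities between cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing gut microbial communities between cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

gutcohort implements the statistical workflow used to contrast the gut
microbiota of two human cohorts — the motivating case being tribal (TR)
versus urban (UR) Indian populations profiled by 16S rRNA amplicon
sequencing — starting from a feature-by-sample abundance table (OTUs or
genera). This vignette is the package's own account of each method, the
parameters that matter, and the design decisions behind them.

## The data model and preprocessing

All stages operate on an `abundance_table`: a non-negative features ×
samples matrix, `counts` or `relative`, with an optional ranked lineage per
feature. Preprocessing mirrors standard amplicon practice:

* **Sparse-feature removal** (`filter_sparse()`): features holding less
  than 0.002% of the grand read total are dropped — the usual OTU-table
  denoising threshold.
* **Rarefaction** (`rarefy()`): each sample is subsampled *without
  replacement* (multivariate hypergeometric) to a common depth, by default
  the minimum column sum — the "rarefy to the shallowest sample" policy.
  Each sample draws from an RNG substream keyed on its id, so the result
  is identical under column reordering.
* **Prevalence filter** (`prevalence_filter()`): before differential
  abundance testing, features must be non-zero in at least 51% of the
  samples of *every* cohort — i.e. have a non-zero median in each group.
* **Taxonomic cumulation** (`collapse_taxa()`): OTU rows sharing a lineage
  prefix are summed to the requested rank; this commutes with conversion
  to relative abundance.

## Alpha diversity

`alpha_diversity()` computes, per sample: Shannon `H = -Σ p_i ln p_i`
(natural log, the vegan convention; the base is exposed), Gini–Simpson
`D = 1 - Σ p_i²` (chosen over inverse Simpson because the comparison is on
the probability scale), and bias-corrected Chao1
`C = S_obs + F1(F1-1) / (2(F2+1))`, which is defined even with no
doubletons. Chao1 needs integer counts, so rarefied counts are the
intended input for all three — rarefaction is required for Chao1 and
harmless for the other two, which are depth-invariant in expectation.

`compare_groups()` runs two-sided Wilcoxon rank-sum tests per metric per
group pair and applies Benjamini–Hochberg correction across the entire
family emitted together (all metrics × all pairs), not per metric. The
rank-sum test is exact for small untied groups and uses the mid-rank
normal approximation with continuity correction otherwise.

## Ordination and cluster number

`jsd_distance()` computes the Jensen–Shannon divergence between sample
profiles through the entropy identity `JSD(P,Q) = H(M) - (H(P)+H(Q))/2`,
`M = (P+Q)/2`, and returns its square root by default — the metric form
used throughout enterotyping work; raw JSD is a flag away since either
reading is defensible. Zeros are replaced by a pseudocount (default
`1e-6`, the classic enterotyping convention) and columns renormalised.

`pcoa()` is classical scaling: double-centred squared distances,
eigendecomposition, axes ordered by eigenvalue. Negative eigenvalues
(possible for non-Euclidean inputs) are reported, never silently dropped.

`pam_jsd()` is k-medoids. Instances with `n <= 10` samples are solved
*exactly* by enumerating medoid subsets (cheap, and it removes the SWAP
heuristic's occasional local optimum on toy problems); larger instances
use BUILD + SWAP. Assignment ties break toward the lowest medoid index so
results are deterministic.

`ch_index()` evaluates Calinski–Harabasz `[SS_B/(k-1)]/[SS_W/(n-k)]` on
the PCoA embedding restricted to positive-eigenvalue axes: CH needs
centroids, which JSD space does not supply. Whether the distance fed in is
sqrt-JSD or raw JSD is up to the caller; the default pipeline uses
sqrt-JSD. `optimal_k()` maximises CH over `k = 2..k_max`.

## Dirichlet-multinomial mixture enterotypes

`fit_dmm()` models count profiles as a K-component mixture of
Dirichlet-multinomials. The E-step computes responsibilities from the
component DM likelihoods (the multinomial coefficient, constant in the
parameters and in K, is omitted). The M-step re-estimates the weights
from responsibility means and each component's concentration vector α by
responsibility-weighted Minka fixed-point updates — an MM step, so the
observed log-likelihood trace is monotone non-decreasing, which the tests
assert on every fit. Defaults: 5 random restarts (component assignments
drawn at random, moment-matched initial α at total mass 10), relative
tolerance `1e-6`, at most 1000 iterations, and fitting on the 500 most
abundant features for tractability on large OTU tables (a full-table mode
is one argument away).

**Model evidence.** K is chosen by minimising a Laplace approximation of
the negative log-evidence. The textbook flat-prior form
`-(logL + (d/2)·ln 2π - ½·ln|H|)` is undefined at the boundary optima EM
actually reaches: a component whose responsibility mass vanishes has
near-zero curvature, and a clamped determinant turns that into a large
*negative* penalty, so selection runs away to the largest K tried. We
therefore work in the unconstrained `η = log α` parametrisation (α is
positive; at a stationary point `|H_η| = |H_α|·Π α²`) and place a weak
`N(0, 9)` prior on each η entry. The prior's normalisation exactly cancels
the α-block `2π` volume term, its `1/9` curvature keeps the determinant
defined for empty components, and its quadratic term penalises the
degenerate `α → ∞` single-sample components. The observed information is
taken block-diagonal per component with the exact rank-one structure
`D + c·αα'` inside each block, plus a multinomial block for the mixture
weights. With this evidence, model selection recovers the true K = 3 in
20/20 seeded runs of the canonical 3-component simulation, while the
flat-prior form picked K in 4–7.

## Bootstrap core taxa

A feature is core-qualified in a cohort when it reaches 0.1% relative
abundance in at least 70% of samples (`core_qualifies()`).
`bootstrap_core()` stabilises that call: 1000 resamples of the cohort
(by default a standard bootstrap — n samples drawn with replacement; the
subset size and replacement policy are exposed), the qualifying set
recomputed each time, and each feature scored by its appearance frequency
scaled to 0–100. Features scoring at least 80 are flagged core. At the
exact 70% prevalence boundary the score equals the probability that a
binomial resample clears the threshold (about 45% at n = 80), which the
tests check against the closed-form binomial oracle. `compare_cores()`
splits two cohorts' reports into shared and exclusive core sets, with
`NA` medians where a feature misses the score cutoff in one cohort.

## LDA effect size (LEfSe-style)

`lefse()` composes a per-feature screen with a bootstrapped
linear-discriminant effect size:

1. **Screen** (`kw_screen()`): for two classes, the exact two-sided
   rank-sum test (the distribution the Kruskal–Wallis statistic reduces
   to at two groups); three or more classes use `kruskal.test()`. Raw
   p-values, no FDR — the LEfSe convention; constant features get p = 1.
2. **Effect size** (`lda_effect()`): samples are scaled to a fixed total
   (10⁶) using the *full table's* column sums, so a feature's value stays
   its share of the whole community even when only screen survivors are
   scored. On each of 30 bootstrap rounds, two-thirds of each class is
   subsampled and a two-class LDA fitted with the pooled within-class
   covariance ridge-regularised by `1e-2` of its mean diagonal — the
   scale-free form preserves invariance to the scaling total, and the
   magnitude tames the noisy discriminant weights that a
   more-features-than-samples fit otherwise produces. The per-feature
   effect averages the feature's share of the discriminant separation
   with its raw class-mean difference; the reported score is
   `sign(Δ)·log10(1 + mean effect)`.

Swapping the class labels flips every score's sign exactly (the bootstrap
substreams are keyed on each class's sample set, not its label). A feature
is called differential when `p < α` and `|LDA| > cutoff`; the
conventional operating points are cutoff 4 for taxa (α = 0.05 at genus
level, 0.01 at OTU level) and 2.5 for functional pathways (α = 0.001).
There is no subclass stage: the two-cohort design has none.
`lefse_clades()` reruns the analysis at each taxonomic rank for
cladogram-style exports.

## Metadata associations

`bin_metadata()` cuts age into six contiguous 5-year bins `[a, a+5)` (last
bin closed), anchored by default at the observed minimum floored to a
multiple of 5 — the anchor is exposed because no convention fixes it —
and BMI at the WHO cuts 18.5/25 into underweight / normal / obese (the
third group is everything at or above 25, since only three groups are
used). Out-of-span ages are flagged, not dropped.

`two_group_test()` offers the rank-sum test and "White's" two-group
procedure realised as a seeded permutation test of the difference in
means (1000 permutations, two-sided, p bounded below by
`1/(permutations+1)`) with a bootstrap percentile 95% CI; the original's
sparse-data heuristic is omitted because filtered abundance tables are
dense. `multi_group_test()` is Kruskal–Wallis with eta-squared
`(H - k + 1)/(n - k)` (negative values near the null are expected at
small n) and Tukey–Kramer post hoc contrasts on rank means with
unequal-n standard errors against the studentised-range distribution.
`trend_summary()` formalises "abundance increases/decreases across bins"
statements: Spearman correlation of abundance against the ordinal bin
index, BH-corrected within the feature family, with a three-way direction
label.

## Randomization-null co-occurrence networks

`spearman_matrix()` computes all pairwise Spearman correlations (mid-rank
ties, t-approximation p-values, BH across all emitted pairs; per-cohort
matrices via `groups`). `swap_null()` builds the null: at each of 10,000
steps, one uniformly chosen sample pair is swapped *independently within
every feature row* — the independence across rows is what destroys
between-feature association while preserving each feature's marginal —
and all pairwise correlations are recorded. Swaps accumulate by default
(`"walk"`), a randomization walk whose stationary law is an independent
per-row permutation, i.e. the exact permutation null; a `"fresh"` mode
restarting from the observed table each step is available since the
original description is ambiguous. The observed table is never mutated.

`critical_r()` is the two-sided rule: the `confidence` quantile (type-7,
linear interpolation) of the pooled |null r|, 0.99 by default, one global
threshold pooled over all pairs. `build_network()` draws an edge only
where `|r| > critical_r` *and* BH-p < 0.01, signed by the correlation;
`export_network()` writes Cytoscape SIF, GraphML (via igraph) or a TSV
edge list. Numeric metadata and diversity indices can enter as extra
rows; categorical metadata is excluded from correlation.

## Classification harness

`classify_cohorts()` wires together `stratified_split()` (per-class
`floor(0.7·n)` with the remainder to the largest fractional parts, so
80 UR + 75 TR yields 56 + 52-or-53 training samples), `repeated_cv()`
(stratified 10-fold CV repeated 10 times; out-of-fold scores pooled per
repeat into one AUC; the final model refit on all training data), and a
held-out test AUC. The learner is pluggable; the default is a bagged
random forest (200 trees, other details at the randomForest package's
defaults). `roc_auc()` sweeps thresholds over unique scores, integrates
by trapezoid, and cross-checks against the normalised Mann–Whitney U
statistic with mid-rank ties — the two agree to 1e-12 by construction.

## The synthetic-cohort generator

`generate_cohorts()` makes every stage testable without external data.
Per sample it draws a mixture component from the cohort's weights,
proportions from that component's Dirichlet, a depth uniform in
10,000–60,000 reads (wide enough to make rarefaction meaningful), and
multinomial counts. Community profiles are Zipf-like (`rank^-1`, with an
optional decay exponent and rank offset), a few dominant taxa over a long
tail. Three kinds of structure can be planted:

* **Differential abundance**: the target feature's α is multiplied by the
  fold change in the enriched cohort's components, preserving the
  Dirichlet form so mixture recovery stays well-posed.
* **Core features**: a Bernoulli(prevalence) presence indicator times a
  concentrated Beta (shape1 = 20) around the target mean abundance
  overrides the feature's proportion. The overlay, rather than a plain α
  adjustment, is used because a low-α Dirichlet coordinate cannot hit a
  prevalence target and an abundance target simultaneously.
* **Metadata links**: age or BMI is coupled to a feature's relative
  abundance through a Gaussian copula at a requested Spearman strength
  (default ρ ≈ 0.5, matching the rank-correlation scale of reported
  associations).

`diversity_gap_spec()` raises one cohort's expected diversity by the
geometric-mean-preserving power map `α' = gm^(1-1/s)·α^(1/s)`: the
log-spread of α shrinks by `1/s`, flattening the profile (higher evenness
and richness) while composing multiplicatively (`s` then `t` equals
`s·t`) and leaving the other cohort untouched.

The generator emulates compositionality, overdispersion, depth variation,
sparsity and planted signal — it does *not* emulate phylogenetic
structure, taxonomy assignment error, batch effects, or the correlated
taxon blocks of real gut communities. Passing planted-truth tests
therefore demonstrates that the algorithms recover the structure they
model, not that real data meet those models.

## Canonical validation studies and their calibration

The `sim_study_*()` functions freeze one design per analysis stage
(75 TR / 80 UR samples except where noted); the tests and the acceptance
script both run exactly these conditions:

* `sim_study_diversity()`: shared component, TR flattened at scale 5.
* `sim_study_ordination()`: each cohort its own dominant component — two
  true clusters for the CH index and a separable classification problem.
* `sim_study_enterotype()`: three equally-weighted well-separated
  components over 100 features, n = 150.
* `sim_study_effects()`: 200 features, total concentration 300, rank
  profile capped by a rank offset of 20 (top feature about 2%), with
  8-fold effects on five mid-abundance features (ranks 70–110, about
  0.3–0.5% baseline; three TR-, two UR-enriched). This design is
  deliberate: planted features must be abundant enough to survive the 51%
  prevalence rule, small enough that closure (the compensatory deflation
  renormalisation imposes on all other features) stays below the LDA = 4
  detection boundary, and the component concentrated enough that
  selection-inflated mean differences of null features do not straddle
  that boundary. Under these conditions the planted set is recovered
  exactly (no false positives, no misses) in about 95% of seeded runs.
* `sim_study_cores()`: five shared plus three TR-exclusive planted cores
  (prevalence 0.9 at 1% abundance; the exclusives sporadic at 0.3 in UR)
  and three sporadic features (prevalence 0.4) that must stay below the
  score cutoff.

Validation problem sizes: the full test suite simulates at the study's
own scale (155 samples, 100–200 features, 20 seeded replicates per
recovery claim; 10,000 randomization steps for the network null; 1000
bootstrap iterations for core scoring) and completes in a few minutes.

## Known limitations

* The DMM evidence uses a block-diagonal information approximation;
  cross-component curvature is ignored (standard practice, but the
  absolute Laplace values are approximate — only differences across K
  matter here).
* The LDA effect size is a contract on sign, thresholds and ranking, not
  a bit-for-bit reimplementation of any particular LEfSe release; the
  original's exact effect formula is folklore.
* `swap_null()` stores the full pooled null (`steps × choose(F,2)`
  values); for hundreds of features, reduce `steps` or subset features.
* Rarefaction discards reads by design; for differential abundance the
  package follows the relative-abundance route instead, and both inputs
  are accepted where the method allows.
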