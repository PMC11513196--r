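---
title: "Stability-selected partial-correlation networks: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-selected partial-correlation networks: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabnet)
```

## The model

`stabnet` estimates Gaussian graphical models (GGMs) over a
subjects-by-variables table of continuous measures — questionnaire traits,
ERP component amplitudes and latencies, and demographic/task covariates.
Under multivariate normality, a zero entry `Θ[i,j]` of the precision matrix
means variables *i* and *j* are conditionally independent given all others;
nonzero entries scale to partial correlations
`ρ_ij = −Θ_ij / sqrt(Θ_ii Θ_jj)`. The assumptions worth keeping in mind:

* **Gaussianity.** Partial correlations fully characterize conditional
  dependence only for jointly Gaussian data. The package therefore
  normalizes marginals (Box-Cox) and screens out variables it cannot
  normalize before estimation; it does not model ordinal or zero-inflated
  variables.
* **Linearity.** Edges capture linear conditional associations only.
* **i.i.d. subjects.** Rows are exchangeable; no clustering or repeated
  measures at the network stage.

## The adaptive random-penalty estimator

A single graphical-lasso fit is sparse but unstable: resampling the
subjects or nudging λ reshuffles the selected edges. The estimator here
decouples *which* edges exist from *how strong* they are:

1. **Ensemble.** `B` members (default 1000); each draws a bootstrap
   resample of the rows (size *n*, with replacement), computes the ML
   covariance, draws a random penalty, and fits the graphical lasso. The
   per-edge nonzero frequency across members is the proportion matrix. An
   entry counts as nonzero when `|Θ_ij| > 1e-8` — far below any
   interpretable partial correlation, far above numerical noise.
2. **Threshold.** The support keeps edges whose proportion *strictly
   exceeds* τ = .65 (a proportion of exactly .65 is dropped).
3. **Refit.** Support-constrained Gaussian ML on the original sample,
   realized as a graphical lasso with penalty 0 on supported entries and
   `1e6 · max|S_ij|` elsewhere; off-support entries land below `1e-8` and
   are then zeroed exactly. Constrained-fit edge weights are therefore
   *unpenalized* estimates — thresholding decides structure, the refit
   decides magnitude.

Bootstrap members that fail to converge are dropped and counted rather
than retried (retrying would break seed reproducibility); more than 10%
failures aborts with an error.

### The random-penalty distribution

The penalty scheme is the one genuinely open design choice, and it decides
the estimator's operating characteristics. Three kinds are provided:

* `"scaled"` (default): one λ per member, log-uniform over
  `[1.5, 4] · sqrt(log(p) / n)`. The anchor `sqrt(log p / n)` is the
  classical graphical-lasso regularization rate — the magnitude that
  separates sampling noise in a covariance entry from signal. Anchoring at
  the noise level keeps the selection frequency of spurious edges well
  below τ while conditional dependencies of realistic size (|ρ| ≥ ~0.2 at
  *n* in the hundreds) are selected in most members.
* `"scalar"`: λ log-uniform over `[r · λ_max, λ_max]` with
  `λ_max = max|S_ij|`, the smallest penalty that empties the graph.
* `"entrywise"`: the scalar draw with independent uniform per-edge
  factors in `[floor, 1]` (randomized-lasso style).

The signal-anchored kinds are included for comparability with
model-averaging implementations that parameterize penalties relative to
`λ_max`, but that anchor tracks the *strongest* edge in the data: the same
ratio `r` that admits weak true edges in signal-rich data floods a null
dataset with false selections, and no single `r` does both. In simulation
at τ = .65, B = 200 the scaled default recovers planted supports
(p = 12, n = 400, |ρ| ∈ [.2, .4]) with sensitivity ≈ .86 and specificity
≈ .95–.97 while averaging **zero** spurious edges on fully independent
columns (p = 10, n = 300) — the test suite pins both.

### Numerical core

The graphical lasso itself (`src/glasso.cpp`) is block coordinate descent
on the dual with an entrywise penalty matrix: each sweep updates one
column of the working covariance `W` by solving a warm-started lasso on
`W₁₁`. The recorded objective trace is the dual objective `log det W`,
which is non-decreasing under exact block updates and is asserted in
tests; convergence is declared when the max change of `W` between sweeps
falls below `tol` (default `1e-6`, max 500 sweeps), and non-convergence is
an error carrying the duality gap `tr(SΘ) − p + Σ λ_ij|Θ_ij|`. Exact zeros
in the lasso coefficients propagate to exact zeros in Θ, so the classical
threshold property (scalar λ ≥ max|S_ij| ⇒ exactly diagonal Θ) holds to
the bit, and the p = 2 solution reproduces the soft-thresholding closed
form.

## Node measures

* **Predictability**: on standardized data, `R²_i = 1 − 1/Θ_ii`,
  identical to the nodewise-regression R² with coefficients
  `β_ij = −Θ_ij/Θ_ii`; reported ×100. **Hold-out predictability** applies
  the training β to a test split standardized *with the training
  transform* and can be negative.
* **Degree centrality**: fraction of other nodes connected,
  `deg_i/(p−1)`.
* **Current-flow (information) closeness**: absolute partial correlations
  as conductances; `(p_c − 1)/Σ_t R_eff(v,t)` per connected component via
  the Laplacian pseudoinverse.
* **Current-flow betweenness**: mean absolute throughput of unit s–t
  currents over pairs not containing the node, normalized by
  `(p_c−1)(p_c−2)/2`.
* **Shortest-path closeness/betweenness**: igraph, with edge distance
  `1/|ρ_ij|` — the standard convention for association networks.
* **Maximal spanning tree**: Prim's algorithm on `|ρ_ij|`, grown per
  component, ties broken lexicographically by node pair so results are
  platform-independent; signed weights are attached to the tree edges.

All centrality and tree computations use *absolute* weights: tree and
centrality structure is meant to reflect connection strength, while the
sign matters for interpretation and is preserved in every output. Signed
conductances would not define a valid resistor network.

## Stability suite

* **Edge bootstrap**: `B` resamples (default 1000), each re-running the
  full three-stage procedure with a reduced inner ensemble (default 100)
  for tractability; both sizes are configurable. Percentile 2.5/97.5 CIs;
  for degenerate point-mass distributions the interval is widened to
  contain the bootstrap mean. Sensitivity (reference-present edges) is the
  fraction of resamples where the edge is recovered; specificity
  (reference-absent) the fraction where it stays absent.
* **Difference tests**: paired — two bootstraps built from the same seed
  and sample size share resample indices, and the two-sided p-value is
  `2·min(P(d≤0), P(d≥0))` over paired differences, floored at `1/B`.
  Pairing makes the tests deterministic and maximally powered; unpaired
  inputs are an error. No multiple-testing correction is applied.
* **Similarity**: Pearson *r* (with its p-value) on vectorized
  upper-triangle weights, and Hamming similarity
  `1 − mismatches/compared entries` on binarized supports; row scope
  restricts both to one node's incident edges (the one-dimensional
  ERP-row comparison). Pearson on short binary-ish vectors is reported
  but should be read with caution — Hamming is the more reliable of the
  two at ~30 entries.
* **Measure stability**: case-dropping subsamples *without* replacement
  at retained fractions .9 down to .3, re-estimation, and correlation of
  node values with the full-sample values. The CS coefficient is the
  largest droppable fraction keeping correlation ≥ .7 in ≥ 95% of
  subsamples. In simulation, predictability is far more stable than
  betweenness, matching the usual ordering for psychological networks.

## The synthetic generator

The generator is the package's ground truth, built to emulate a
trait–ERP individual-differences study:

* `make_precision()`: Erdős–Rényi support at an exact edge count, edge
  partial correlations with magnitudes uniform in a requested range and
  Rademacher signs. Positive definiteness is enforced by boosting the
  diagonal until the smallest eigenvalue reaches .05, then rescaling to a
  unit-diagonal covariance; the returned truth is recomputed from the
  final matrix, so it is exact even when the boost shrank the requested
  weights.
* `make_study()` defaults: 29 traits + ERN + CRN amplitudes +
  age/handedness/performance + both component latencies (36 nodes), edge
  density .12, |ρ| ∈ [.05, .45], and an *n* = 236 training /
  *n* = 107 testing split — the sample architecture of a split-half
  replication study of error monitoring, with edge magnitudes spanning
  the weak-to-moderate range such networks report.
* `make_epochs()`: per subject, latent amplitude
  `a_i ~ N(−4, 4.5²)` µV and latency `l_i ~ N(50, 15²)` ms; each trial is
  a Gaussian-shaped peak (SD 20 ms) scaled by `a_i + N(0, 8²)` plus white
  noise, on a 256 Hz, −100…600 ms response-locked axis with 28 trials per
  subject. These defaults sit at the scale reported for error-related
  activity: mean amplitudes of a few µV, within-subject trial SDs around
  8 µV, between-subject SDs around 4–5 µV, and a few dozen usable error
  trials — the regime in which dependability hovers around .85–.90 and
  the .70 exclusion rule actually bites.

What the generator does **not** emulate: bounded/discrete questionnaire
scales (marginals are Gaussian or monotonically skewed Gaussians),
missing data, EEG artifacts and their rejection, latency jitter across
trials within a subject, and any nonlinear or interaction structure.
Passing tests therefore certify the estimator and its diagnostics under
a correctly specified sparse GGM with adequate *n* — not robustness to
ordinal data or model misspecification.

## ERP quantification

* **Mean amplitude**: per-trial mean inside the window (default
  0–100 ms), averaged over trials; trial-level scores feed variability
  and dependability.
* **Fractional-area latency**: earliest time at which the cumulative
  rectified area of the *polarity-consistent* signal reaches the fraction
  (default .5) of the window total, trapezoid rule with linear
  interpolation. Restricting rectification to the declared polarity
  (negative for ERN/CRN) keeps positive overshoot from dragging the
  latency; zero polarity-consistent area gives `NA` with a warning. The
  measure is exactly invariant to amplitude scaling.
* **Dependability**: one-way random-effects decomposition. With subject
  trial variances `v_i` and counts `n_i`,
  `σ²_b = var(subject means) − mean(v_i/n_i)` and
  `dep_i = σ²_b / (σ²_b + v_i/n_i)`, clipped to [0, 1]; a non-positive
  `σ²_b` estimate yields 0 with a warning. The generalizability-theory
  literature offers several estimators (method-of-moments vs Bayesian,
  different trial weightings); this per-subject method-of-moments form is
  fixed here for reproducibility and verified against the
  generating-variance plug-in on synthetic epochs.
* **Exclusions**: fewer than 5 trials, or dependability below .70.
  Both rules are strict inequalities, so exact boundary values (5 trials,
  dependability = .70) are *kept*.

## Normalization pipeline

Fixed order: Box-Cox per column → non-normality screen → standardize.

* Shift convention `1 − min(x)` when `min(x) ≤ 0`, so the shifted minimum
  is exactly 1 — ERP amplitudes are routinely negative and this keeps the
  λ-likelihood well behaved.
* λ maximizes the profile log-likelihood over [−5, 5]
  (`stats::optimize`, tolerance 1e-4); verified against the
  `MASS::boxcox` grid.
* The screen drops variables whose post-transform |skewness| exceeds 2 —
  a monotone power transform cannot normalize point masses, and such
  variables (e.g. heavily zero-inflated scales) violate the GGM's
  Gaussianity requirement. The threshold is a configurable stand-in for
  what is otherwise a judgment call.
* Transforms are **fit on training data only** and applied unchanged to
  the test split (centers, scales, shifts and λ all frozen). Hold-out
  values below the training shift boundary are floored at a small
  positive offset rather than erroring — on bounded questionnaire data
  this is rare; on Gaussian synthetic data it occurs occasionally and
  affects only the extreme tail of one column.

## Determinism

Every stochastic entry point takes an explicit integer seed and leaves the
global RNG untouched; ensembles and bootstraps derive per-member child
seeds below 2³¹ from it. Identical (input, config, seed) triples produce
bit-identical networks, bootstrap distributions, and study outputs.

## Problem sizes in the test suite

The suite exercises the estimator at p = 5–12 nodes with n = 300–500
subjects and ensembles of 50–200 members, bootstrap CIs at 100 resamples
× 50-member inner ensembles over 100 replicates, and large-sample oracle
checks at n = 10⁴–10⁵ — sizes chosen so every operating characteristic is
estimated with usable Monte-Carlo precision while the whole suite stays
interactive. The full-scale defaults (B = 1000 ensembles over 36-node,
236-subject tables) run in seconds and are covered by the end-to-end
study test at reduced B.

## Known limitations

* Gaussian data only; no nonparanormal or rank-based extension, no
  mixed/ordinal graphical models, no latent-variable networks.
* No EBIC or cross-validated single-λ path — stability selection *is*
  the model-selection mechanism.
* Bootstrap p-values are floored at 1/B and uncorrected for multiplicity.
* Current-flow measures assume nonnegative conductances, hence absolute
  weights; a signed generalization is out of scope.
* The proportion matrix quantifies selection stability, not edge-weight
  uncertainty; the two are reported side by side and should not be
  conflated.
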