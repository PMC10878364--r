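---
title: "Connectome-based predictive modeling: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based predictive modeling: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

CPM treats each pairwise functional connection ("edge") as a candidate
predictor of a continuous behavioral score. For a parcellation with $N$
nodes, subject $s$ contributes an edge vector
$x_s \in \mathbb{R}^{N(N-1)/2}$ of Fisher-transformed correlations
$z_{ij} = \operatorname{atanh}(r_{ij})$ between regional time courses,
and a score $y_s$. Within each cross-validation training set:

1. every edge is correlated with the score — Pearson $r_e$ with a
   two-sided $p$ from the $t$ distribution on $n-2$ degrees of freedom,
   or, under confound control, the partial correlation after
   residualizing both edge and score on the confounds (with intercept),
   on $n-2-C$ degrees of freedom;
2. edges with strictly $p < \theta$ (default $\theta = 0.01$) are split
   by the sign of $r_e$ into a positive and a negative network;
3. each training subject's network strength is the plain sum of their
   selected edge values, $S_s = \sum_{e \in \text{mask}} x_{se}$;
4. strength and score are z-scored with training mean and ($n-1$)-sd,
   an ordinary least-squares line of normalized score on normalized
   strength is fit, and a held-out subject is predicted by normalizing
   their strength with the *training* parameters and mapping the fitted
   value back through the training score mean and sd.

Performance is the Pearson correlation between out-of-fold predictions
and observed scores, or the partial correlation controlling the same
confounds, and its significance comes from a permutation test that
shuffles scores across subjects and reruns the *entire* pipeline —
selection, strength, model fit — per permutation, so selection bias is
inside the null.

The procedure assumes a monotone linear relation between summed edge
strength and score, approximately Gaussian edge values (which the
Fisher transform encourages), exchangeable subjects under the null, and
independent subjects throughout (no family structure or repeated
sessions).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `selection_p_threshold` | 0.01 | strict per-edge selection threshold; smaller values give sparser, more stable masks |
| `cv_scheme`, `k`, `kfold_repeats` | loo; 10; 100 | k-fold performance is the mean pooled-prediction $r$ over repeated random partitions |
| `n_permutations` | 1000 | permutation-test resolution; the smallest attainable $p$ is $1/(m+1)$ |
| `perm_kfold_repeats` | 10 | k-fold repetitions inside each permutation (see below) |
| `confound_names` | empty | switches selection to partial correlation and evaluation to partial $r$ |
| `fd_exclusion_threshold` | 0.3 mm | subjects with mean framewise displacement strictly above are excluded |
| `normalize_edges` | FALSE | z-score each selected edge with training parameters before summing (see below) |

## Behavioral preprocessing

The pipeline order is fixed: motion filtering, then imputation, then
the composite. Subjects whose mean FD exceeds 0.3 mm are excluded
(strictly greater; a subject at exactly the threshold is retained).
Missing subscale cells are imputed by a pluggable strategy — a
column-mean baseline and an iterative tree-ensemble default (each
incomplete column repeatedly re-predicted from the others by a random
forest until the imputed cells stabilize); observed cells are never
altered and results are deterministic given the seed. Hyperparameters
(`ntree`, `max_iter`) are exposed because no canonical values exist for
this step.

The negative-emotion composite standardizes five subscales (state
anxiety, depression, perceived stress, negative affect, loneliness),
extracts the first principal component of their **correlation** matrix
(the subscales have different ranges, so covariance PCA would let range
dominate), scales the eigenvector so each loading is the component's
correlation with its subscale, orients the loadings so their sum is
positive (eigenvectors are sign-ambiguous; the expected structure has
all-positive loadings), and sums loading-weighted z-scores per subject.
A first eigenvalue ≤ 1, or a second eigenvalue > 1, is reported as a
warning rather than an error: the eigenvalue-greater-than-one rule is
used descriptively, not enforced.

## What the synthetic generator emulates

`generate_dataset()` draws a questionnaire-like score
($\mu = 101.07$, $\sigma = 20.41$ by default), plants a designated edge
set whose values are $\beta \cdot \tilde{y} + \text{confound terms} +
\mathcal{N}(0, \sigma_e^2)$ with $\tilde{y}$ the standardized score, and
fills all other edges with pure $\mathcal{N}(0, \sigma_e^2)$ noise on
the Fisher-z scale. The planted edge-score correlation therefore
converges to $\beta/\sqrt{\beta^2 + \sigma_e^2}$ (≈ −0.33 under the
default $\beta = -0.35$, $\sigma_e = 1$). Confounds (age, sex, mean FD
with a configurable fraction exceeding 0.3 mm) and a one-factor
five-subscale emotion panel (true loadings 0.78, 0.636, 0.786, 0.818,
0.756; factor-score correlation 0.3) can leak into score and edges with
configurable loadings — zero by default, so the default spec is a clean
signal-recovery problem. Default dimensions are 300 subjects over 60
nodes (1,770 edges) with 12 planted negative edges; a 677-subject,
268-node preset reproduces the full problem scale when runtime permits.

The generator deliberately does **not** emulate several properties of
real resting-state data: spatial autocorrelation among edges, the
positive mean and heavy dependence structure of real Fisher-z values,
motion-correlated edge artifacts, or site/scanner effects. Passing
tests therefore demonstrate that the *estimator machinery* is correct
and calibrated — not that comparable effect sizes are recoverable from
real fMRI, where dependent edges make selection noisier.
`generate_timeseries()` additionally supports exercising the
time-series-to-FC stage with a known target correlation structure
(Cholesky-factor sampling; the implied correlation matrix must be
positive definite).

## Numerical and algorithmic choices

- **Per-fold correlations by group subtraction.** Leave-one-out
  selection needs the edge-score correlation over every training set.
  Recomputing per fold is $O(n^2 E)$; the engine instead centers the
  data once and subtracts each held-out group's contribution from
  global sums, giving all folds in $O(nE)$. Partial correlations come
  from the correlation-matrix Schur complement
  $r_{xy \cdot Z} = (r_{xy} - r_{xZ} R_{ZZ}^{-1} r_{Zy}) / \sqrt{(1 -
  r_{xZ} R_{ZZ}^{-1} r_{Zx})(1 - r_{yZ} R_{ZZ}^{-1} r_{Zy})}$,
  algebraically identical to residualizing; the test suite verifies
  agreement with an explicit loop-and-`lm()` reference at $10^{-10}$.
- **Thresholding without per-edge p-values.** Inside cross-validation,
  strict $p < \theta$ at fixed degrees of freedom is equivalent to
  $|r| > r_\theta$ with $r_\theta = t_\theta / \sqrt{\mathrm{df} +
  t_\theta^2}$, so one `qt()` call replaces $E$ `pt()` calls per fold.
  The user-facing `correlate_edges()` still reports exact p-values.
- **Zero-variance edges** get $r = 0$, $p = 1$ and are never selected;
  their count is reported rather than warned edge-by-edge.
- **Degenerate folds** (empty mask, or constant training strengths)
  predict the training-mean score instead of aborting, and are counted
  in the result — this keeps LOOCV defined at small $n$ where a fold
  may select nothing.
- **Permutation p-value.** The add-one estimate $(b+1)/(m+1)$ is
  reported (a raw proportion can be exactly zero, which is not a valid
  permutation $p$), with ties counted against the observed statistic;
  the raw proportion is also returned. Under confound control, only the
  scores are permuted — edges and confounds stay attached to their
  subjects, preserving the brain-confound dependence — and the partial
  $r$ is recomputed per permutation.
- **k-fold details.** The first $n \bmod k$ folds receive one extra
  subject; assignment is a seeded shuffle. With $k = n$ and one repeat
  the procedure reproduces LOOCV exactly (asserted in the suite).
  Inside each permutation the repeated k-fold procedure runs with
  `perm_kfold_repeats` (default 10) rather than the full 100
  repetitions: the permuted statistic remains exchangeable with an
  averaged observed statistic, and full fidelity is one configuration
  change away.
- **Determinism.** Every random step (partitions, permutations, the
  generator, imputation) draws from a seed passed explicitly; global
  RNG state is saved and restored. Identical inputs and seed give
  byte-identical artifacts.

## Open choices, resolved

- **Edge normalization before strength.** Normalizing edges across
  training subjects cannot change selection (correlation is
  scale-invariant), but it changes the strength sum. The default sums
  raw Fisher-z edges — the strength then has transparent units — and
  `normalize_edges = TRUE` provides the alternative reading.
- **Contributing-network weights** are the full-sample (partial)
  correlations, not per-fold averages: fold-wise weights would be
  ambiguous for edges absent from some folds' models. A config-level
  alternative is not offered because the intersection mask itself
  already encodes fold stability.
- **External prediction** uses the fold-averaged slopes, intercepts
  *and* normalization parameters; by symmetry with averaging the
  regression parameters, the validation strengths are normalized with
  the averaged training statistics. When the validation sample uses a
  different questionnaire (different scale), `normalization =
  "validation"` z-scores strengths within the validation sample
  instead; predictions stay on the discovery scale either way and only
  the scale-free correlation is the reported outcome. Scores are never
  rescaled across questionnaires — the data model carries the scale,
  and the evaluation statistic does not need harmonization.
- **The positive-network path** is fully implemented and reported
  alongside the negative network, but the external-generalization
  workflow is exercised primarily with the negative network, which is
  the scientifically motivated target in the motivating application.

## Validation problem sizes

The suite validates: exact agreement with a brute-force reference on 20
random instances ($n \le 12$, $\le 15$ edges, including
confound-controlled cases, permutation streams matched draw-for-draw);
permutation-test calibration on 200 null datasets ($n = 100$, 30 nodes,
$m = 199$), with the rejection rate at $\alpha = 0.05$ required to land
in the exact binomial 95% interval $[0.024, 0.087]$; detection power
and above-chance planted-edge recall (hypergeometric $p < 0.01$ per
run) on 50 signal datasets at the default spec with $m = 99$; the
noiseless limit ($\beta = -1$, $\sigma_e = 0$) predicting at
$r > 0.99$ internally and externally; structural identities
(mask disjointness, intersection containment, the node-strength
handshake $\sum_v s_v = 2 \sum_e |w_e|$, $N(N-1)/2$ edge counts,
$k$-fold/LOOCV equivalence); the packaged 268-node atlas fixture's
region sizes; and composite loading recovery at $n = 500$. These sizes
are the package's chosen validation conditions; the full paper-scale
preset runs the same code unchanged.

## Known limitations

Selection is univariate-filter CPM only — no regularized or
multivariate edge models (ridge, SVR), and no robust or rank-based
selection statistics. Preprocessing of raw fMRI (motion scrubbing,
nuisance regression, filtering) is upstream and out of scope; the
package consumes node time series or connectivity matrices. The
tree-ensemble imputer is a pragmatic default, not a validated missing-
data model for any particular questionnaire battery. The synthetic
atlas fixture reproduces only the published per-region node *counts*;
node-level assignments and coordinates are placeholders, so macroscale
summaries on synthetic data are structural checks, not anatomical
claims.
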