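---
title: "Minimum-volume NMF decomposition of brain images and clinical prediction from component loads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum-volume NMF decomposition of brain images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxelnmf)
```

## The problem

Neurodegenerative diseases such as progressive supranuclear palsy produce
spatially structured changes on imaging — regional grey-matter atrophy on
MRI, regional hypometabolism on FDG-PET — whose pattern varies across
patients along with the clinical picture. `voxelnmf` implements a
data-driven pipeline for relating the two: it decomposes a cohort's masked
image volumes into a small set of nonnegative spatial components, gives
every subject a load on each component, and asks how well those loads
(plus age) predict the presence and severity of individual clinical
features.

The pipeline has five computational stages, each usable on its own:

1. **Imaging I/O** — NIfTI volumes are intensity-normalized (for PET, SUVR
   by the median of an eroded white-matter reference region), masked, and
   flattened into a nonnegative subjects-by-voxels matrix.
2. **Factorization** — minimum-volume rank-deficient NMF.
3. **Rank selection** — repeated k-fold cross-validated reconstruction
   error.
4. **Clinical prediction** — elastic-net regression of each outcome on age
   and component loads, with MCC/accuracy (binary) or R²/absolute-error
   (continuous) evaluation and paired modality comparisons under FDR
   control.
5. **Coefficient maps** — back-projection of model slopes into voxel space.

## The factorization model

Given a nonnegative matrix $X \in \mathbb{R}_{\ge 0}^{n \times v}$
(subjects by masked voxels), the package solves

$$\min_{L, D \ge 0}\ \lVert X - L D\rVert_F^2
  + \lambda \log\det\!\big(D D^\top + \delta I_r\big),
  \qquad \text{s.t. } \textstyle\sum_j L_{ij} \le 1 \ \forall i,$$

with $L \in \mathbb{R}_{\ge 0}^{n \times r}$ the subject loads and
$D \in \mathbb{R}_{\ge 0}^{r \times v}$ the component dictionary.

Three modelling choices deserve comment:

* **The log-det "volume" penalty.** Plain NMF is not identifiable when the
  dictionary is rank-deficient — and heavily smoothed voxel data are very
  nearly so. Penalizing $\log\det(DD^\top + \delta I)$ shrinks the volume
  of the simplex spanned by the component rows, which restores a unique,
  parts-like solution in exactly those rank-deficient settings. The ridge
  $\delta > 0$ (default 1) keeps the penalty bounded below.
* **The capped simplex on loads.** Any NMF has a diagonal rescaling
  ambiguity ($L S^{-1}, S D$). Constraining each subject's load row to
  $\{\ell \ge 0, \sum \ell \le 1\}$ removes it, making loads comparable
  across subjects and the volume penalty meaningful. The cap (rather than
  an exact simplex) lets low-signal subjects take small total loads.
* **A scale-free penalty weight.** The user-facing `vol_weight`
  $\tilde\lambda$ (default 0.01) is converted to the absolute
  $\lambda = \tilde\lambda\,\lVert X - L_0D_0\rVert_F^2 /
  \max(1, |\log\det(D_0D_0^\top + \delta I)|)$ at the initial factors, so
  the same setting behaves comparably across datasets with different
  intensity units. The only tunable parameter of substance is the rank.

### Optimization

The fit alternates two blocks, each of which provably does not increase
the objective, so the recorded `objective_trace` is monotone (a tested
invariant, tolerance $10^{-9}$ relative):

* **Loads:** the subproblem is a convex quadratic per subject over the
  capped simplex. During iterations it is advanced by projected-gradient
  steps with the exact Lipschitz step size $1/(2\,\sigma_{\max}(DD^\top))$
  (the row-wise projection onto the capped simplex is the usual sort-based
  simplex projection). After convergence the loads are polished by an
  exact two-phase active-set solver — Lawson–Hanson NNLS first, and if the
  cap is violated, an equality-constrained active-set pass — the same
  solver `project_loads()` applies to held-out subjects. Tests verify it
  against exhaustive enumeration of active sets at small rank.
* **Dictionary:** $\log\det(DD^\top + \delta I)$ is concave in $DD^\top$,
  so its tangent at the current iterate majorizes it; the resulting convex
  quadratic surrogate
  $\operatorname{tr}(D^\top(L^\top L + \lambda G^{-1})D) - 2\operatorname{tr}(D^\top L^\top X)$
  is decreased by projected-gradient steps on the nonnegative orthant.
  Decreasing the surrogate decreases the true objective
  (majorize–minimize); a roundoff guard keeps the previous dictionary if
  accumulated floating-point error ever says otherwise. We chose this
  over the more common multiplicative updates precisely because
  monotonicity with the log-det term is then a theorem rather than a
  hope, and monotonicity is part of the package's contract.

### Initialization

`nndsvd` (default) builds deterministic factors from the nonnegative parts
of the leading singular pairs. `random` is a *seeded successive-projection*
(SPA) initialization: the first exemplar is a random high-norm subject
row, subsequent exemplars maximize the residual norm after projecting out
those already chosen. On separable data (cohorts containing nearly pure
subjects per component) SPA lands near the vertices for any seed, which is
why refits under different seeds recover the same components — a tested
identifiability property. Plain i.i.d. random factors do not have this
property and were rejected during development.

## Rank selection

For each candidate rank, subjects are split into $k$ folds (sizes within
one of each other); the NMF is fit on $k-1$ folds and the held-out fold is
projected onto the fitted dictionary; the discovery and hold-out mean
absolute reconstruction errors are recorded. The cycle repeats `repeats`
times with fresh splits, so each rank accrues $k \cdot m$ error pairs
(25 with the 5×5 default). Per-fit seeds are derived deterministically
from the scan seed and the (rank, repeat, fold) triple.

`choose_rank()` applies a **one-standard-error rule**: take the global
minimum of the mean hold-out error, compute the standard error of the
hold-out values at that rank, and return the *smallest* rank whose mean is
within one SE of the minimum. Two reasons for this exact rule: "both
errors at or near their lowest point" must become deterministic to be
software, and the hold-out curve on realistic data *flattens* rather than
rising sharply past the true rank — projecting onto a larger dictionary
never fits held-out subjects much worse — so the raw argmin drifts within
the flat region while the 1-SE rule stays at its left edge. On phantom
cohorts with a planted rank, the rule recovers the rank within ±1 across
seeds (a tested property).

## Clinical prediction

Each outcome is regressed on age plus component loads with an elastic net:
Gaussian likelihood for continuous scores, Bernoulli-logit for binary
features; predictors standardized, intercept unpenalized; regularization
strength selected by 5-fold CV (minimum mean deviance). The mixing
parameter follows the study design: **0.2** (ridge-leaning) for
single-modality models, **0.8** (lasso-leaning) for combined MRI+FDG
models, where the combined design is one age column plus both load blocks.
The fit is backed by glmnet, with a dedicated refit at the selected
strength so coefficients are converged at that point rather than
interpolated off the path. Only complete cases per outcome enter a model
(no imputation), and a binary outcome needs at least 3 subjects per class.

Evaluation uses the Matthews correlation coefficient — equal to the
Pearson correlation of truth and prediction indicators, 0 for a
coin-tossing classifier, and 0 by convention when a marginal is empty —
plus accuracy for binary outcomes; $R^2$ and an absolute-error summary for
continuous ones. Because the conventional reading of "MAE" (mean) and the
expansion "median absolute error" disagree in the tables this package
mirrors, both are implemented; the evaluation report defaults to the
median and `error_summary: mean` switches it.

Modality comparisons use a two-sided **sign-flip permutation test** on
per-subject paired errors (misclassification indicators or absolute
errors): all $2^n$ assignments are enumerated for $n \le 12$, otherwise
seeded Monte-Carlo with $(1 + \#\text{extreme})/(1 + n_\text{perm})$. The
source tables this mirrors do not name their test; a paired permutation
test makes the fewest distributional assumptions and its type-I error is
verified at the nominal 5% level in the suite. Benjamini–Hochberg
adjustment (implemented directly, tested against `p.adjust`) controls the
FDR across outcomes. The classification threshold is 0.5 on predicted
probability (none is stated upstream).

## Coefficient maps

For a fitted model, `build_coefficient_map()` computes
$\sum_j \beta_j D_{j\cdot}$ over components (age and intercept excluded)
and writes it back into 3D through the grid. Slopes on the
standardized-predictor scale are the default — component loads have
different spreads, and standardized slopes make their contributions
commensurable; `slope_scale = "original"` switches. Since loads and
weights are nonnegative, the sign of the map at a voxel is the sign of the
dominating slope: negative means more signal there lowers the predicted
probability/severity. The map is linear in the slopes (tested exactly).

## The synthetic phantom world

Because the cohort this design derives from is not publicly deposited,
every stage is exercised on phantoms with known truth:

* **Components** are sums of 3 isotropic Gaussian blobs (FWHM 4 voxels) at
  seeded random mask locations, lightly smoothed (σ = 0.8 voxels) to mimic
  the spatial covariance of 6-mm-smoothed imaging data, max-normalized,
  and resampled until pairwise correlations are below 0.6.
* **Loads** are Dirichlet-distributed directions (concentration 0.8 —
  most subjects dominated by a couple of components, as clinical
  heterogeneity suggests) scaled by a per-subject total uniform on
  [0.5, 1], so rows sit strictly inside the capped simplex.
* **Noise** is zero-truncated Gaussian (default SD 5% of mean signal),
  keeping $X \ge 0$ as tissue-probability and SUVR values are.
* **Outcomes** are linked to the true loads through linear or logistic
  links with an age covariate, mirroring the prediction model.
* The default grid is a 24³ cube with an ellipsoidal mask (~5.5k voxels);
  the test suite uses 10³–16³ versions of the same construction to stay
  fast, a pure scale-down.

What a green test establishes: the optimizer recovers planted components
and loads (matched correlation ≥ 0.9 under noise, ≥ 0.99 noiseless
separable), the CV scan finds a planted rank within ±1, and load-linked
outcomes are predictable out of sample. What it does not establish:
anything about real anatomy, disease-progression structure, scanner
effects, registration error, or the clinical scales themselves — the
phantom world has none of these.

## Numerical choices and degenerate inputs

* Convergence: relative objective change below `rel_tol` (default 1e-6),
  `max_iter` 500; rank-scan fits may use a reduced budget since rank
  discrimination does not require deep convergence.
* Active-set solves fall back to a tiny ridge (1e-10 relative) when a
  Gram submatrix is numerically singular, as happens by design in
  rank-deficient dictionaries.
* Voxel order is column-major (first axis fastest) over mask voxels,
  fixed in `masked_grid` and serialized with results, so artifacts are
  byte-reproducible.
* Values in $[-10^{-6}, 0)$ in input images are clamped to zero
  (interpolation noise); anything more negative is an error.
* Zero-variance components are flagged unmatched rather than given a
  correlation; an empty reference region or non-positive reference median
  is an error for SUVR; an all-zero subject row legitimately projects to
  zero loads.

## Limitations

* Upstream spatial normalization, segmentation, smoothing and scanner
  harmonization are out of scope; inputs must already live on a common
  grid.
* The exact objective of the factorization this package re-implements is
  documented here rather than inherited: the upstream description names
  its algorithm family but prints neither formula nor update rules, so
  this package commits to the standard log-det criterion and its own
  provably monotone updates.
* Single-process execution; the rank scan is embarrassingly parallel but
  runs serially.
* The permutation comparison assumes exchangeable paired errors under the
  null; clustered or longitudinal designs would need a different test.
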