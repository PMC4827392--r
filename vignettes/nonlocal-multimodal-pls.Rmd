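---
title: "Non-local multimodal image correlation with tractable PLSR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-local multimodal image correlation with tractable PLSR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nonlocalpls)
```

## The problem

Structural and metabolic brain images carry correlated information about
neurodegeneration, but the coupling is not necessarily spatially local:
tissue loss in one set of regions can go with reduced metabolic uptake in
quite different regions. A model restricted to voxel-to-voxel or
patch-to-patch correspondence cannot express such a relationship, however
much training data it sees. This package models the *global* cross-modality
covariance of subject-by-voxel matrices with partial least squares
regression (PLSR), and provides the local patch-synthesis model as the
natural comparator.

## The model

Let `X` (subjects x voxels, predictor modality) and `Y` (subjects x voxels,
predicted modality) be column-centered. PLS extracts paired unit-norm
weight maps `(w_i, c_i)` maximising the covariance of the projections
`t_i = X w_i` and `u_i = Y c_i`; `(w_i, c_i)` is the leading singular pair
of the cross-covariance `X'Y`. A scalar inner model `u_i ~ b_i t_i` with
`b_i = t_i'u_i / t_i't_i` links the two blocks, and after each extraction
both blocks are deflated on the x-score:

```
p_i = X't_i / t_i't_i     q_i = Y't_i / t_i't_i
X <- X - t_i p_i'         Y <- Y - t_i q_i'
```

Prediction for a new predictor image uses the factored operator
`T_new = X_new W (P'W)^{-1}`, `Y_hat = T_new diag(b) C'`, un-centered with
the stored training means.

Two design choices deserve comment, because the literature knows several
PLS2 variants:

- **Deflation.** Both blocks are deflated on the x-score `t` (regression
  deflation). This guarantees mutually orthogonal x-scores and makes the
  factored operator exact on training data. Deflating `Y` by the full
  loading `t q'` or by the rank-reduced `b t c'` yields identical
  subsequent components — the difference is a rank-one term with left
  factor `t`, annihilated by the already-deflated `X'` — so the choice is
  immaterial; the full loading is used.
- **Prediction.** `Y_hat = T diag(b) C'` projects each score's
  contribution onto the unit y-weight `c_i` (the convention in which the
  y-weights are normalised and a scalar inner coefficient is estimated).
  Implementations that instead predict with the full y-loadings `q_i`
  reconstruct the projection of `Y` onto the score space; the two differ
  on finite component counts. The tests pin the implemented convention
  against an independently coded textbook NIPALS PLS2 with normalised
  y-weights.

### Tractability

`X'Y` is voxels-by-voxels and can never be materialised at imaging scale.
All decompositions run in subjects space: with Gram matrices `Gx = XX'`
and `Gy = YY'` (`K x K`), the leading x-score is the principal eigenvector
of `Gx Gy`, computed from the symmetric PSD form `Gx^{1/2} Gy Gx^{1/2}`
for numerical robustness (the nonsymmetric product can mislead a general
eigen-solver when eigenvalues cluster). Weights follow by back-projection
and normalisation, with the sign fixed so the largest-|entry| of `w` is
positive, applied to `(w, c, t, u)` jointly. Peak additional memory is
`O(K^2 + KN + mN)`; an allocation audit in the test suite verifies that
fitting at `N = 10^4` never allocates anything within a factor four of an
`N x N` array. Component extraction stops early, with a warning, when a
residual block's Frobenius norm falls below `1e-12` of its initial value.

The PCR comparator runs the same way (PCA of `X` via `Gx`, then
least-squares of `Y` on the PC scores). PCR picks directions of maximal
X-variance whether or not they predict `Y`; planting a high-variance
X-only distractor in the phantom makes the difference visible at `m = 1`.

## The local comparator

The patch model predicts each voxel of the target modality by finding,
among the aligned atlas pairs, the x-patch most similar (L2) to the
query's x-patch around that voxel, and copying the winning atlas's
y-intensity at the matched centre. Defaults: cubic patches of side 5
(the common convention in the patch-synthesis literature; "radius" and
"voxel count" readings are not used), search restricted to the same voxel
location across atlases (`search_radius = 0`, configurable), single best
patch (no multi-atlas aggregation), centre-voxel lookup with a documented
patch-mean variant, boundary windows clamped to the grid. Ties break to
the lowest atlas index, then lexicographic offset, making the output
deterministic. The search is exhaustive (no approximate indexing) and
implemented in C++; a leave-one-out wrapper excludes each query subject
from its own database.

## The phantom generator

Real multimodal cohorts of the necessary size are access-restricted, so
validation uses synthetic cohorts with planted truth. Subject `k`'s images
are

```
X_k = sum_j s_kj wx_j + c_k v + e_x,   Y_k = sum_j s_kj wy_j + c_k v + e_y
```

with unit-norm Gaussian-blob maps `wx_j, wy_j` (smoothed at a standardised
resolution, FWHM-to-sigma `fwhm / 2.3548`, smoothing before
normalisation), shared loadings `s_kj ~ N(group mean, loading_sd)`, a
central ventricle-like confound `v` with subject strength
`c_k ~ amplitude * N(1, 0.3)` appearing in both modalities, and additive
noise. The x- and y-centres of a component are free, so the planted
correlation can be made non-local (disjoint supports, the default) or
purely local (coincident supports) — the two regimes behind the headline
comparison. Analysis is restricted to a spherical "brain" mask (radius 7.5
voxels in the default 16^3 grid).

Defaults mirror the study design at toy scale: 3 components, 3 groups
(HC/MCI/AD analogues), 80 subjects per group, `loading_sd = 1`,
`noise_sd = 0.2`. Two generator choices are correctness requirements
rather than tuning:

- **Orthogonal group-mean contrasts.** The mean-loading profiles of
  different components across groups are orthogonal contrasts (a linear
  disease-severity axis on component 1, an MCI-specific quadratic contrast
  on component 2, none on component 3, scaled so total variances are well
  separated). If the profiles were correlated across components, the
  loading covariance would be non-diagonal and the planted maps would
  *not* be the singular directions of the cross-covariance — the phantom
  would pose an unrecoverable target even at zero noise (mixing is visible
  analytically and numerically). Distinct total variances likewise keep
  the singular values separated so individual components are identifiable,
  not just their span.
- **Resolution-filtered noise.** By default the white noise field
  (`sd = noise_sd`) passes through the same Gaussian resolution filter as
  the signal. Images standardised to a given smoothness have spatially
  correlated noise; independent per-voxel noise of equal amplitude is a
  much harsher and physically implausible regime in which unit-norm smooth
  maps drown at realistic amplitude ratios. `noise_smoothing = FALSE`
  restores the independent-noise model for sensitivity checks.

What the phantom does *not* emulate: registration error, scanner field
strength effects, count statistics of emission tomography, intensity
normalisation artefacts, or anatomically realistic region shapes. Passing
tests therefore demonstrate correctness of the pipeline under the planted
statistical structure, not performance on real cohorts.

## Centering and conventions

Both modalities are column-mean centered before fitting (required for
covariance maximisation to be meaningful); no per-voxel variance scaling
is applied, since voxel units are commensurate within a modality. Whether
variance standardisation would change results on real data is left to
sensitivity analysis. Predictions are returned in original units.
Re-centering a centered dataset errors. Voxel coordinates are 0-based and
arrays flatten in R's native column-major order (first axis fastest) —
one convention, used and asserted everywhere.

## Discriminability and reproducibility

Group separation is assessed on the *x-side* latent scores of held-out
subjects (`project_scores`): at prediction time only the predictor
modality is available, so its scores are the natural feature space; the
y-side alternative is one projection away. Pairwise two-class Fisher LDA
(pooled within-class covariance, diagonal ridge `1e-6`) is fit with
features standardised first, so weight magnitudes are comparable and
ranking components by |weight| is meaningful. Each subject's discriminant
value comes from a fit excluding that subject, and the AUC of the pooled
held-out values uses the rank (Mann-Whitney) formulation with midranks.

Component identity across repeats uses the concatenated (x-map, y-map)
vector — both modalities' patterns must co-reproduce, the stricter
criterion. Matching is greedy on |Pearson r| above 0.5 (strongest first,
each component used at most once); reproducibility counts how often a
reference-repeat component is matched *and* ranked in the other repeat's
top-5. Network extraction binarises |map| at a quantile (default 0.95),
applies a ball-structuring-element opening (default radius 1) and labels
6-connected clusters, recording each cluster's sign to separate correlated
from anticorrelated hubs; threshold and radius are exposed because no
principled default exists.

## Problem sizes and numerical tolerances

The shipped experiments run at 16^3 grids with 60-240 training subjects
and 6-10 components — small enough for a laptop, large enough that every
qualitative contrast of interest (non-local vs local, PLSR vs PCR,
reproducible vs noise components) is decisively visible. Exact-equivalence
tests (subjects-space solution vs dense SVD, factored vs dense operator,
patch search vs exhaustive search) use tolerances `1e-6`-`1e-9` on
problems small enough for the dense oracle. Degenerate inputs are handled
explicitly: all-zero blocks, zero-norm scores, singular `P'W` (condition
number reported), zero-variance correlation inputs, zero pooled SDs and
constant paired differences all error or flag rather than silently
propagate NaN.

## Limitations

- The linear latent model cannot represent nonlinear intensity
  relationships; the patch baseline can, which is part of why it remains
  the right comparator on local structure.
- LDA weights on standardised scores rank components by linear separation
  only.
- Greedy matching is order-dependent in pathological near-tie
  configurations; the tests pin its behaviour against exhaustive
  enumeration on such cases.
- The phantom's group effects are planted on loadings of fixed spatial
  maps; spatially varying group effects (shape differences) are out of
  scope.
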