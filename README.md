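# nonlocalpls

Joint analysis of two co-registered brain image modalities — typically a
structural grey-matter map (predictor, `X`) and a metabolic uptake map
(predicted, `Y`) — under the hypothesis that their correlation is
**non-local**: disease-related atrophy in one set of regions can be coupled
to hypometabolism in completely different regions, which voxel-wise or
patch-wise (local) models cannot represent by construction.

The core of the package is a computationally tractable **partial least
squares regression (PLSR)** for subject-by-voxel matrices. With `K` subjects
and `N` voxels (`K` in the hundreds, `N` in the thousands to millions), PLS
components are the singular pairs of the `N x N` cross-covariance
`X'Y`, which is far too large to materialise. The package instead solves the
equivalent `K x K` subjects-space eigen-problem: the leading x-score `t` is
the principal eigenvector of `(XX')(YY')` (solved in the symmetric form
`Gx^(1/2) Gy Gx^(1/2)`), from which the weight maps follow by
back-projection:

```
c = Y't / |Y't|,   w = X'(Yc) / |X'(Yc)|,   t = Xw,   u = Yc
```

Components are extracted iteratively with deflation of both blocks on the
x-score (`p = X't/t't`, `q = Y't/t't`, `X <- X - tp'`, `Y <- Y - tq'`), a
scalar inner model `b_i = t'u / t't` links the score pairs, and prediction
uses the factored regression operator

```
T_new = X_new W (P'W)^-1 ,   Y_hat = T_new diag(b) C'
```

so no voxels-by-voxels matrix is ever formed. Around this core the package
provides:

- a **patch-based local synthesis baseline** (nearest 5x5x5 patch in an
  atlas database under the L2 metric, Rcpp-accelerated, with a
  leave-one-out variant) — the state-of-practice local comparator;
- a **principal component regression** comparator sharing the prediction
  interface;
- **evaluation**: per-group absolute-error maps, regional means under a
  label atlas, correlation with reference regional values (Fisher-z CI),
  pooled-SD effect sizes, paired t-tests;
- **discriminability and reproducibility**: leave-one-out Fisher LDA on the
  latent scores with rank-based AUC, ranking of components by |LDA weight|,
  greedy cross-repeat matching of component maps at |r| > 0.5, and
  reproducibility counts;
- **network extraction** from component maps (quantile thresholding,
  morphological opening, 6-connected cluster labelling with signs);
- a **synthetic phantom generator** planting known non-local (or local)
  multimodal correlation structure, group effects, a ventricle-like
  confound and a region atlas, so that every stage of the pipeline can be
  validated against ground truth.

## Worked example

Fit the model on the default phantom cohort (240 subjects, three planted
components whose x- and y-supports are disjoint) and check recovery:

```r
library(nonlocalpls)

cohort <- sample_cohort(phantom_spec(seed = 1234L))
fit <- fit_pls(center_dataset(cohort$dataset), 6)

# best |cosine| between each planted y-map and the estimated y-weights
apply(abs(crossprod(cohort$truth$components_y, fit$C)), 1, max)
#> 0.9985 0.9978 0.9980

# match truth to estimate on concatenated (x, y) maps at |r| > 0.5
match_components(rbind(cohort$truth$components_x, cohort$truth$components_y),
                 rbind(fit$W, fit$C))$pairs
#>   comp_i comp_j correlation
#> 1      1      1   0.9989
#> 2      2      2   0.9975
#> 3      3      3   0.9974
```

All three planted non-local components are recovered nearly perfectly. The
numbered scripts under `analysis/` walk through the full study: cohort
simulation, PLSR fit, patch baseline, repeated cross-validated model
comparison, and component discriminability/reproducibility. On the
non-local phantom the cross-validated regional mean absolute error is about
0.021 for PLSR against 0.16 for the patch baseline (paired t-test p < 1e-30
in every repeat); when the phantom is rebuilt with coincident (purely
local) supports the gap collapses to under 0.01 — the local baseline is
only competitive when the planted correlation actually is local.

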