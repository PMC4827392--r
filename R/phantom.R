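#' Specification for a synthetic multimodal phantom cohort
#'
#' Defines a cohort of paired 3D volumes (a "structural" predictor modality X
#' and a "metabolic" predicted modality Y) driven by a small number of planted
#' latent components. Each component is a smooth Gaussian blob in each
#' modality; the two blobs of a component may be centred at completely
#' different locations, planting a *non-overlapping* (non-local) correlation
#' between the modalities. One shared subject loading per component drives
#' both modalities, which is exactly the structure a cross-covariance latent
#' model assumes. A ventricle-like confound blob common to both modalities
#' and additive voxel noise complete the generative model.
#'
#' Group mean loadings are given as a groups-by-components matrix whose rows
#' name the clinical-analogue groups. The default plants three components in
#' three groups (HC/MCI/AD analogues): component 1 carries a linear disease
#' severity contrast, component 2 an MCI-specific contrast, component 3 pure
#' within-group variability. The mean profiles of different components are
#' orthogonal across groups, so the loading covariance stays diagonal and the
#' planted maps are genuinely the singular directions of the cross-covariance
#' (a requirement for using the phantom as a recovery ground truth, not a
#' tuning choice).
#'
#' By default the additive noise field is passed through the same Gaussian
#' resolution filter as the signal (`noise_smoothing = TRUE`): volumes at a
#' standardised smoothness have spatially correlated noise, not white noise.
#' Set `noise_smoothing = FALSE` for independent per-voxel noise.
#'
#' @param grid_shape Integer triple, voxels per axis (all entries >= 4).
#' @param n_components Number of planted latent components.
#' @param component_centers_x,component_centers_y Per-component blob centres,
#'   a `n_components` x 3 matrix of 0-based voxel coordinates for each
#'   modality. Centres may be disjoint across modalities.
#' @param blob_sigma Spatial Gaussian width of component blobs (voxels).
#' @param smoothing_fwhm Post-hoc smoothing width (voxels, FWHM), emulating a
#'   standardised image resolution. Converted with [fwhm_to_sigma()].
#' @param group_means Groups x components matrix of mean loadings; row names
#'   are the group labels.
#' @param loading_sd Within-group loading standard deviation (> 0).
#' @param noise_sd Additive voxel noise standard deviation (>= 0), the
#'   amplitude of the white noise field before resolution filtering.
#' @param noise_smoothing Filter the noise field at `smoothing_fwhm`
#'   (default `TRUE`); `FALSE` gives independent per-voxel noise.
#' @param confound_amplitude Strength of the shared central "ventricle"
#'   region signal appearing in both modalities.
#' @param subjects_per_group Integer vector of per-group subject counts, in
#'   the order of `group_means` rows.
#' @param mask_radius Radius (voxels) of the spherical "brain" analysis mask
#'   centred in the grid; `Inf` keeps the full grid.
#' @param distractor Optional list `(center, sigma, sd)` planting an extra
#'   high-variance component in the X modality only, with loadings
#'   uncorrelated to Y -- useful to contrast covariance-driven and
#'   variance-driven decompositions.
#' @param seed RNG seed used by [sample_cohort()].
#' @return An object of class `phantom_spec`.
#' @seealso [make_components()], [sample_cohort()], [make_region_atlas()]
#' @export
phantom_spec <- function(grid_shape = c(16L, 16L, 16L),
                         n_components = 3L,
                         component_centers_x = rbind(c(4, 4, 4),
                                                     c(11, 4, 8),
                                                     c(4, 11, 11)),
                         component_centers_y = rbind(c(11, 11, 4),
                                                     c(4, 8, 11),
                                                     c(11, 11, 11)),
                         blob_sigma = 1.5,
                         smoothing_fwhm = 3,
                         group_means = rbind(HC  = c(3.0,  0.8, 0),
                                             MCI = c(0.0, -1.6, 0),
                                             AD  = c(-3.0, 0.8, 0)),
                         loading_sd = 1,
                         noise_sd = 0.2,
                         noise_smoothing = TRUE,
                         confound_amplitude = 0.5,
                         subjects_per_group = c(80L, 80L, 80L),
                         mask_radius = 7.5,
                         distractor = NULL,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  n_components <- as.integer(n_components)
  component_centers_x <- rbind(component_centers_x)[seq_len(n_components), , drop = FALSE]
  component_centers_y <- rbind(component_centers_y)[seq_len(n_components), , drop = FALSE]
  group_means <- as.matrix(group_means)[, seq_len(n_components), drop = FALSE]
  if (is.null(rownames(group_means)))
    rownames(group_means) <- paste0("G", seq_len(nrow(group_means)))

  spec <- structure(list(
    grid_shape = grid_shape,
    n_components = n_components,
    component_centers_x = component_centers_x,
    component_centers_y = component_centers_y,
    blob_sigma = blob_sigma,
    smoothing_fwhm = smoothing_fwhm,
    group_means = group_means,
    loading_sd = loading_sd,
    noise_sd = noise_sd,
    noise_smoothing = isTRUE(noise_smoothing),
    confound_amplitude = confound_amplitude,
    subjects_per_group = as.integer(subjects_per_group),
    mask_radius = mask_radius,
    distractor = distractor,
    seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(grid_shape) != 3L || any(grid_shape < 4L))
      stop("grid_shape must be an integer triple with entries >= 4")
    if (n_components < 1L) stop("n_components must be >= 1")
    if (loading_sd <= 0) stop("loading_sd must be > 0")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    for (cm in list(component_centers_x, component_centers_y)) {
      if (nrow(cm) != n_components || ncol(cm) != 3L)
        stop("component centers must be an n_components x 3 matrix")
      bad <- which(cm < 0 | cm > matrix(grid_shape - 1L, nrow(cm), 3L, byrow = TRUE))
      if (length(bad))
        stop("component center outside the grid: row ",
             paste(unique((bad - 1L) %% nrow(cm) + 1L), collapse = ", "))
    }
    if (ncol(group_means) != n_components)
      stop("group_means must have one column per component")
    if (length(subjects_per_group) != nrow(group_means))
      stop("subjects_per_group must match the rows of group_means")
    if (any(subjects_per_group < 1L)) stop("subjects_per_group entries must be >= 1")
  })
  invisible(spec)
}

#' Analysis mask of a phantom
#'
#' Spherical "brain" mask centred in the grid, or the full grid when
#' `mask_radius` is infinite.
#'
#' @param spec A [phantom_spec()].
#' @return Logical 3D array.
#' @export
phantom_mask <- function(spec) {
  d <- spec$grid_shape
  if (!is.finite(spec$mask_radius)) return(array(TRUE, d))
  ctr <- (d - 1) / 2
  g <- voxel_grid(d)
  r2 <- (g[, 1] - ctr[1])^2 + (g[, 2] - ctr[2])^2 + (g[, 3] - ctr[3])^2
  array(r2 <= spec$mask_radius^2, d)
}

# Isotropic Gaussian blob (peak 1) over the full grid, as a 3D array.
gaussian_blob <- function(center, sigma, grid_shape) {
  g <- voxel_grid(grid_shape)
  v <- exp(-((g[, 1] - center[1])^2 + (g[, 2] - center[2])^2 +
               (g[, 3] - center[3])^2) / (2 * sigma^2))
  array(v, grid_shape)
}

component_map <- function(center, spec, mask) {
  b <- gaussian_blob(center, spec$blob_sigma, spec$grid_shape)
  b <- smooth_volume(b, fwhm_to_sigma(spec$smoothing_fwhm))
  unit_norm(flatten_volume(b, mask))
}

#' Planted spatial component maps of a phantom
#'
#' One Gaussian-blob map per component and per modality, smoothed at the
#' phantom's standardised resolution and normalised to unit Euclidean norm
#' over the analysis mask. The X- and Y-modality maps of a component are
#' centred at the locations given in the spec, so their spatial overlap is
#' fully controlled (disjoint centres plant a non-local correlation).
#'
#' @param spec A [phantom_spec()].
#' @return List with `components_x` and `components_y`, each a
#'   masked-voxels x n_components matrix with unit-norm columns.
#' @export
make_components <- function(spec) {
  validate_phantom_spec(spec)
  mask <- phantom_mask(spec)
  cx <- vapply(seq_len(spec$n_components),
               function(j) component_map(spec$component_centers_x[j, ], spec, mask),
               numeric(sum(mask)))
  cy <- vapply(seq_len(spec$n_components),
               function(j) component_map(spec$component_centers_y[j, ], spec, mask),
               numeric(sum(mask)))
  list(components_x = cbind(cx), components_y = cbind(cy))
}

confound_map <- function(spec, mask) {
  ctr <- (spec$grid_shape - 1) / 2
  b <- gaussian_blob(ctr, 2 * spec$blob_sigma, spec$grid_shape)
  b <- smooth_volume(b, fwhm_to_sigma(spec$smoothing_fwhm))
  unit_norm(flatten_volume(b, mask))
}

noise_field <- function(spec, mask) {
  v <- array(rnorm(prod(spec$grid_shape), 0, spec$noise_sd), spec$grid_shape)
  if (spec$noise_smoothing)
    v <- smooth_volume(v, fwhm_to_sigma(spec$smoothing_fwhm))
  flatten_volume(v, mask)
}

#' Draw a synthetic multimodal cohort with known ground truth
#'
#' Subject k's images are `X_k = sum_j s_kj * wx_j + c_k * v + e_x` and
#' `Y_k = sum_j s_kj * wy_j + c_k * v + e_y`, where the `wx_j`/`wy_j` are the
#' planted unit-norm maps of [make_components()], the shared loadings
#' `s_kj ~ Normal(group_mean, loading_sd)`, `v` is the ventricle-like
#' confound map with subject strength `c_k`, and `e` is the additive noise
#' field. All randomness is driven by `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return List with `dataset` (a [multimodal_dataset()]) and `truth`
#'   (class `phantom_truth`: planted maps, loadings, group labels, region
#'   atlas, confound strengths and the spec).
#' @export
sample_cohort <- function(spec) {
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  mask <- phantom_mask(spec)
  comps <- make_components(spec)
  conf <- confound_map(spec, mask)

  groups <- rownames(spec$group_means)
  n_per <- spec$subjects_per_group
  K <- sum(n_per)
  group_labels <- factor(rep(groups, times = n_per), levels = groups)
  subject_ids <- sprintf("sub-%03d", seq_len(K))

  mu <- spec$group_means[as.integer(group_labels), , drop = FALSE]
  loadings <- mu + matrix(rnorm(K * spec$n_components, 0, spec$loading_sd),
                          K, spec$n_components)
  conf_strength <- if (spec$confound_amplitude > 0)
    spec$confound_amplitude * rnorm(K, mean = 1, sd = 0.3) else numeric(K)

  signal_x <- loadings %*% t(comps$components_x)
  signal_y <- loadings %*% t(comps$components_y)
  if (spec$confound_amplitude > 0) {
    signal_x <- signal_x + outer(conf_strength, conf)
    signal_y <- signal_y + outer(conf_strength, conf)
  }

  distractor_loadings <- NULL
  if (!is.null(spec$distractor)) {
    dmap <- component_map(spec$distractor$center, spec, mask)
    distractor_loadings <- rnorm(K, 0, spec$distractor$sd)
    signal_x <- signal_x + outer(distractor_loadings, dmap)
  }

  X <- signal_x
  Y <- signal_y
  if (spec$noise_sd > 0) {
    for (k in seq_len(K)) X[k, ] <- X[k, ] + noise_field(spec, mask)
    for (k in seq_len(K)) Y[k, ] <- Y[k, ] + noise_field(spec, mask)
  }

  dataset <- multimodal_dataset(X, Y, subject_ids, group_labels, mask,
                                spec$grid_shape)
  truth <- structure(list(
    components_x = comps$components_x,
    components_y = comps$components_y,
    loadings = loadings,
    group_labels = group_labels,
    atlas = make_region_atlas(spec),
    confound = conf_strength,
    distractor_loadings = distractor_loadings,
    spec = spec
  ), class = "phantom_truth")
  list(dataset = dataset, truth = truth)
}

#' Region-label atlas over the planted Y-modality component supports
#'
#' Integer label volume with one region per planted component, obtained by
#' thresholding the (unsmoothed) Y-modality blob of each component at
#' `exp(-2)` of its peak (a 2-sigma ellipsoid), intersected with the analysis
#' mask. Voxels claimed by several regions are assigned to the nearest
#' centre. Label 0 is background. A sidecar table of labels and centres is
#' attached as attribute `"regions"`.
#'
#' @param spec A [phantom_spec()].
#' @return Integer 3D array of region labels.
#' @export
make_region_atlas <- function(spec) {
  validate_phantom_spec(spec)
  mask <- phantom_mask(spec)
  d <- spec$grid_shape
  g <- voxel_grid(d)
  atlas <- array(0L, d)
  bestd2 <- array(Inf, d)
  for (j in seq_len(spec$n_components)) {
    ctr <- spec$component_centers_y[j, ]
    d2 <- (g[, 1] - ctr[1])^2 + (g[, 2] - ctr[2])^2 + (g[, 3] - ctr[3])^2
    inside <- array(d2 <= 4 * spec$blob_sigma^2, d) & mask
    claim <- inside & (array(d2, d) < bestd2)
    atlas[claim] <- j
    bestd2[claim] <- d2[claim]
  }
  attr(atlas, "regions") <- data.frame(
    label = seq_len(spec$n_components),
    center_x = spec$component_centers_y[, 1],
    center_y = spec$component_centers_y[, 2],
    center_z = spec$component_centers_y[, 3]
  )
  atlas
}
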