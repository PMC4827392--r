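#' Per-group mean absolute error maps
#'
#' Voxel-wise mean of `|Y_hat - Y|` within each group.
#'
#' @param Y_hat,Y Aligned prediction and observation matrices
#'   (subjects x masked voxels).
#' @param group_labels Per-subject group labels.
#' @return Named list of mean absolute error vectors, one per group level.
#' @export
absolute_error_map <- function(Y_hat, Y, group_labels) {
  Y_hat <- rbind(Y_hat); Y <- rbind(Y)
  if (!all(dim(Y_hat) == dim(Y)))
    stop("Y_hat and Y must have identical dimensions")
  group_labels <- as.factor(group_labels)
  if (length(group_labels) != nrow(Y))
    stop("group_labels must match the rows of Y")
  err <- abs(Y_hat - Y)
  lapply(stats::setNames(nm = levels(group_labels)), function(g)
    colMeans(err[group_labels == g, , drop = FALSE]))
}

#' Per-region mean values under a label atlas
#'
#' Arithmetic mean of the masked voxels of each region label, for one image
#' or a whole cohort.
#'
#' @param values Masked-voxel vector, or subjects x masked-voxels matrix.
#' @param atlas Integer 3D label array aligned to the data grid (0 =
#'   background).
#' @param mask Logical 3D array selecting the columns of `values`.
#' @param regions Region labels to summarise; defaults to all positive
#'   labels present in the atlas.
#' @return Subjects x regions matrix of means (column names are the labels).
#' @export
regional_means <- function(values, atlas, mask, regions = NULL) {
  values <- rbind(values)
  alab <- as.vector(atlas)[as.vector(mask)]
  if (length(alab) != ncol(values))
    stop("atlas/mask geometry does not match the data columns")
  present <- sort(unique(alab[alab > 0]))
  if (is.null(regions)) regions <- present
  missing <- setdiff(regions, present)
  if (length(missing))
    stop("region label(s) absent from atlas: ", paste(missing, collapse = ", "))
  out <- vapply(regions, function(r)
    rowMeans(values[, alab == r, drop = FALSE]), numeric(nrow(values)))
  out <- matrix(out, nrow = nrow(values),
                dimnames = list(NULL, paste0("region_", regions)))
  out
}

#' Pearson correlation with a reference, with Fisher-z confidence interval
#'
#' @param predicted,reference Paired finite numeric vectors, `n >= 4`.
#' @param conf_level Confidence level for the Fisher z-transform interval.
#' @return List with `r`, `ci` (length-2 vector), and `n`.
#' @export
correlation_with_reference <- function(predicted, reference,
                                       conf_level = 0.95) {
  if (length(predicted) != length(reference))
    stop("predicted and reference must have equal length")
  n <- length(predicted)
  if (n < 4L) stop("need at least 4 paired values")
  if (!all(is.finite(predicted)) || !all(is.finite(reference)))
    stop("inputs must be finite")
  if (sd(predicted) == 0 || sd(reference) == 0)
    stop("zero-variance input: correlation undefined")
  r <- cor(predicted, reference)
  if (abs(r) >= 1) {
    ci <- c(r, r)
  } else {
    z <- atanh(r)
    hw <- qnorm(1 - (1 - conf_level) / 2) / sqrt(n - 3)
    ci <- tanh(c(z - hw, z + hw))
  }
  list(r = r, ci = ci, n = n)
}

#' Cohen's d effect size with pooled standard deviation
#'
#' Standardised mean difference `(mean(A) - mean(B)) / s_pooled` with the
#' pooled (n-1 weighted) standard deviation. The sign convention is A minus
#' B.
#'
#' @param values_a,values_b Numeric vectors, each with at least 2 values.
#' @return Cohen's d.
#' @export
effect_size <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
  sp2 <- ((na - 1) * var(values_a) + (nb - 1) * var(values_b)) / (na + nb - 2)
  if (sp2 == 0) stop("zero pooled standard deviation: effect size undefined")
  (mean(values_a) - mean(values_b)) / sqrt(sp2)
}

#' Paired t-test on per-subject errors of two methods
#'
#' Two-sided paired t-test on per-subject (regional) absolute errors. When
#' the paired differences have zero variance the statistic is undefined;
#' this degenerate case is reported as a no-difference outcome with an
#' explicit flag rather than an error.
#'
#' @param errors_a,errors_b Paired numeric vectors (same subjects).
#' @return List with `statistic`, `p`, `df`, `mean_diff` and `degenerate`.
#' @export
paired_error_test <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b))
    stop("paired vectors must have equal length")
  n <- length(errors_a)
  if (n < 2L) stop("need at least 2 pairs")
  d <- errors_a - errors_b
  if (sd(d) == 0) {
    return(list(statistic = NA_real_, p = if (all(d == 0)) 1 else NA_real_,
                df = n - 1L, mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- t.test(errors_a, errors_b, paired = TRUE)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d), degenerate = FALSE)
}

#' Regional prediction report for one method
#'
#' Convenience wrapper combining [regional_means()] and per-subject regional
#' absolute errors, the building blocks of the model-comparison tables.
#'
#' @param Y_hat,Y Prediction and observation matrices
#'   (subjects x masked voxels).
#' @param atlas,mask Region atlas and analysis mask.
#' @return List with `predicted`, `observed` (subjects x regions means) and
#'   `abs_error` (subjects x regions mean absolute error), plus
#'   `mean_abs_error` (per-subject mean over regions).
#' @export
regional_report <- function(Y_hat, Y, atlas, mask) {
  pred <- regional_means(Y_hat, atlas, mask)
  obs <- regional_means(Y, atlas, mask)
  abse <- regional_means(abs(rbind(Y_hat) - rbind(Y)), atlas, mask)
  list(predicted = pred, observed = obs, abs_error = abse,
       mean_abs_error = rowMeans(abse))
}
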