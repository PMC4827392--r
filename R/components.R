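#' Mann-Whitney AUC from scores and binary labels
#'
#' Area under the ROC curve computed by the rank (Mann-Whitney) formulation
#' with midranks for ties, i.e. the proportion of positive/negative pairs
#' ranked concordantly, counting ties as 1/2.
#'
#' @param scores Numeric vector of discriminant values.
#' @param positive Logical vector, `TRUE` for the positive class.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Fisher two-class LDA direction on standardized features:
# w = (Sw_pooled + ridge I)^-1 (mu_pos - mu_neg), with per-feature
# standardization baked in so weight magnitudes are comparable.
fisher_lda_direction <- function(Z, positive, ridge = 1e-6) {
  Zp <- Z[positive, , drop = FALSE]
  Zn <- Z[!positive, , drop = FALSE]
  if (nrow(Zp) < 2L || nrow(Zn) < 2L)
    stop("each class needs at least 2 subjects")
  Sp <- stats::cov(Zp); Sn <- stats::cov(Zn)
  Sw <- ((nrow(Zp) - 1) * Sp + (nrow(Zn) - 1) * Sn) / (nrow(Z) - 2)
  Swr <- Sw + diag(ridge, ncol(Z))
  w <- tryCatch(solve(Swr, colMeans(Zp) - colMeans(Zn)),
                error = function(e)
                  stop("pooled within-class covariance is singular beyond ",
                       "ridge rescue: ", conditionMessage(e)))
  as.vector(w)
}

#' Leave-one-out LDA discriminability of latent scores
#'
#' Two-class Fisher LDA (pooled within-class covariance with a `1e-6`
#' diagonal ridge) on per-subject latent scores, for one ordered label
#' pair. Features are standardized before fitting so weight magnitudes are
#' comparable across components. Each subject's discriminant value comes
#' from a model fit *excluding* that subject; the AUC is computed from the
#' pooled held-out values by the rank (Mann-Whitney) formulation. The
#' reported weights come from the fit on all subjects; the first label of
#' `label_pair` is the positive class.
#'
#' @param scores Subjects x m latent score matrix.
#' @param labels Per-subject labels.
#' @param label_pair Character vector of two labels, positive class first.
#' @param ridge Diagonal ridge added to the pooled covariance.
#' @return An object of class `discriminability_result`: `comparison`,
#'   `lda_weights`, `loo_scores`, `auc`, `top_components`.
#' @export
lda_loo_auc <- function(scores, labels, label_pair, ridge = 1e-6) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  stopifnot(length(label_pair) == 2L)
  keep <- labels %in% label_pair
  if (sum(labels == label_pair[1]) < 2L || sum(labels == label_pair[2]) < 2L)
    stop("both labels of the pair need at least 2 subjects")
  Z <- scores[keep, , drop = FALSE]
  pos <- labels[keep] == label_pair[1]
  mu <- colMeans(Z); sdz <- apply(Z, 2L, sd)
  sdz[sdz == 0] <- 1
  Z <- sweep(sweep(Z, 2L, mu), 2L, sdz, `/`)
  n <- nrow(Z)
  w_all <- fisher_lda_direction(Z, pos, ridge)
  loo <- vapply(seq_len(n), function(i) {
    w_i <- fisher_lda_direction(Z[-i, , drop = FALSE], pos[-i], ridge)
    sum(Z[i, ] * w_i)
  }, numeric(1))
  res <- structure(list(comparison = label_pair,
                        lda_weights = w_all,
                        loo_scores = loo,
                        positive = pos,
                        auc = rank_auc(loo, pos),
                        top_components = NULL),
                   class = "discriminability_result")
  res$top_components <- rank_components(res)
  res
}

#' Rank components by absolute LDA weight
#'
#' Indices of the (up to) `k` largest `|weight|`, in descending order;
#' ties are broken deterministically by lower component index.
#'
#' @param result A [lda_loo_auc()] result, or a numeric weight vector.
#' @param k Number of top components to report (default 5).
#' @return Integer vector of component indices.
#' @export
rank_components <- function(result, k = 5L) {
  w <- if (inherits(result, "discriminability_result")) result$lda_weights
       else as.numeric(result)
  ord <- order(-abs(w), seq_along(w))
  ord[seq_len(min(k, length(w)))]
}

#' Greedy matching of component maps between two model fits
#'
#' Repeatedly pairs the unmatched component pair with the largest absolute
#' Pearson correlation exceeding `threshold` (default 0.5). Each component
#' appears in at most one match; the procedure is symmetric in its
#' arguments. Component identity is whatever map representation is passed
#' in -- typically the concatenated (x-map, y-map) vector per component, so
#' both modalities' patterns must co-reproduce.
#'
#' @param maps_i,maps_j Voxels x components matrices on the same grid.
#' @param threshold Absolute-correlation matching threshold.
#' @return An object of class `match_table`: data frame `pairs`
#'   (`comp_i`, `comp_j`, `correlation`, signed), plus `unmatched_i`,
#'   `unmatched_j`.
#' @export
match_components <- function(maps_i, maps_j, threshold = 0.5) {
  maps_i <- as.matrix(maps_i); maps_j <- as.matrix(maps_j)
  if (nrow(maps_i) != nrow(maps_j))
    stop("map grids do not match: ", nrow(maps_i), " vs ", nrow(maps_j), " voxels")
  R <- cor(maps_i, maps_j)
  A <- abs(R)
  pairs <- data.frame(comp_i = integer(0), comp_j = integer(0),
                      correlation = numeric(0))
  while (any(A > threshold, na.rm = TRUE)) {
    ij <- which(A == max(A, na.rm = TRUE), arr.ind = TRUE)[1, ]
    pairs <- rbind(pairs, data.frame(comp_i = ij[1], comp_j = ij[2],
                                     correlation = R[ij[1], ij[2]]))
    A[ij[1], ] <- NA; A[, ij[2]] <- NA
  }
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 unmatched_i = setdiff(seq_len(ncol(maps_i)), pairs$comp_i),
                 unmatched_j = setdiff(seq_len(ncol(maps_j)), pairs$comp_j),
                 threshold = threshold),
            class = "match_table")
}

#' @export
print.match_table <- function(x, ...) {
  cat("match_table:", nrow(x$pairs), "pairs at |r| >", x$threshold, "\n")
  if (nrow(x$pairs)) print(x$pairs)
  invisible(x)
}

#' Cross-repeat reproducibility counts of discriminative components
#'
#' For each component of a reference repeat, counts in how many repeats it
#' is both matched (by [match_components()] on the component maps) and
#' among that repeat's top discriminative components. The reference repeat
#' itself contributes 1 when the component is in its own top list, so with
#' identical repeats every top component scores `n_repeats`. Components of
#' other repeats with no reference match are reported separately.
#'
#' @param repeat_results List, one entry per repeat, each with `maps`
#'   (voxels x components matrix) and `top` (indices of the repeat's top
#'   discriminative components).
#' @param reference Index of the reference repeat (default 1).
#' @param threshold Matching threshold passed to [match_components()].
#' @return List with `counts` (per reference component), `n_repeats`, and
#'   `unmatched_other` (per non-reference repeat, its top components that
#'   found no reference match).
#' @export
reproducibility_counts <- function(repeat_results, reference = 1L,
                                   threshold = 0.5) {
  n_rep <- length(repeat_results)
  if (n_rep < 2L) stop("need at least 2 repeats")
  for (r in repeat_results)
    if (is.null(r$maps) || is.null(r$top))
      stop("every repeat needs 'maps' and 'top'")
  ref <- repeat_results[[reference]]
  m_ref <- ncol(ref$maps)
  counts <- integer(m_ref)
  counts[intersect(ref$top, seq_len(m_ref))] <-
    counts[intersect(ref$top, seq_len(m_ref))] + 1L
  unmatched_other <- vector("list", n_rep)
  for (j in setdiff(seq_len(n_rep), reference)) {
    mt <- match_components(ref$maps, repeat_results[[j]]$maps, threshold)
    hit <- mt$pairs$comp_j %in% repeat_results[[j]]$top
    counts[mt$pairs$comp_i[hit]] <- counts[mt$pairs$comp_i[hit]] + 1L
    unmatched_other[[j]] <-
      intersect(repeat_results[[j]]$top, mt$unmatched_j)
  }
  list(counts = counts, n_repeats = n_rep, reference = reference,
       unmatched_other = unmatched_other)
}

ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  g[rowSums(g^2) <= radius^2, , drop = FALSE]
}

shift_logical <- function(bin, off, fill = FALSE) {
  d <- dim(bin)
  out <- array(fill, d)
  src <- lapply(1:3, function(a) {
    i <- seq_len(d[a]) - off[a]
    i[i >= 1 & i <= d[a]]
  })
  dst <- lapply(1:3, function(a) {
    i <- seq_len(d[a])
    i[i - off[a] >= 1 & i - off[a] <= d[a]]
  })
  out[dst[[1]], dst[[2]], dst[[3]]] <- bin[src[[1]], src[[2]], src[[3]]]
  out
}

# Binary erosion/dilation with an arbitrary offset set; outside the grid is
# treated as background (FALSE).
binary_erode <- function(bin, offsets) {
  out <- array(TRUE, dim(bin))
  for (i in seq_len(nrow(offsets)))
    out <- out & shift_logical(bin, -offsets[i, ], fill = FALSE)
  out
}

binary_dilate <- function(bin, offsets) {
  out <- array(FALSE, dim(bin))
  for (i in seq_len(nrow(offsets)))
    out <- out | shift_logical(bin, offsets[i, ], fill = FALSE)
  out
}

#' Binary morphological opening with a ball structuring element
#'
#' Erosion followed by dilation; removes structures smaller than the ball.
#'
#' @param bin Logical 3D array.
#' @param radius Ball radius in voxels.
#' @return Opened logical array.
#' @export
binary_opening <- function(bin, radius = 1) {
  off <- ball_offsets(radius)
  binary_dilate(binary_erode(bin, off), off)
}

# 6-connected components labelling by flood fill.
label_connected <- function(bin) {
  d <- dim(bin)
  lab <- array(0L, d)
  idx <- which(bin)
  nbr <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  current <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- start
    lab[start] <- current
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      v0 <- v - 1L
      cz <- v0 %/% (d[1] * d[2])
      cy <- (v0 %% (d[1] * d[2])) %/% d[1]
      cx <- v0 %% d[1]
      for (k in 1:6) {
        nx <- cx + nbr[k, 1]; ny <- cy + nbr[k, 2]; nz <- cz + nbr[k, 3]
        if (nx < 0 || ny < 0 || nz < 0 ||
            nx >= d[1] || ny >= d[2] || nz >= d[3]) next
        nv <- 1L + nx + d[1] * (ny + d[2] * nz)
        if (bin[nv] && lab[nv] == 0L) {
          lab[nv] <- current
          queue <- c(queue, nv)
        }
      }
    }
  }
  lab
}

#' Extract a cluster network from a component map
#'
#' Binarises the absolute component map at a quantile of its absolute
#' values, applies a binary morphological opening with a ball structuring
#' element, and labels the surviving 6-connected clusters. The sign of each
#' cluster (mean of the original map over the cluster) is recorded so
#' correlated and anticorrelated hubs can be distinguished.
#'
#' @param component_map 3D array (a component map written back to the grid),
#'   or a masked-voxel vector together with `mask`/`grid_shape` via `geom`.
#' @param quantile_threshold Quantile of `|map|` (over the mask) used to
#'   binarise, in (0, 1).
#' @param opening_radius Ball radius of the morphological opening.
#' @param mask Optional logical array restricting the quantile and the
#'   clusters.
#' @return Integer label array of clusters, with attribute `"signs"` (named
#'   per-cluster sign) and `"n_clusters"`. Empty post-opening masks give a
#'   zero labelling with a warning.
#' @export
extract_network <- function(component_map, quantile_threshold = 0.95,
                            opening_radius = 1, mask = NULL) {
  stopifnot(is.array(component_map), length(dim(component_map)) == 3L)
  if (quantile_threshold <= 0 || quantile_threshold >= 1)
    stop("quantile_threshold must be in (0, 1)")
  vals <- if (is.null(mask)) abs(component_map) else abs(component_map[mask])
  thr <- quantile(vals, quantile_threshold)
  bin <- abs(component_map) >= thr
  if (!is.null(mask)) bin <- bin & mask
  opened <- binary_opening(bin, opening_radius)
  if (!any(opened)) {
    warning("no voxels survive thresholding + opening; empty labelling")
    lab <- array(0L, dim(component_map))
    attr(lab, "signs") <- numeric(0)
    attr(lab, "n_clusters") <- 0L
    return(lab)
  }
  lab <- label_connected(opened)
  ncl <- max(lab)
  signs <- vapply(seq_len(ncl), function(l)
    sign(mean(component_map[lab == l])), numeric(1))
  attr(lab, "signs") <- stats::setNames(signs, paste0("cluster_", seq_len(ncl)))
  attr(lab, "n_clusters") <- ncl
  lab
}
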