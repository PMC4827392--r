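#' Build an aligned atlas database for patch-based synthesis
#'
#' Stores the (already spatially aligned) atlas pairs as full-grid volumes
#' for local nearest-patch lookup. Patches are cubic with odd side length
#' (default 5, i.e. 5x5x5 voxels); the search is restricted to the same
#' voxel location across atlases by default (`search_radius = 0`), with an
#' optional cubic offset search. Patch windows at the grid boundary are
#' clamped to the grid; no padding values are invented.
#'
#' @param dataset A [multimodal_dataset()] of atlas pairs (uncentered
#'   intensities).
#' @param patch_side Odd cubic patch side length in voxels (>= 1).
#' @param search_radius Voxel offset radius around the query location.
#' @return An object of class `patch_db`.
#' @export
build_patch_db <- function(dataset, patch_side = 5L, search_radius = 0L) {
  patch_side <- as.integer(patch_side)
  search_radius <- as.integer(search_radius)
  if (patch_side < 1L || patch_side %% 2L == 0L)
    stop("patch_side must be an odd integer >= 1")
  if (search_radius < 0L) stop("search_radius must be >= 0")
  if (n_subjects(dataset) < 1L) stop("empty patch database")
  to_full <- function(M) {
    out <- matrix(0, nrow(M), prod(dataset$grid_shape))
    out[, as.vector(dataset$mask)] <- M
    out
  }
  structure(list(atlas_x = to_full(dataset$X), atlas_y = to_full(dataset$Y),
                 subject_ids = dataset$subject_ids,
                 mask = dataset$mask, grid_shape = dataset$grid_shape,
                 patch_side = patch_side, search_radius = search_radius),
            class = "patch_db")
}

#' @export
print.patch_db <- function(x, ...) {
  cat("patch_db:", nrow(x$atlas_x), "atlas pairs, patch side", x$patch_side,
      ", search radius", x$search_radius, "\n")
  invisible(x)
}

#' Patch-based synthesis of the target modality
#'
#' For each masked voxel, finds the atlas (and offset within the search
#' radius) whose x-patch around the voxel minimises the L2 distance to the
#' query's x-patch, and outputs the chosen atlas's y-intensity at the
#' corresponding centre (`aggregate = "center"`) or the mean of its y-patch
#' (`aggregate = "mean"`). Ties are broken by lowest atlas index, then
#' lexicographic offset. Output intensities are always values present in
#' the atlas y-volumes: this is a lookup, not a regression.
#'
#' @param X_new Query predictor images: subjects x masked-voxels matrix (or
#'   a single masked-voxel vector) on the database grid.
#' @param db A [build_patch_db()] database.
#' @param aggregate `"center"` (default) or `"mean"`.
#' @param exclude Optional per-query 1-based atlas index to exclude from the
#'   search (0 or `NULL` = none), used by leave-one-out schemes.
#' @return List with `yhat` (subjects x masked-voxels predictions) and
#'   `winner` (subjects x masked-voxels winning atlas index).
#' @export
synthesize_target <- function(X_new, db, aggregate = c("center", "mean"),
                              exclude = NULL) {
  aggregate <- match.arg(aggregate)
  X_new <- rbind(X_new)
  nm <- sum(db$mask)
  if (ncol(X_new) != nm)
    stop("X_new has ", ncol(X_new), " columns, expected ", nm)
  if (nrow(db$atlas_x) < 1L) stop("empty patch database")
  Qfull <- matrix(0, nrow(X_new), prod(db$grid_shape))
  Qfull[, as.vector(db$mask)] <- X_new
  if (is.null(exclude)) exclude <- integer(nrow(X_new))
  res <- patch_search_cpp(db$atlas_x, db$atlas_y, Qfull,
                          as.integer(db$grid_shape), as.vector(db$mask),
                          db$patch_side, db$search_radius,
                          aggregate == "mean", as.integer(exclude))
  list(yhat = res$yhat[, as.vector(db$mask), drop = FALSE],
       winner = res$winner[, as.vector(db$mask), drop = FALSE])
}

#' Leave-one-out patch synthesis over a cohort
#'
#' Predicts every subject's target modality from a database containing all
#' other subjects (the subject itself is excluded from the patch search).
#'
#' @param dataset A [multimodal_dataset()] with at least 2 subjects.
#' @param patch_side,search_radius,aggregate As in [build_patch_db()] and
#'   [synthesize_target()].
#' @return List with `yhat` and `winner` matrices as in
#'   [synthesize_target()].
#' @export
leave_one_out_synthesis <- function(dataset, patch_side = 5L,
                                    search_radius = 0L,
                                    aggregate = c("center", "mean")) {
  aggregate <- match.arg(aggregate)
  K <- n_subjects(dataset)
  if (K < 2L) stop("leave-one-out synthesis needs at least 2 subjects")
  db <- build_patch_db(dataset, patch_side, search_radius)
  synthesize_target(dataset$X, db, aggregate, exclude = seq_len(K))
}
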