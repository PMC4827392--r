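#' Paired subject-by-voxel matrices for two image modalities
#'
#' Container for the matrices `X` (predictor modality) and `Y` (predicted
#' modality), one row per subject and one column per voxel inside the
#' analysis mask, plus subject metadata and grid geometry. Voxels are
#' flattened in R's native column-major order (first axis fastest); voxel
#' coordinates are 0-based.
#'
#' @param X,Y Numeric matrices, subjects x masked voxels.
#' @param subject_ids Character vector of unique subject identifiers.
#' @param group_labels Factor (or vector coercible to factor) of per-subject
#'   group labels.
#' @param mask Logical 3D array; `TRUE` voxels are the matrix columns.
#' @param grid_shape Integer triple of voxels per axis.
#' @return An object of class `multimodal_dataset`.
#' @export
multimodal_dataset <- function(X, Y, subject_ids, group_labels, mask, grid_shape) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  grid_shape <- as.integer(grid_shape)
  if (!is.array(mask) || !identical(dim(mask), grid_shape))
    stop("mask must be a logical array with dim equal to grid_shape")
  nm <- sum(mask)
  if (nm == 0L) stop("mask is empty")
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (ncol(X) != nm || ncol(Y) != nm)
    stop("column counts of X and Y must equal the mask true-count (", nm, ")")
  if (anyDuplicated(subject_ids)) stop("subject_ids must be unique")
  if (length(subject_ids) != nrow(X))
    stop("subject_ids length must match the rows of X")
  group_labels <- as.factor(group_labels)
  if (length(group_labels) != nrow(X))
    stop("group_labels length must match the rows of X")
  structure(list(X = X, Y = Y,
                 subject_ids = as.character(subject_ids),
                 group_labels = group_labels,
                 mask = mask, grid_shape = grid_shape,
                 x_mean = NULL, y_mean = NULL, centered = FALSE),
            class = "multimodal_dataset")
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  cat("multimodal_dataset:", nrow(x$X), "subjects x", ncol(x$X), "masked voxels",
      sprintf("(grid %s)", paste(x$grid_shape, collapse = "x")),
      if (x$centered) "[centered]" else "", "\n")
  print(table(x$group_labels))
  invisible(x)
}

#' Number of subjects / masked voxels in a dataset
#' @param dataset A [multimodal_dataset()].
#' @return Integer count.
#' @export
n_subjects <- function(dataset) nrow(dataset$X)

#' @rdname n_subjects
#' @export
n_voxels <- function(dataset) ncol(dataset$X)

read_volume <- function(path) {
  v <- tryCatch(RNifti::readNifti(path),
                error = function(e) stop("unreadable volume '", path, "': ",
                                         conditionMessage(e)))
  a <- array(as.numeric(v), dim = dim(v))
  if (length(dim(a)) != 3L) stop("volume '", path, "' is not 3D")
  a
}

#' Assemble a multimodal dataset from NIfTI volume pairs
#'
#' Reads one predictor-modality and one predicted-modality volume per
#' subject, applies the mask, and stacks the masked voxels (column-major
#' flattening) into the `X` and `Y` matrices. Rows follow the input order.
#'
#' @param x_paths,y_paths Equal-length character vectors of NIfTI paths.
#' @param labels Per-subject group labels (same length as the path lists).
#' @param mask_path Path to a NIfTI mask volume; nonzero voxels are included.
#' @param subject_ids Optional subject identifiers; defaults to the
#'   basenames of `x_paths`.
#' @return A [multimodal_dataset()].
#' @export
load_image_pairs <- function(x_paths, y_paths, labels, mask_path,
                             subject_ids = NULL) {
  if (length(x_paths) != length(y_paths))
    stop("x_paths and y_paths must have equal length")
  if (length(labels) != length(x_paths))
    stop("labels must match the number of subjects")
  mask_vol <- read_volume(mask_path)
  mask <- mask_vol != 0
  if (!any(mask)) stop("mask '", mask_path, "' is empty")
  grid_shape <- dim(mask)
  read_masked <- function(path) {
    a <- read_volume(path)
    if (!identical(dim(a), grid_shape))
      stop("volume '", path, "' has shape ", paste(dim(a), collapse = "x"),
           ", expected ", paste(grid_shape, collapse = "x"))
    flatten_volume(a, mask)
  }
  X <- do.call(rbind, lapply(x_paths, read_masked))
  Y <- do.call(rbind, lapply(y_paths, read_masked))
  if (is.null(subject_ids)) subject_ids <- basename(x_paths)
  multimodal_dataset(X, Y, subject_ids, labels, mask, grid_shape)
}

#' Write a masked voxel vector as a NIfTI volume
#'
#' Masked-out voxels are written as 0; the grid shape is preserved.
#'
#' @param values Numeric vector of length `sum(mask)`.
#' @param dataset A [multimodal_dataset()] supplying mask and grid geometry
#'   (or any list with `mask` and `grid_shape`).
#' @param path Output file path (`.nii` / `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_image <- function(values, dataset, path) {
  if (length(values) != sum(dataset$mask))
    stop("values length (", length(values), ") must equal the mask true-count (",
         sum(dataset$mask), ")")
  vol <- unflatten_volume(values, dataset$grid_shape, dataset$mask)
  RNifti::writeNifti(vol, path)
  invisible(path)
}

#' Column-mean centering of both modalities
#'
#' Subtracts per-voxel (column) means from `X` and `Y` independently and
#' records them, so predictions can be returned in original units. No
#' variance scaling is applied: voxel units are commensurate within a
#' modality and covariance maximisation only requires centering.
#'
#' @param dataset An uncentered [multimodal_dataset()].
#' @return The centered dataset with `x_mean` / `y_mean` recorded.
#' @export
center_dataset <- function(dataset) {
  if (isTRUE(dataset$centered))
    stop("dataset is already centered; re-centering is not allowed")
  dataset$x_mean <- colMeans(dataset$X)
  dataset$y_mean <- colMeans(dataset$Y)
  dataset$X <- sweep(dataset$X, 2L, dataset$x_mean)
  dataset$Y <- sweep(dataset$Y, 2L, dataset$y_mean)
  dataset$centered <- TRUE
  dataset
}

#' Subset a dataset by subject index
#'
#' @param dataset A [multimodal_dataset()].
#' @param idx Integer or logical subject index.
#' @return A [multimodal_dataset()] with the selected rows (uncentered
#'   state and means are preserved as-is).
#' @export
subset_subjects <- function(dataset, idx) {
  out <- dataset
  out$X <- dataset$X[idx, , drop = FALSE]
  out$Y <- dataset$Y[idx, , drop = FALSE]
  out$subject_ids <- dataset$subject_ids[idx]
  out$group_labels <- droplevels(dataset$group_labels[idx])
  out
}

#' Write a phantom cohort to disk
#'
#' One NIfTI file per subject and modality, the mask and region atlas as
#' NIfTI, and the subject table, planted loadings and region table as CSV.
#'
#' @param cohort A list as returned by [sample_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(cohort, dir) {
  ds <- cohort$dataset; tr <- cohort$truth
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(array(as.integer(ds$mask), ds$grid_shape),
                     file.path(dir, "mask.nii.gz"))
  atlas <- tr$atlas
  RNifti::writeNifti(array(as.integer(atlas), ds$grid_shape),
                     file.path(dir, "atlas.nii.gz"))
  utils::write.csv(attr(atlas, "regions"), file.path(dir, "regions.csv"),
                   row.names = FALSE)
  for (k in seq_len(n_subjects(ds))) {
    write_image(ds$X[k, ], ds, file.path(dir, paste0(ds$subject_ids[k], "_x.nii.gz")))
    write_image(ds$Y[k, ], ds, file.path(dir, paste0(ds$subject_ids[k], "_y.nii.gz")))
  }
  utils::write.csv(data.frame(subject_id = ds$subject_ids,
                              label = as.character(ds$group_labels)),
                   file.path(dir, "subjects.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(tr$loadings), file.path(dir, "loadings.csv"),
                   row.names = FALSE)
  invisible(dir)
}
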