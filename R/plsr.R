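#' Leading cross-covariance singular pair via the subjects-space eigen trick
#'
#' Computes the leading left/right singular-vector pair `(w, c)` of the
#' voxels-by-voxels cross-covariance `t(Xc) %*% Yc` without materialising any
#' voxels-by-voxels matrix. The x-score `t = Xc w` is an eigenvector of the
#' K x K product `(Xc Xc')(Yc Yc')`; for numerical robustness the symmetric
#' reformulation is solved: with `Gx = Xc Xc'` and `Gy = Yc Yc'`, the leading
#' eigenvector `v` of the symmetric PSD matrix `Gx^(1/2) Gy Gx^(1/2)` gives
#' `t = Gx^(1/2) v`, from which `c`, `w`, and `u` follow by back-projection
#' and normalisation. The sign is fixed so that the entry of `w` with the
#' largest absolute value is positive; `(w, c, t, u)` are flipped together so
#' the quadruple stays sign-coherent.
#'
#' @param Xc,Yc Centered matrices with the same number of rows (subjects).
#' @return List with unit-norm weight vectors `w`, `c`, scores `t = Xc w`,
#'   `u = Yc c`, and the singular value `sigma` of the cross-covariance.
#' @export
leading_covariance_pair <- function(Xc, Yc) {
  Xc <- as.matrix(Xc); Yc <- as.matrix(Yc)
  K <- nrow(Xc)
  if (nrow(Yc) != K) stop("Xc and Yc must have the same number of rows")
  if (K < 2L) stop("need at least 2 subjects")
  if (all(Xc == 0) || all(Yc == 0)) stop("all-zero input block")
  Gx <- tcrossprod(Xc)
  Gy <- tcrossprod(Yc)
  ex <- eigen(Gx, symmetric = TRUE)
  S12 <- ex$vectors %*% (sqrt(pmax(ex$values, 0)) * t(ex$vectors))
  ea <- eigen(S12 %*% Gy %*% S12, symmetric = TRUE)
  if (any(!is.finite(ea$values)))
    stop("subjects-space eigen-solver failed: non-finite eigenvalues")
  t0 <- as.vector(S12 %*% ea$vectors[, 1L])
  if (sqrt(sum(t0^2)) < 1e-12 * sqrt(sum(Xc^2)))
    stop("degenerate leading score: cross-covariance is numerically zero")
  cc <- unit_norm(as.vector(crossprod(Yc, t0)))
  w <- unit_norm(as.vector(crossprod(Xc, Yc %*% cc)))
  tt <- as.vector(Xc %*% w)
  uu <- as.vector(Yc %*% cc)
  i <- which.max(abs(w))
  if (w[i] < 0) { w <- -w; cc <- -cc; tt <- -tt; uu <- -uu }
  list(w = w, c = cc, t = tt, u = uu, sigma = sqrt(max(ea$values[1L], 0)))
}

#' Deflate both data blocks on the current x-score
#'
#' Removes the extracted component's contribution before the next extraction:
#' with loadings `p = Xc' t / (t' t)` and `q = Yc' t / (t' t)`, returns
#' `Xc - t p'` and `Yc - t q'`. Both blocks are deflated on the x-score `t`
#' (standard PLS2 regression deflation), which guarantees `t' Xc* = 0`,
#' `t' Yc* = 0` and mutual orthogonality of successive x-scores.
#'
#' @param Xc,Yc Centered (possibly already deflated) data blocks.
#' @param t Current x-score vector.
#' @return List with deflated blocks `Xc`, `Yc` and loadings `p`, `q`.
#' @export
deflate_blocks <- function(Xc, Yc, t) {
  tt <- sum(t^2)
  if (tt < .Machine$double.eps) stop("zero-norm score: cannot deflate")
  p <- as.vector(crossprod(Xc, t)) / tt
  q <- as.vector(crossprod(Yc, t)) / tt
  list(Xc = Xc - tcrossprod(t, p), Yc = Yc - tcrossprod(t, q), p = p, q = q)
}

#' Fit a multimodal PLS regression model
#'
#' Extracts `m` latent components by iterating
#' [leading_covariance_pair()], estimating the scalar inner coefficient
#' `b_i = (t' u) / (t' t)` linking the score pairs, and deflating both
#' blocks on the x-score with [deflate_blocks()]. If the residual Frobenius
#' norm of either block falls below `1e-12` times its initial value,
#' extraction stops early with a warning and fewer components are returned.
#'
#' @param dataset A centered [multimodal_dataset()] (see [center_dataset()]).
#' @param m Number of latent components, `1 <= m <= subjects - 1`.
#' @return An object of class `pls_model` with fields `W`, `C` (unit-norm
#'   x-/y-weights), `P`, `Q` (loadings), `T`, `U` (scores), `b` (inner
#'   coefficients), `x_mean`, `y_mean`, `m`, plus the mask/grid geometry for
#'   exporting component maps.
#' @export
fit_pls <- function(dataset, m) {
  if (!isTRUE(dataset$centered))
    stop("dataset must be centered first (see center_dataset())")
  model <- fit_pls_blocks(dataset$X, dataset$Y, m)
  model$x_mean <- dataset$x_mean
  model$y_mean <- dataset$y_mean
  model$mask <- dataset$mask
  model$grid_shape <- dataset$grid_shape
  model
}

#' @describeIn fit_pls Fit directly on centered data blocks (the two
#'   modalities need not share a voxel grid). Centering vectors default to
#'   zero; no grid geometry is attached.
#' @param Xc,Yc Centered predictor / predicted blocks with equal row counts.
#' @export
fit_pls_blocks <- function(Xc, Yc, m) {
  Xc <- as.matrix(Xc); Yc <- as.matrix(Yc)
  K <- nrow(Xc)
  m <- as.integer(m)
  if (m < 1L || m > K - 1L)
    stop("m must satisfy 1 <= m <= subjects - 1 (= ", K - 1L, ")")
  nx0 <- sqrt(sum(Xc^2)); ny0 <- sqrt(sum(Yc^2))
  W <- P <- Tm <- NULL; C <- Q <- Um <- NULL; b <- numeric(0)
  for (i in seq_len(m)) {
    if (sqrt(sum(Xc^2)) < 1e-12 * nx0 || sqrt(sum(Yc^2)) < 1e-12 * ny0) {
      warning("residual norm below tolerance after ", i - 1L,
              " components; returning fewer than m = ", m)
      break
    }
    pair <- leading_covariance_pair(Xc, Yc)
    b <- c(b, sum(pair$t * pair$u) / sum(pair$t^2))
    d <- deflate_blocks(Xc, Yc, pair$t)
    W <- cbind(W, pair$w); C <- cbind(C, pair$c)
    P <- cbind(P, d$p); Q <- cbind(Q, d$q)
    Tm <- cbind(Tm, pair$t); Um <- cbind(Um, pair$u)
    Xc <- d$Xc; Yc <- d$Yc
  }
  structure(list(W = W, C = C, P = P, Q = Q, T = Tm, U = Um, b = b,
                 x_mean = numeric(nrow(W)), y_mean = numeric(nrow(C)),
                 m = ncol(W), mask = NULL, grid_shape = NULL),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("pls_model:", x$m, "latent components,",
      nrow(x$W), "x-voxels,", nrow(x$C), "y-voxels\n")
  cat("inner coefficients b:", format(x$b, digits = 3), "\n")
  invisible(x)
}

#' Factored PLSR regression operator
#'
#' Returns the linear map from a new predictor image to its predicted
#' modality in factored form: scores `T_new = Xc_new W (P' W)^-1`, prediction
#' `Y_hat = T_new diag(b) C' + y_mean`. No voxels-by-voxels coefficient
#' matrix is ever materialised; on training data the factored map reproduces
#' the standard PLSR pseudoinverse solution exactly.
#'
#' @param model A fitted [fit_pls()] model.
#' @return An object of class `pls_operator` with the rotation
#'   `R = W (P' W)^-1`, inner coefficients `b`, y-weights `C` and the
#'   centering vectors.
#' @export
regression_operator <- function(model) {
  PtW <- crossprod(model$P, model$W)
  kappa <- kappa(PtW, exact = TRUE)
  if (!is.finite(kappa) || kappa > 1e12)
    stop("P'W is numerically singular (condition number ", format(kappa), ")")
  structure(list(R = model$W %*% solve(PtW), b = model$b, C = model$C,
                 x_mean = model$x_mean, y_mean = model$y_mean),
            class = "pls_operator")
}

#' Project new predictor images onto the latent space
#'
#' Centers `X_new` with the training mean and returns the subjects x m score
#' matrix `T_new = (X_new - x_mean) W (P' W)^-1`, the feature space used for
#' discriminability analysis.
#'
#' @param model A fitted [fit_pls()] model.
#' @param X_new Matrix (or vector) of new predictor images, columns matching
#'   the training x-voxels.
#' @return Scores matrix, one row per subject.
#' @export
project_scores <- function(model, X_new) {
  op <- regression_operator(model)
  X_new <- rbind(X_new)
  if (ncol(X_new) != nrow(op$R))
    stop("X_new has ", ncol(X_new), " columns, expected ", nrow(op$R))
  sweep(X_new, 2L, op$x_mean) %*% op$R
}

#' Predict the target modality from new predictor images
#'
#' @param object A fitted [fit_pls()] model.
#' @param X_new Matrix (or vector) of new predictor images.
#' @param ... Unused.
#' @return Predicted target-modality matrix in original (un-centered) units,
#'   rows aligned with `X_new`.
#' @export
predict.pls_model <- function(object, X_new, ...) {
  Tn <- project_scores(object, X_new)
  Yc <- (Tn * rep(object$b, each = nrow(Tn))) %*% t(object$C)
  sweep(Yc, 2L, object$y_mean, `+`)
}

#' Principal component regression comparator
#'
#' PCA on the predictor block (top `m` components, computed in subjects
#' space so no voxels-by-voxels matrix is formed), followed by least-squares
#' regression of the predicted block onto the PC scores. Shares the
#' prediction interface of the PLSR model for head-to-head comparison:
#' where PLSR picks directions maximising cross-block covariance, PCR picks
#' directions of maximal X-variance whether or not they carry any
#' information about Y.
#'
#' @param dataset A centered [multimodal_dataset()].
#' @param m Number of principal components, at most the rank of `X`.
#' @return An object of class `pcr_model` with the PC basis `V`
#'   (voxels x m), regression coefficients `B` (m x y-voxels) and centering
#'   vectors.
#' @export
fit_pcr <- function(dataset, m) {
  if (!isTRUE(dataset$centered))
    stop("dataset must be centered first (see center_dataset())")
  Xc <- dataset$X; Yc <- dataset$Y
  K <- nrow(Xc)
  eg <- eigen(tcrossprod(Xc), symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-12
  if (m > sum(pos)) stop("m = ", m, " exceeds the rank of X (= ", sum(pos), ")")
  U <- eg$vectors[, seq_len(m), drop = FALSE]
  dvals <- sqrt(eg$values[seq_len(m)])
  V <- crossprod(Xc, U) %*% diag(1 / dvals, m)   # right singular vectors
  Tp <- Xc %*% V                                  # PC scores (K x m)
  B <- solve(crossprod(Tp), crossprod(Tp, Yc))    # m x voxels_y
  structure(list(V = V, B = B, x_mean = dataset$x_mean,
                 y_mean = dataset$y_mean, m = m),
            class = "pcr_model")
}

#' @rdname fit_pcr
#' @param object A fitted `pcr_model`.
#' @param X_new New predictor images.
#' @param ... Unused.
#' @export
predict.pcr_model <- function(object, X_new, ...) {
  X_new <- rbind(X_new)
  Tn <- sweep(X_new, 2L, object$x_mean) %*% object$V
  sweep(Tn %*% object$B, 2L, object$y_mean, `+`)
}

#' Export a model's component maps as NIfTI volumes
#'
#' Writes each x-weight and y-weight map of the fitted model as a NIfTI
#' volume (zeros outside the analysis mask), for visual inspection.
#'
#' @param model A fitted [fit_pls()] model.
#' @param dir Output directory (created if needed).
#' @param components Which components to export (default all).
#' @return The directory, invisibly.
#' @export
export_component_maps <- function(model, dir, components = seq_len(model$m)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geom <- list(mask = model$mask, grid_shape = model$grid_shape)
  for (j in components) {
    write_image(model$W[, j], geom, file.path(dir, sprintf("component_%02d_x.nii.gz", j)))
    write_image(model$C[, j], geom, file.path(dir, sprintf("component_%02d_y.nii.gz", j)))
  }
  invisible(dir)
}
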