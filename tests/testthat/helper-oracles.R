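# Independent reference implementations used as oracles. These are written
# the slow, obvious way (dense decompositions, exhaustive searches, naive
# loops) and never share code with the package internals they check.

# Dense SVD-with-deflation PLS2: forms the full voxels x voxels
# cross-covariance explicitly and takes its leading singular pair, deflating
# both blocks on the x-score. Sign convention mirrors the package's.
dense_svd_pls_oracle <- function(Xc, Yc, m) {
  W <- C <- Tm <- NULL
  b <- numeric(0)
  for (i in seq_len(m)) {
    sv <- svd(t(Xc) %*% Yc, nu = 1, nv = 1)
    w <- sv$u[, 1]; cc <- sv$v[, 1]
    j <- which.max(abs(w))
    if (w[j] < 0) { w <- -w; cc <- -cc }
    t0 <- as.vector(Xc %*% w); u0 <- as.vector(Yc %*% cc)
    b <- c(b, sum(t0 * u0) / sum(t0^2))
    p <- as.vector(t(Xc) %*% t0) / sum(t0^2)
    q <- as.vector(t(Yc) %*% t0) / sum(t0^2)
    Xc <- Xc - outer(t0, p); Yc <- Yc - outer(t0, q)
    W <- cbind(W, w); C <- cbind(C, cc); Tm <- cbind(Tm, t0)
  }
  list(W = W, C = C, T = Tm, b = b)
}

# Textbook NIPALS PLS2 (power iteration; normalized x-weights and y-weights,
# scalar inner relation b, Y deflated by b t q'). Returns training-data
# predictions of the centered Y block.
nipals_pls2_oracle <- function(Xc, Yc, m, tol = 1e-28, max_iter = 10000) {
  E <- Xc; F_ <- Yc
  Yhat <- matrix(0, nrow(Yc), ncol(Yc))
  for (i in seq_len(m)) {
    u <- F_[, which.max(apply(F_, 2, var))]
    t_old <- rep(Inf, nrow(E))
    for (it in seq_len(max_iter)) {
      w <- as.vector(t(E) %*% u); w <- w / sqrt(sum(w^2))
      t0 <- as.vector(E %*% w)
      q <- as.vector(t(F_) %*% t0); q <- q / sqrt(sum(q^2))
      u <- as.vector(F_ %*% q)
      if (sum((t0 - t_old)^2) / sum(t0^2) < tol) break
      t_old <- t0
    }
    p <- as.vector(t(E) %*% t0) / sum(t0^2)
    b <- sum(u * t0) / sum(t0^2)
    Yhat <- Yhat + b * outer(t0, q)
    E <- E - outer(t0, p)
    F_ <- F_ - b * outer(t0, q)
  }
  Yhat
}

# Exhaustive nearest-patch search in plain R loops, clamping windows to the
# grid exactly as documented. Volumes are 3D arrays; returns full volumes.
brute_patch_oracle <- function(atlas_x, atlas_y, query, mask, patch_side,
                               search_radius = 0, aggregate = "center") {
  d <- dim(query)
  hp <- patch_side %/% 2
  cl <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  out <- array(0, d)
  win <- array(NA_integer_, d)
  for (vx in 1:d[1]) for (vy in 1:d[2]) for (vz in 1:d[3]) {
    if (!mask[vx, vy, vz]) next
    xs <- max(1, vx - hp):min(d[1], vx + hp)
    ys <- max(1, vy - hp):min(d[2], vy + hp)
    zs <- max(1, vz - hp):min(d[3], vz + hp)
    qp <- query[xs, ys, zs]
    best <- Inf; besta <- NA; bo <- c(0, 0, 0)
    for (a in seq_along(atlas_x)) {
      for (dx in -search_radius:search_radius)
        for (dy in -search_radius:search_radius)
          for (dz in -search_radius:search_radius) {
            ap <- atlas_x[[a]][cl(xs + dx, 1, d[1]), cl(ys + dy, 1, d[2]),
                               cl(zs + dz, 1, d[3])]
            d2 <- sum((qp - ap)^2)
            if (d2 < best) { best <- d2; besta <- a; bo <- c(dx, dy, dz) }
          }
    }
    if (aggregate == "center") {
      out[vx, vy, vz] <- atlas_y[[besta]][cl(vx + bo[1], 1, d[1]),
                                          cl(vy + bo[2], 1, d[2]),
                                          cl(vz + bo[3], 1, d[3])]
    } else {
      out[vx, vy, vz] <- mean(atlas_y[[besta]][cl(xs + bo[1], 1, d[1]),
                                               cl(ys + bo[2], 1, d[2]),
                                               cl(zs + bo[3], 1, d[3])])
    }
    win[vx, vy, vz] <- besta
  }
  list(yhat = out, winner = win)
}

# AUC by exhaustive concordant-pair counting (ties count 1/2).
pair_count_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Random centered matrix helper.
centered_matrix <- function(K, N) {
  scale(matrix(rnorm(K * N), K, N), scale = FALSE)
}
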