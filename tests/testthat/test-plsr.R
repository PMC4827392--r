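test_that("leading pair reduces to PCA when the two blocks coincide", {
  set.seed(10)
  Xc <- centered_matrix(8, 15)
  p <- leading_covariance_pair(Xc, Xc)
  pc1 <- svd(Xc, nu = 0, nv = 1)$v[, 1]
  expect_gt(abs(sum(p$w * pc1)), 1 - 1e-10)
  expect_gt(abs(sum(p$w * p$c)), 1 - 1e-10)
})

test_that("leading pair recovers an exact rank-1 factor model", {
  set.seed(11)
  t0 <- rnorm(9)
  w0 <- unname(nonlocalpls:::unit_norm(rnorm(20)))
  c0 <- unname(nonlocalpls:::unit_norm(rnorm(25)))
  p <- leading_covariance_pair(outer(t0, w0), outer(t0, c0))
  expect_gt(abs(sum(p$w * w0)), 1 - 1e-8)
  expect_gt(abs(sum(p$c * c0)), 1 - 1e-8)
})

test_that("subjects-space solution equals the dense SVD of t(Xc) Yc", {
  set.seed(12)
  Xc <- centered_matrix(6, 20)
  Yc <- centered_matrix(6, 25)
  p <- leading_covariance_pair(Xc, Yc)
  sv <- svd(t(Xc) %*% Yc, nu = 1, nv = 1)
  expect_gt(abs(sum(p$w * sv$u[, 1])), 1 - 1e-8)
  expect_gt(abs(sum(p$c * sv$v[, 1])), 1 - 1e-8)
  # sign convention: largest-|entry| of w is positive
  expect_gt(p$w[which.max(abs(p$w))], 0)
  expect_error(leading_covariance_pair(Xc * 0, Yc), "all-zero")
})

test_that("deflation annihilates the extracted direction", {
  set.seed(13)
  # rank-1 X deflates to zero
  t0 <- rnorm(7); w0 <- nonlocalpls:::unit_norm(rnorm(12))
  X1 <- outer(t0, w0)
  d <- deflate_blocks(X1, centered_matrix(7, 9), t0)
  expect_lt(max(abs(d$Xc)), 1e-10)

  # orthogonality to the score after deflation, any data
  Xc <- centered_matrix(8, 14); Yc <- centered_matrix(8, 11)
  p <- leading_covariance_pair(Xc, Yc)
  d2 <- deflate_blocks(Xc, Yc, p$t)
  expect_lt(max(abs(crossprod(d2$Xc, p$t))), 1e-8)
  expect_lt(max(abs(crossprod(d2$Yc, p$t))), 1e-8)

  # successive scores are mutually orthogonal
  p2 <- leading_covariance_pair(d2$Xc, d2$Yc)
  expect_lt(abs(sum(p$t * p2$t)), 1e-8)
  expect_error(deflate_blocks(Xc, Yc, rep(0, 8)), "zero-norm")
})

test_that("fit_pls with m = 1 equals the single leading pair", {
  set.seed(14)
  Xc <- centered_matrix(8, 10); Yc <- centered_matrix(8, 10)
  m1 <- fit_pls_blocks(Xc, Yc, 1)
  p <- leading_covariance_pair(Xc, Yc)
  expect_equal(as.vector(m1$W), p$w)
  expect_equal(as.vector(m1$C), p$c)
  expect_equal(m1$b, sum(p$t * p$u) / sum(p$t^2))
  expect_error(fit_pls_blocks(Xc, Yc, 8), "m must satisfy")
})

test_that("all weight pairs match the dense SVD-with-deflation oracle", {
  set.seed(15)
  for (rep in 1:5) {
    K <- sample(4:10, 1)
    Xc <- centered_matrix(K, sample(10:30, 1))
    Yc <- centered_matrix(K, sample(10:30, 1))
    m <- min(3, K - 1)
    fit <- fit_pls_blocks(Xc, Yc, m)
    orc <- dense_svd_pls_oracle(Xc, Yc, m)
    for (i in seq_len(m)) {
      expect_gt(abs(sum(fit$W[, i] * orc$W[, i])), 1 - 1e-8)
      expect_gt(abs(sum(fit$C[, i] * orc$C[, i])), 1 - 1e-8)
    }
  }
})

test_that("noiseless phantom is reconstructed to machine precision", {
  spec <- tiny_spec(noise_sd = 0, confound_amplitude = 0,
                    subjects_per_group = c(6L, 6L, 6L))
  ch <- sample_cohort(spec)
  ctr <- center_dataset(ch$dataset)
  fit <- fit_pls(ctr, 3)
  yhat <- predict(fit, ch$dataset$X)
  relerr <- sqrt(sum((yhat - ch$dataset$Y)^2) / sum(ch$dataset$Y^2))
  expect_lt(relerr, 1e-6)
})

test_that("training predictions agree with a textbook NIPALS PLS2", {
  set.seed(16)
  Xc <- centered_matrix(20, 30)
  Yc <- centered_matrix(20, 30)
  for (m in c(1, 3, 5)) {
    fit <- fit_pls_blocks(Xc, Yc, m)
    yhat <- predict(fit, Xc)  # x_mean is 0 for pre-centered input
    orc <- nipals_pls2_oracle(Xc, Yc, m)
    expect_lt(sqrt(sum((yhat - orc)^2)) / sqrt(sum(orc^2)), 1e-6)
  }
})

test_that("the factored operator reproduces scores and a dense coefficient", {
  set.seed(17)
  Xc <- centered_matrix(8, 10)
  Yc <- centered_matrix(8, 12)
  fit <- fit_pls_blocks(Xc, Yc, 4)
  expect_equal(unname(project_scores(fit, Xc)), unname(fit$T),
               tolerance = 1e-8)

  # dense-coefficient oracle: B = W (P'W)^-1 diag(b) C' materialised
  op <- regression_operator(fit)
  B <- op$R %*% diag(fit$b, fit$m) %*% t(fit$C)
  expect_equal(unname(predict(fit, Xc)), unname(Xc %*% B), tolerance = 1e-9)
})

test_that("full-dimensional fit interpolates noiseless factor data", {
  set.seed(18)
  K <- 8
  S <- matrix(rnorm(K * (K - 1)), K, K - 1)
  Wt <- qr.Q(qr(matrix(rnorm(15 * (K - 1)), 15)))[, 1:(K - 1)]
  Ct <- qr.Q(qr(matrix(rnorm(14 * (K - 1)), 14)))[, 1:(K - 1)]
  Xc <- scale(S %*% t(Wt), scale = FALSE)
  Yc <- scale(S %*% t(Ct), scale = FALSE)
  fit <- fit_pls_blocks(Xc, Yc, K - 1)
  expect_lt(max(abs(predict(fit, Xc) - Yc)), 1e-6)
})

test_that("prediction is affine and centering-aware", {
  set.seed(19)
  fit <- fit_pls_blocks(matrix(rnorm(120), 10, 12),
                        matrix(rnorm(110), 10, 11), 3)
  fit$x_mean <- rnorm(12); fit$y_mean <- rnorm(11)  # nontrivial training means

  # the training mean input maps to the training mean output
  expect_equal(as.vector(predict(fit, fit$x_mean)), fit$y_mean,
               tolerance = 1e-10)

  x1 <- rnorm(12); x2 <- rnorm(12); a <- 0.3
  lhs <- predict(fit, a * x1 + (1 - a) * x2)
  rhs <- a * predict(fit, x1) + (1 - a) * predict(fit, x2)
  expect_equal(lhs, rhs, tolerance = 1e-8)

  # zero image projects to the projection of -x_mean, not zero
  z <- project_scores(fit, rep(0, 12))
  expect_equal(as.vector(z),
               as.vector((-fit$x_mean) %*% fit$W %*%
                           solve(crossprod(fit$P, fit$W))),
               tolerance = 1e-10)
  expect_error(predict(fit, rep(0, 5)), "columns")
})

test_that("score matrix is orthogonal and covariances decay monotonically", {
  set.seed(20)
  fit <- fit_pls_blocks(matrix(rnorm(15 * 40), 15, 40),
                        matrix(rnorm(15 * 35), 15, 35), 6)
  G <- crossprod(fit$T)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  covs <- vapply(seq_len(fit$m), function(i)
    abs(cov(fit$T[, i], fit$U[, i])), numeric(1))
  expect_true(all(diff(covs) <= 1e-10))
})

test_that("PCR equals OLS at full rank and matches the dense eigen basis", {
  set.seed(21)
  Xc <- centered_matrix(10, 6)   # more subjects than voxels: full column rank
  Yc <- centered_matrix(10, 6)
  mask <- array(TRUE, c(6L, 1L, 1L))
  ds <- center_dataset(multimodal_dataset(Xc, Yc, paste0("s", 1:10),
                                          rep_len(c("A", "B"), 10),
                                          mask, c(6L, 1L, 1L)))
  pcr <- fit_pcr(ds, 6)
  ols <- Xc %*% solve(crossprod(Xc), crossprod(Xc, Yc))
  expect_equal(unname(predict(pcr, Xc)), unname(ols), tolerance = 1e-8)

  # m = 1 PCA direction equals the leading eigenvector of t(Xc) Xc
  pcr1 <- fit_pcr(ds, 1)
  ev <- eigen(crossprod(Xc), symmetric = TRUE)$vectors[, 1]
  expect_gt(abs(sum(pcr1$V[, 1] * ev)), 1 - 1e-8)
  expect_error(fit_pcr(ds, 7), "rank")
})

test_that("a high-variance X-only distractor hurts PCR but not PLSR", {
  wins <- 0L
  for (seed in 1:5) {
    spec <- tiny_spec(seed = 100L + seed,
                      subjects_per_group = c(10L, 10L, 10L),
                      distractor = list(center = c(4, 4, 2), sigma = 1, sd = 8))
    ch <- sample_cohort(spec)
    train <- subset_subjects(ch$dataset, 1:20)
    test <- subset_subjects(ch$dataset, 21:30)
    ctr <- center_dataset(train)
    pls1 <- fit_pls(ctr, 1)
    pcr1 <- fit_pcr(ctr, 1)
    err <- function(yh) mean(abs(yh - test$Y))
    if (err(predict(pls1, test$X)) < err(predict(pcr1, test$X)))
      wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("projected test scores track the planted loadings", {
  spec <- phantom_spec(subjects_per_group = c(40L, 40L, 40L), seed = 5L)
  ch <- sample_cohort(spec)
  train_idx <- seq(1, 120, by = 2)
  test_idx <- setdiff(1:120, train_idx)
  fit <- fit_pls(center_dataset(subset_subjects(ch$dataset, train_idx)), 3)
  sc <- project_scores(fit, ch$dataset$X[test_idx, ])
  truth <- ch$truth$loadings[test_idx, ]
  # each planted loading should be strongly tracked by some estimated score
  for (j in 1:3)
    expect_gt(max(abs(cor(truth[, j], sc))), 0.9)
})
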