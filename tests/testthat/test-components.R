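test_that("rank AUC equals exhaustive pair counting and handles extremes", {
  set.seed(50)
  scores <- rnorm(20)
  pos <- rep(c(TRUE, FALSE), 10)
  expect_equal(rank_auc(scores, pos), pair_count_auc(scores, pos))

  # ties counted as 1/2
  tied <- c(1, 1, 2, 2, 3)
  pt_ <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  expect_equal(rank_auc(tied, pt_), pair_count_auc(tied, pt_))

  # perfect separation
  expect_equal(rank_auc(c(1, 2, 3, 10, 11), c(F, F, F, T, T)), 1)
  # AUC is invariant under strictly monotone transforms
  expect_equal(rank_auc(exp(scores), pos), rank_auc(scores, pos))
  expect_equal(rank_auc(rank(scores), pos), rank_auc(scores, pos))
})

test_that("LOO LDA separates separable scores and not permuted labels", {
  set.seed(51)
  n <- 40
  scores <- cbind(c(rnorm(n, 5), rnorm(n, -5)), matrix(rnorm(2 * n * 4), 2 * n, 4))
  labels <- rep(c("pos", "neg"), each = n)
  res <- lda_loo_auc(scores, labels, c("pos", "neg"))
  expect_equal(res$auc, 1.0)
  expect_equal(res$top_components[1], 1L)
  expect_equal(res$auc, pair_count_auc(res$loo_scores, res$positive))

  # permuted labels: AUC near the Mann-Whitney null within 3 SE
  perm <- sample(labels)
  res_p <- lda_loo_auc(scores, perm, c("pos", "neg"))
  se_null <- sqrt((n + n + 1) / (12 * n * n))
  expect_lt(abs(res_p$auc - 0.5), 3 * se_null)

  expect_error(lda_loo_auc(scores, labels, c("pos", "missing")),
               "at least 2 subjects")
})

test_that("LDA weights agree with an independent reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(52)
  n <- 30
  Z <- cbind(rnorm(2 * n, rep(c(1, -1), each = n)),
             matrix(rnorm(2 * n * 3), 2 * n, 3))
  labels <- rep(c("a", "b"), each = n)
  res <- lda_loo_auc(Z, labels, c("a", "b"))
  ref <- MASS::lda(Z, grouping = labels)
  # directions are proportional (scaling conventions differ)
  cs <- abs(cor(res$lda_weights / apply(Z, 2, sd), as.vector(ref$scaling)))
  expect_gt(cs, 1 - 1e-6)
})

test_that("component ranking orders by |weight| with index tie-breaks", {
  expect_equal(rank_components(c(0.1, -0.9, 0.3)), c(2L, 3L, 1L))
  expect_equal(rank_components(rep(0.5, 7)), 1:5)
  set.seed(53)
  w <- rnorm(30)
  expect_equal(rank_components(w, k = 5), order(-abs(w))[1:5])
  expect_equal(rank_components(w, k = 50), order(-abs(w)))
})

test_that("greedy matching keeps the strongest pairs above threshold", {
  set.seed(54)
  maps <- matrix(rnorm(200 * 3), 200, 3)

  # identical sets: perfect matching with correlation 1
  mt <- match_components(maps, maps)
  expect_equal(nrow(mt$pairs), 3L)
  expect_equal(mt$pairs$comp_i, mt$pairs$comp_j)
  expect_true(all(abs(mt$pairs$correlation - 1) < 1e-12))

  # mutually decorrelated sets: no matches (columns orthogonal to each
  # other and to the constant, so Pearson correlations are exactly 0)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(200 * 6), 200, 6))))[, -1]
  mt0 <- match_components(Q[, 1:3], Q[, 4:6])
  expect_equal(nrow(mt0$pairs), 0L)
  expect_equal(mt0$unmatched_i, 1:3)

  # symmetric in its arguments: same pair set either way round
  maps_b <- maps[, c(2, 1, 3)] + matrix(rnorm(600, sd = 0.3), 200, 3)
  m_ab <- match_components(maps, maps_b)
  m_ba <- match_components(maps_b, maps)
  expect_equal(sort(m_ab$pairs$correlation), sort(m_ba$pairs$correlation),
               tolerance = 1e-12)
  ab <- m_ab$pairs[order(m_ab$pairs$comp_i), c("comp_i", "comp_j")]
  ba <- m_ba$pairs[order(m_ba$pairs$comp_j), c("comp_j", "comp_i")]
  expect_equal(unname(as.matrix(ab)), unname(as.matrix(ba)))
})

test_that("competing matches resolve exactly as exhaustive enumeration", {
  # construct maps whose correlation matrix has two candidates above
  # threshold for component 1; the greedy rule must take the strongest
  set.seed(55)
  base <- matrix(rnorm(500 * 3), 500, 3)
  a1 <- base[, 1]
  b1 <- 0.8 * a1 + 0.6 * rnorm(500)          # strong partner
  b2 <- 0.65 * a1 + sqrt(1 - 0.65^2) * rnorm(500)  # weaker competitor
  maps_i <- cbind(a1, base[, 2], base[, 3])
  maps_j <- cbind(b2, b1, base[, 3])
  mt <- match_components(maps_i, maps_j, threshold = 0.5)

  # exhaustive enumeration over all one-to-one assignments, greedy order
  R <- abs(cor(maps_i, maps_j))
  greedy <- function(R, thr) {
    out <- NULL
    while (any(R > thr, na.rm = TRUE)) {
      ij <- which(R == max(R, na.rm = TRUE), arr.ind = TRUE)[1, ]
      out <- rbind(out, ij)
      R[ij[1], ] <- NA; R[, ij[2]] <- NA
    }
    out
  }
  orc <- greedy(R, 0.5)
  expect_equal(unname(as.matrix(mt$pairs[, 1:2])), unname(orc))
  # the strongest candidate pair for a1 is (1 -> 2), not (1 -> 1)
  expect_true(any(mt$pairs$comp_i == 1 & mt$pairs$comp_j == 2))
  # matches never exceed the smaller component count
  expect_lte(nrow(mt$pairs), 3L)
})

test_that("reproducibility counts reward matched top components", {
  set.seed(56)
  maps <- matrix(rnorm(300 * 4), 300, 4)
  rep1 <- list(maps = maps, top = c(1L, 3L))

  # identical repeats: every top component counted in all repeats
  rc <- reproducibility_counts(list(rep1, rep1, rep1))
  expect_equal(rc$counts, c(3L, 0L, 3L, 0L))

  # disjoint maps: nothing matches
  Q <- qr.Q(qr(matrix(rnorm(300 * 8), 300, 8)))
  rep_a <- list(maps = Q[, 1:4], top = 1:2)
  rep_b <- list(maps = Q[, 5:8], top = 1:2)
  rc0 <- reproducibility_counts(list(rep_a, rep_b))
  expect_equal(rc0$counts, c(1L, 1L, 0L, 0L))  # only the reference itself
  expect_equal(rc0$unmatched_other[[2]], 1:2)

  # permuted copy: matching follows the permutation, top status respected
  rep_c <- list(maps = maps[, c(2, 1, 4, 3)], top = c(2L, 4L))
  rc2 <- reproducibility_counts(list(rep1, rep_c))
  expect_equal(rc2$counts, c(2L, 0L, 2L, 0L))
  expect_error(reproducibility_counts(list(rep1)), "at least 2")
})

test_that("network extraction isolates clusters like a flood-fill oracle", {
  grid <- c(12L, 12L, 12L)
  vol <- array(0, grid)
  vol[2:5, 2:5, 2:5] <- 1       # blob A (positive)
  vol[8:11, 8:11, 8:11] <- -1   # blob B (anticorrelated)
  lab <- extract_network(vol, quantile_threshold = 0.95, opening_radius = 1)
  expect_equal(attr(lab, "n_clusters"), 2L)
  expect_equal(sort(unname(attr(lab, "signs"))), c(-1, 1))

  # both blobs survive the opening (minus their corners) and stay separate
  expect_setequal(unique(as.vector(lab[2:5, 2:5, 2:5])), c(0L, lab[3, 3, 3]))
  expect_setequal(unique(as.vector(lab[8:11, 8:11, 8:11])), c(0L, lab[9, 9, 9]))
  expect_gt(lab[3, 3, 3], 0L)
  expect_gt(lab[9, 9, 9], 0L)
  expect_false(lab[3, 3, 3] == lab[9, 9, 9])
  expect_true(all(lab[6:7, , ] == 0))

  # one large blob: a single cluster
  one <- array(0, grid); one[3:9, 3:9, 3:9] <- 2
  lab1 <- extract_network(one, 0.85, 1)
  expect_equal(attr(lab1, "n_clusters"), 1L)

  # isolated single-voxel spikes are removed by the opening
  spikes <- array(0, grid)
  spikes[cbind(c(2, 6, 10), c(2, 6, 10), c(2, 6, 10))] <- 5
  expect_warning(lab_s <- extract_network(spikes, 0.999, 1), "empty")
  expect_equal(attr(lab_s, "n_clusters"), 0L)
  expect_error(extract_network(vol, 1.2, 1), "quantile_threshold")
})

test_that("opening removes sub-structuring-element features only", {
  grid <- c(10L, 10L, 10L)
  bin <- array(FALSE, grid)
  bin[3:7, 3:7, 3:7] <- TRUE   # big cube survives
  bin[9, 9, 9] <- TRUE         # lone voxel dies
  opened <- binary_opening(bin, radius = 1)
  expect_true(all(opened[4:6, 4:6, 4:6]))
  expect_false(opened[9, 9, 9])
  expect_true(sum(opened) <= sum(bin))
})
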