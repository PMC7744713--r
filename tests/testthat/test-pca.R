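test_that("PCA bookkeeping: variance, cos2 and contribution normalizations", {
  set.seed(3)
  X <- matrix(rnorm(24 * 10), 24, 10,
              dimnames = list(sprintf("c%02d", 1:24), paste0("f", 1:10)))
  p <- run_pca(X, scale = TRUE)
  expect_equal(sum(p$percent_variance), 100, tolerance = 1e-9)
  expect_equal(unname(rowSums(p$cos2)), rep(1, 24), tolerance = 1e-9)
  expect_equal(unname(colSums(p$contributions)),
               rep(100, ncol(p$contributions)), tolerance = 1e-9)
  # correlation PCA: eigenvalues sum to the number of retained features
  expect_equal(sum(p$eigenvalues), 10, tolerance = 1e-9)
  # cos2 over the first two dims is the score-plot coloring quantity
  cc <- cos2_conditions(p, 1:2)
  expect_true(all(cc >= 0 & cc <= 1))
  expect_equal(unname(cc),
               unname(rowSums(p$scores[, 1:2]^2) / rowSums(p$scores^2)))
})

test_that("rank-1 data loads entirely on the first component", {
  t_vec <- seq(-1, 1, length.out = 8)
  X <- cbind(a = 3 * t_vec, b = -2 * t_vec)
  rownames(X) <- paste0("c", 1:8)
  p <- run_pca(X, scale = TRUE)
  expect_equal(unname(p$percent_variance[1]), 100, tolerance = 1e-9)
  expect_length(p$eigenvalues, 1)
})

test_that("eigenvalues match an independent covariance eigendecomposition", {
  X <- matrix(c(1, 2, 4,
                2, 1, 0.5), 3, 2,
              dimnames = list(c("c1", "c2", "c3"), c("f1", "f2")))
  p <- run_pca(X, scale = FALSE)
  oracle <- eigen(stats::cov(X), symmetric = TRUE)$values
  expect_equal(unname(p$eigenvalues), oracle[oracle > 1e-12], tolerance = 1e-10)

  set.seed(11)
  Y <- matrix(rnorm(7 * 5), 7, 5, dimnames = list(paste0("c", 1:7), paste0("f", 1:5)))
  py <- run_pca(Y, scale = FALSE)
  ev <- eigen(stats::cov(Y), symmetric = TRUE)$values
  expect_equal(unname(py$eigenvalues), ev[seq_along(py$eigenvalues)],
               tolerance = 1e-9)
})

test_that("scaling inside run_pca equals pre-standardized input", {
  set.seed(4)
  X <- matrix(rnorm(12 * 6, sd = rep(c(1, 10, 100), each = 24)), 12, 6,
              dimnames = list(paste0("c", 1:12), paste0("f", 1:6)))
  a <- run_pca(X, scale = TRUE)
  b <- run_pca(standardize_features(X), scale = FALSE)
  expect_equal(a$eigenvalues, b$eigenvalues, tolerance = 1e-9)
  expect_equal(a$scores, b$scores, tolerance = 1e-9)
})

test_that("contributions are invariant to data sign flips", {
  set.seed(5)
  X <- matrix(rnorm(10 * 4), 10, 4,
              dimnames = list(paste0("c", 1:10), paste0("f", 1:4)))
  a <- run_pca(X, scale = TRUE)
  b <- run_pca(-X, scale = TRUE)
  expect_equal(a$contributions, b$contributions, tolerance = 1e-9)
  expect_equal(a$eigenvalues, b$eigenvalues, tolerance = 1e-9)
})

test_that("pathway aggregation partitions and averages contributions", {
  set.seed(6)
  X <- matrix(rnorm(8 * 4), 8, 4)
  rownames(X) <- paste0("c", 1:8)
  fm <- feature_matrix(X, data.frame(
    feature_id = paste0("f", 1:4), omic_type = "flux",
    group = c("solo", "trio", "trio", "trio")))
  p <- run_pca(fm, scale = TRUE)
  agg_sum <- pathway_aggregate(p, dims = 1:2, stat = "sum")
  # partition: group sums over dims {1,2} total 100 per component
  expect_equal(sum(agg_sum$value), 200, tolerance = 1e-9)
  per_feature <- rowSums(p$contributions[, 1:2])
  expect_equal(agg_sum$value[agg_sum$group == "solo"],
               unname(per_feature["f1"]), tolerance = 1e-12)
  agg_mean <- pathway_aggregate(p, dims = 1:2, stat = "mean")
  # singleton group: mean equals the lone feature's summed contribution
  expect_equal(agg_mean$value[agg_mean$group == "solo"],
               unname(per_feature["f1"]), tolerance = 1e-12)
  expect_equal(agg_mean$value[agg_mean$group == "trio"],
               mean(per_feature[2:4]), tolerance = 1e-12)
  expect_equal(agg_mean$n_features[agg_mean$group == "trio"], 3L)
  expect_error(pathway_aggregate(p, dims = integer(0)), "nonempty")
})

test_that("PC-feature correlations behave on constructed cases", {
  set.seed(7)
  X <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(paste0("c", 1:12), paste0("f", 1:5)))
  p <- run_pca(X, scale = TRUE)
  # a feature equal to the scores correlates perfectly
  r1 <- pc_feature_correlation(p, 1, p$scores[, 1])
  expect_equal(r1$r, 1, tolerance = 1e-12)
  expect_equal(r1$ci_high, 1)

  # one dominant feature: PC1 coordinates track it almost perfectly
  dom <- rnorm(12, sd = 50)
  Xd <- cbind(big = dom, matrix(rnorm(12 * 4, sd = 0.01), 12, 4))
  rownames(Xd) <- paste0("c", 1:12)
  colnames(Xd)[2:5] <- paste0("n", 1:4)
  pd <- run_pca(Xd, scale = FALSE)
  expect_gt(abs(pc_feature_correlation(pd, 1, Xd[, "big"])$r), 0.99)

  # Gram-Schmidt: a feature orthogonalized against the scores gives r ~ 0
  # with a CI bracketing 0
  y <- rnorm(12)
  s1 <- p$scores[, 1]
  y_orth <- y - sum(y * (s1 - mean(s1))) / sum((s1 - mean(s1))^2) * (s1 - mean(s1))
  ro <- pc_feature_correlation(p, 1, y_orth)
  expect_equal(ro$r, 0, tolerance = 1e-10)
  expect_lt(ro$ci_low, 0)
  expect_gt(ro$ci_high, 0)
})
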