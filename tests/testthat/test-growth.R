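test_that("pearson_ci reproduces hand and brute-force values", {
  x <- c(1, 5, 3, 7, 2, 9)
  expect_equal(pearson_ci(x, x)$r, 1)
  expect_equal(pearson_ci(x, x)$ci_high, 1)
  expect_equal(pearson_ci(x, -x)$r, -1)
  expect_equal(pearson_ci(x, -x)$ci_low, -1)

  # r of the 3-point pattern (1,2,3) vs (1,2,4), duplicated to satisfy n >= 4
  r <- pearson_ci(rep(c(1, 2, 3), 2), rep(c(1, 2, 4), 2))$r
  expect_equal(r, 3 / (2 * sqrt(7 / 3)), tolerance = 1e-9)
  expect_equal(r, 0.981980506, tolerance = 1e-6)

  expect_error(pearson_ci(1:3, c(1, 2, 4)), "n >= 4")
  expect_error(pearson_ci(rep(1, 5), 1:5), "constant")

  # brute-force oracle: covariance / sd formula and textbook Fisher interval
  set.seed(8)
  for (i in 1:300) {
    n <- sample(4:30, 1)
    a <- rnorm(n); b <- rnorm(n)
    ci <- pearson_ci(a, b)
    r_brute <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(ci$r, r_brute, tolerance = 1e-12)
    half <- qnorm(0.975) / sqrt(n - 3)
    expect_equal(ci$ci_low, tanh(atanh(r_brute) - half), tolerance = 1e-12)
    expect_equal(ci$ci_high, tanh(atanh(r_brute) + half), tolerance = 1e-12)
  }

  # CI width shrinks with n at fixed r
  widths <- vapply(c(5, 10, 20, 50), function(n) {
    a <- seq_len(n); b <- a + rep(c(-1, 1), length.out = n)
    ci <- pearson_ci(a, b)
    ci$ci_high - ci$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("feature-growth correlation recovers planted orderings", {
  n <- 12
  set.seed(9)
  y <- runif(n, 0.01, 0.2)
  yc <- y - mean(y)
  e <- rnorm(n); ec <- e - sum(e * yc) / sum(yc^2) * yc  # orthogonal to y
  mix <- function(rho) {
    v <- rho * yc / sd(yc) + sqrt(1 - rho^2) * ec / sd(ec)
    v
  }
  X <- cbind(full = y, pos8 = mix(0.8), zero = mix(0), neg8 = mix(-0.8),
             negfull = -2 * y)
  rownames(X) <- sprintf("c%02d", 1:n)
  fm <- feature_matrix(X, data.frame(feature_id = colnames(X),
                                     omic_type = "flux",
                                     group = c("g1", "g1", "g2", "g2", "g3")))
  growth <- stats::setNames(y, rownames(X))
  recs <- correlate_features(fm, growth)
  expect_equal(recs$feature_id[1:2], c("full", "negfull"))  # |r| = 1 first
  expect_equal(recs$feature_id[5], "zero")
  expect_equal(recs$r[recs$feature_id == "pos8"], 0.8, tolerance = 1e-9)
  expect_equal(recs$r[recs$feature_id == "neg8"], -0.8, tolerance = 1e-9)
  expect_true(all(recs$n == n))

  tops <- top_correlates(recs, 2)
  expect_equal(tops$positive$feature_id[1], "full")
  expect_equal(tops$negative$feature_id[1], "negfull")

  # growth on a 12-of-24 subset restricts every record to n = 12
  X24 <- matrix(rnorm(24 * 3), 24, 3,
                dimnames = list(sprintf("c%02d", 1:24), c("a", "b", "c")))
  fm24 <- feature_matrix(X24, data.frame(feature_id = c("a", "b", "c"),
                                         omic_type = "flux", group = ""))
  g12 <- stats::setNames(runif(12), sprintf("c%02d", seq(1, 24, by = 2)))
  r24 <- correlate_features(fm24, g12)
  expect_true(all(r24$n == 12))
  expect_error(correlate_features(fm24, g12[1:3]), ">= 4 conditions")
})

test_that("subsystem aggregation: mean |r| and half-open PCC bins", {
  recs <- data.frame(
    feature_id = paste0("f", 1:6), omic_type = "flux",
    group = c("g1", "g1", "g2", "g2", "g2", ""),
    r = c(0.5, -0.5, 0.1, 0.29, -0.1, 0.65),
    ci_low = -1, ci_high = 1, n = 12)
  m <- aggregate_by_subsystem(recs, "mean_abs")
  expect_equal(m$mean_abs_r[m$group == "g1"], 0.5)
  expect_equal(m$mean_abs_r[m$group == "g2"], mean(c(0.1, 0.29, 0.1)))
  expect_true("unassigned" %in% m$group)

  b <- aggregate_by_subsystem(recs, "bin_counts")
  # boundary convention: r = 0.1 falls in [0.1, 0.3[, r = -0.1 in [-0.1, 0.1[
  expect_equal(b[b$group == "g2", "[0.1,0.3["], 2)
  expect_equal(b[b$group == "g2", "[-0.1,0.1["], 1)
  expect_equal(b[b$group == "g1", "[-0.3,-0.1["], 0)
  # bin totals per group equal the group's record count (all r in range here)
  counts <- rowSums(b[, -1])
  expect_equal(unname(counts[b$group == "g2"]), 3)
  expect_error(aggregate_by_subsystem(recs, "bin_counts", bins = c(0.3, 0.1)),
               "strictly increasing")
})

test_that("LASSO shrinks fully at large penalties and meets OLS at zero", {
  set.seed(10)
  n <- 20; p <- 3
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("c%02d", 1:n), c("x1", "x2", "x3")))
  y <- stats::setNames(0.05 + 2 * X[, 1] - X[, 3] + rnorm(n, sd = 0.1),
                       rownames(X))
  fm <- feature_matrix(X, data.frame(feature_id = colnames(X),
                                     omic_type = "flux", group = ""))
  # heavy penalty: everything shrinks to zero, intercept = mean growth
  big <- fit_lasso(fm, y, lambda_grid = c(1000, 999, 998), lambda_fixed = 1000)
  expect_true(all(big$coefficients == 0))
  expect_equal(big$intercept, mean(y), tolerance = 1e-8)

  # lambda = 0 matches the normal-equations solution
  ols <- fit_lasso(fm, y, lambda_fixed = 0)
  Xd <- cbind(1, X)
  beta_ne <- solve(crossprod(Xd), crossprod(Xd, y))
  expect_lt(max(abs(c(ols$intercept, ols$coefficients) - beta_ne[, 1])), 1e-8)

  # in the low-dimensional regime the nonzero count is nonincreasing in
  # lambda along the default grid
  cvfit <- fit_lasso(fm, y, seed = 1)
  expect_true(cvfit$path_monotone)
  expect_equal(cvfit$path_nonzero[1], 0)
})

test_that("cross-validated LASSO recovers a planted sparse support", {
  hits <- vapply(1:10, function(s) {
    set.seed(100 + s)
    X <- matrix(rnorm(24 * 50), 24, 50,
                dimnames = list(sprintf("c%02d", 1:24), sprintf("f%02d", 1:50)))
    fm <- feature_matrix(X, data.frame(feature_id = colnames(X),
                                       omic_type = "transcript", group = ""))
    sim <- simulate_growth(fm, support_size = 3, snr = 10, seed = 100 + s)
    fit <- fit_lasso(fm, sim$growth, seed = s)
    truth <- names(sim$beta)[sim$beta != 0]
    all(truth %in% fit$nonzero$feature_id)
  }, logical(1))
  expect_gte(sum(hits), 9)

  # nonzero count along the grid is nonincreasing in lambda on this fixture
  set.seed(100)
  X <- matrix(rnorm(24 * 50), 24, 50,
              dimnames = list(sprintf("c%02d", 1:24), sprintf("f%02d", 1:50)))
  fm <- feature_matrix(X, data.frame(feature_id = colnames(X),
                                     omic_type = "transcript", group = ""))
  sim <- simulate_growth(fm, support_size = 3, snr = 10, seed = 42)
  fit <- fit_lasso(fm, sim$growth, seed = 1)
  # the largest grid lambda (lambda_max) shrinks everything to zero
  expect_equal(fit$path_nonzero[1], 0)
})
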