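test_that("expression tables parse per-condition profiles and reject bad cells", {
  path <- system.file("extdata", "mini_expression.csv", package = "cyanoflux")
  profs <- read_expression_table(path)
  expect_length(profs, 3)
  expect_named(profs, c("ctrl", "highlight", "dark"))
  expect_equal(unname(profs$ctrl$values["gA"]), 10)
  expect_length(profs$dark$values, 4)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("gene_id,c1,c2", "g1,1,2", "g2,-1.2,3"), bad)
  expect_error(read_expression_table(bad), "negative.*row 2.*g2.*c1")
  writeLines(c("gene_id,c1", "g1,1", "g1,2"), bad)
  expect_error(read_expression_table(bad), "duplicate gene")
  unlink(bad)
})

test_that("fold changes follow the pseudocount ratio formula", {
  ctrl <- expr_profile("ctrl", c(g1 = 10, g2 = 0, g3 = 4))
  expect_equal(fold_changes(ctrl, ctrl)$theta,
               c(g1 = 1, g2 = 1, g3 = 1))
  hi <- expr_profile("hi", c(g1 = 20, g2 = 5, g3 = 8))
  fc <- fold_changes(hi, ctrl, epsilon = 1e-9)
  expect_equal(unname(fc$theta["g1"]), 2, tolerance = 1e-6)
  expect_equal(unname(fold_changes(hi, ctrl, epsilon = 1)$theta["g2"]), 6)
  expect_error(
    fold_changes(expr_profile("x", c(g1 = 1, gZ = 2)), ctrl),
    "mismatched gene sets.*gZ")
})

test_that("reaction activity folds fold-changes through GPRs", {
  m <- make_toy_model("photo")
  fc <- list(condition_id = "c",
             theta = c(psbA = 2, psbD = 0.5, psaA = 3, psaB = 4,
                       flv1 = 0.2, flv3 = 5))
  act <- reaction_activity(fc, m)
  expect_equal(unname(act$theta_r["PSII"]), 0.5)   # and -> min
  expect_equal(unname(act$theta_r["PSI"]), 3)      # and -> min
  expect_equal(unname(act$theta_r["MEHLER"]), 5)   # or -> max
  expect_equal(unname(act$theta_r["CBB"]), 1)      # genes absent -> neutral
  expect_equal(unname(act$theta_r["ATPM"]), 1)     # empty GPR -> 1
  expect_setequal(act$neutral_genes, c("rbcL", "rbcS"))
})

test_that("bound modulation scales symmetrically in fold-change and gamma", {
  expect_equal(bound_scale_factor(1, gamma = 1), 1)
  expect_equal(bound_scale_factor(exp(1), gamma = 1), 2)
  expect_equal(bound_scale_factor(exp(-1), gamma = 1), 0.5)
  expect_error(bound_scale_factor(0), "theta")

  # monotone nondecreasing in theta; gamma = 0 is a no-op
  thetas <- exp(seq(-3, 3, length.out = 61))
  f <- bound_scale_factor(thetas, gamma = 2)
  expect_false(is.unsorted(f))
  expect_equal(bound_scale_factor(thetas, gamma = 0), rep(1, 61))
  # symmetry: f(theta) * f(1/theta) = 1
  expect_equal(f * bound_scale_factor(1 / thetas, gamma = 2), rep(1, 61))

  m <- make_toy_model("photo")
  act <- list(condition_id = "c",
              theta_r = stats::setNames(rep(exp(1), n_reactions(m)),
                                        m$reactions$id))
  m2 <- modulate_bounds(m, act, integration_settings(gamma = 1))
  expect_equal(m2$reactions$lower_bound, 2 * m$reactions$lower_bound)
  expect_equal(m2$reactions$upper_bound, 2 * m$reactions$upper_bound)
  # bound signs never flip, ordering preserved
  expect_true(all(sign(m2$reactions$lower_bound) == sign(m$reactions$lower_bound)))
  expect_true(all(m2$reactions$lower_bound <= m2$reactions$upper_bound))
  # neutral activity leaves the model untouched
  act1 <- list(condition_id = "c",
               theta_r = stats::setNames(rep(1, n_reactions(m)), m$reactions$id))
  expect_equal(modulate_bounds(m, act1), m)
})

test_that("condition overrides take precedence over expression modulation", {
  m <- make_toy_model("photo")
  genes <- m$genes
  ctrl <- expr_profile("ctrl", stats::setNames(rep(10, length(genes)), genes))
  hot <- expr_profile("hot", stats::setNames(rep(50, length(genes)), genes))
  specs <- list(hot = condition_spec(
    "hot", data.frame(reaction_id = "EX_PHOTON", lower_bound = 0, upper_bound = 0)))
  mods <- condition_models(m, list(ctrl = ctrl, hot = hot), "ctrl", specs)
  # despite 5x up-regulation everywhere, the explicit photon override wins
  expect_equal(unname(reaction_bounds(mods$hot, "EX_PHOTON")), c(0, 0))
  # control model is the base model (theta = 1) with no overrides
  expect_equal(mods$ctrl, m)
})
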