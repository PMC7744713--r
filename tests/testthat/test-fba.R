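test_that("plain FBA solves the hand-solved chain and degenerate cases", {
  m <- make_toy_model("minimal")
  res <- fba_lp(m, "BIOMASS")
  expect_equal(res$optimum, 10, tolerance = 1e-8)
  expect_equal(unname(res$v[c("EX_A", "CONV", "BIOMASS")]), c(-10, 10, 10),
               tolerance = 1e-7)
  expect_equal(max(abs(as.numeric(m$S %*% res$v))), 0, tolerance = 1e-9)

  # objective fixed at (0, 0) -> optimum 0
  m0 <- apply_condition(m, condition_spec(
    "z", data.frame(reaction_id = "BIOMASS", lower_bound = 0, upper_bound = 0)))
  expect_equal(fba_lp(m0, "BIOMASS")$optimum, 0, tolerance = 1e-10)

  expect_error(fba_lp(make_infeasible_model(), "OUT"), "infeasible")
  expect_error(fba_lp(make_unbounded_model(), "FWD"), "unbounded")
})

test_that("bilevel solve is lexicographic: Z1, then Z2, then minimum norm", {
  p <- make_toy_model("photo")
  fd <- regularized_bilevel_fba(p, objective_pair("BIOMASS", "ATPM"))
  # hand-solved: photons 100, co2 10 -> biomass 10 (Z1); the 20 spare
  # photons drive one extra PSII+PSI turn -> 10 ATP to maintenance (Z2)
  expect_equal(fd$Z1, 10, tolerance = 1e-6)
  expect_equal(fd$Z2, 10, tolerance = 1e-5)
  expect_equal(unname(fd$v["BIOMASS"]), 10, tolerance = 1e-5)
  expect_equal(unname(fd$v["EX_PHOTON"]), -100, tolerance = 1e-4)

  fd_psi <- regularized_bilevel_fba(p, objective_pair("BIOMASS", "PSI"))
  expect_equal(fd_psi$Z2, 50, tolerance = 1e-5)

  # unique-optimum chain: stage 3 returns the stage-1 LP point
  m <- make_toy_model("minimal")
  fd_m <- regularized_bilevel_fba(m, objective_pair("BIOMASS", "SINK"))
  lp <- fba_lp(m, "BIOMASS")
  expect_equal(fd_m$v, lp$v, tolerance = 1e-6)
})

test_that("the L2 regularizer splits degenerate parallel routes equally", {
  pp2 <- make_parallel_paths_model(2, uptake = 10)
  fd2 <- regularized_bilevel_fba(pp2, objective_pair("BIOMASS", "EX_A"))
  expect_equal(unname(fd2$v[c("PATH1", "PATH2")]), c(5, 5), tolerance = 1e-6)

  pp4 <- make_parallel_paths_model(4, uptake = 12)
  fd4 <- regularized_bilevel_fba(pp4, objective_pair("BIOMASS", "EX_A"))
  expect_equal(unname(fd4$v[paste0("PATH", 1:4)]), rep(3, 4), tolerance = 1e-6)

  # the unregularized LP is genuinely degenerate: perturbed objectives find
  # two distinct optima with the same biomass
  S <- as.matrix(pp2$S); lb <- pp2$reactions$lower_bound
  ub <- pp2$reactions$upper_bound
  bio <- as.numeric(pp2$reactions$id == "BIOMASS")
  p1 <- as.numeric(pp2$reactions$id == "PATH1")
  a <- solve_lp(S, lb, ub, bio + 1e-3 * p1)
  b <- solve_lp(S, lb, ub, bio - 1e-3 * p1)
  expect_equal(sum(bio * a$v), sum(bio * b$v), tolerance = 1e-6)
  expect_gt(max(abs(a$v - b$v)), 5)
})

test_that("dark conditions force zero biomass and photosystem flux", {
  dark <- apply_condition(make_toy_model("photo"), condition_spec(
    "dark", data.frame(reaction_id = "EX_PHOTON", lower_bound = 0, upper_bound = 0)))
  for (sec in c("ATPM", "PSI", "PSII")) {
    fd <- regularized_bilevel_fba(dark, objective_pair("BIOMASS", sec))
    expect_equal(fd$Z1, 0, tolerance = 1e-8)
    expect_equal(unname(snap_fluxes(fd$v[c("BIOMASS", "PSI", "PSII")])),
                 c(0, 0, 0))
  }
})

test_that("stage-3 fluxes match an independent dense KKT enumeration", {
  m <- make_toy_model("minimal")
  pair <- objective_pair("BIOMASS", "SINK")
  fd <- regularized_bilevel_fba(m, pair)
  oracle <- kkt_stage3(m, pair)
  expect_equal(unname(fd$v), oracle, tolerance = 1e-6)

  pp <- make_parallel_paths_model(2)
  pairp <- objective_pair("BIOMASS", "EX_A")
  fdp <- regularized_bilevel_fba(pp, pairp)
  expect_equal(unname(fdp$v), kkt_stage3(pp, pairp), tolerance = 1e-6)
})

test_that("no feasible alternative beats the regularized flux norm", {
  pp <- make_parallel_paths_model(2, uptake = 10)
  fd <- regularized_bilevel_fba(pp, objective_pair("BIOMASS", "EX_A"))
  # feasible alternates: any split (t, 10 - t) of the routes
  set.seed(7)
  for (t in runif(25, 0, 10)) {
    v_alt <- c(-10, t, 10 - t, 10)
    expect_true(sqrt(sum(fd$v^2)) <= sqrt(sum(v_alt^2)) + 1e-6)
  }
})

test_that("relaxing the biomass fraction never decreases the secondary optimum", {
  p <- make_toy_model("photo")
  z2 <- vapply(c(1, 0.9, 0.7, 0.5), function(f) {
    regularized_bilevel_fba(p, objective_pair("BIOMASS", "ATPM"),
                            solver_settings(fraction_of_optimum = f))$Z2
  }, numeric(1))
  expect_true(all(diff(z2) >= -1e-8))
})

test_that("penalized single-QP mode respects the primary constraint", {
  p <- make_toy_model("photo")
  fd <- regularized_bilevel_fba(p, objective_pair("BIOMASS", "ATPM"),
                                solver_settings(mode = "penalized", lambda = 1e-4))
  expect_equal(unname(fd$v["BIOMASS"]), 10, tolerance = 1e-4)
  expect_gt(fd$Z2, 9)  # secondary pushed close to its optimum
})

test_that("batch flux matrices keep shape, determinism and error context", {
  m <- make_toy_model("photo")
  dim_m <- apply_condition(m, condition_spec(
    "dim", data.frame(reaction_id = "EX_PHOTON", lower_bound = -40, upper_bound = 0)))
  models <- list(c1 = m, c2 = dim_m, c3 = m)
  fm <- batch_flux_matrix(models, objective_pair("BIOMASS", "ATPM"))
  expect_equal(dim(fm$fluxes), c(3, n_reactions(m)))
  expect_equal(rownames(fm$fluxes), c("c1", "c2", "c3"))
  expect_equal(fm$fluxes["c1", ], fm$fluxes["c3", ])  # identical models
  expect_lt(fm$fluxes["c2", "BIOMASS"], fm$fluxes["c1", "BIOMASS"])
  # mass balance on every row
  for (i in 1:3)
    expect_lt(max(abs(as.numeric(m$S %*% fm$raw[i, ]))), 1e-9)

  models$c2 <- make_infeasible_model()
  models$c2$reactions$id <- m$reactions$id[seq_len(3)]
  expect_error(batch_flux_matrix(models, objective_pair("BIOMASS", "ATPM")),
               "reaction id set")
  bad <- apply_condition(m, condition_spec("bad", data.frame(
    reaction_id = "ATPM", lower_bound = 500, upper_bound = 1000)))
  expect_error(
    batch_flux_matrix(list(c1 = m, broken = bad),
                      objective_pair("BIOMASS", "ATPM")),
    "condition 'broken'")
})
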