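# Independent oracles and small fixture builders shared across tests.

# Brute-force KKT solve of  min 1/2 ||v||^2 - d'v  s.t.  E v = e,
# G v >= h  by enumerating active inequality sets and checking primal and
# dual feasibility of the stationarity system. Exponential in the number
# of inequalities -- for toy networks only. Independent of the package's
# null-space/active-set route.
kkt_qp_oracle <- function(E, e, G, h, d = NULL) {
  n <- ncol(G)
  if (is.null(d)) d <- rep(0, n)
  E <- as.matrix(E)
  m_ineq <- nrow(G)
  rank_E <- if (nrow(E)) qr(E)$rank else 0
  max_active <- n - rank_E
  best <- NULL
  for (size in 0:max_active) {
    for (act in combn_list(m_ineq, size)) {
      A <- rbind(E, G[act, , drop = FALSE])
      b <- c(e, h[act])
      # stationarity: v = d + t(A) mult ; constraints: A v = b
      M <- A %*% t(A)
      mult <- tryCatch(solve(M, b - A %*% d), error = function(err) NULL)
      if (is.null(mult)) next
      v <- d + as.numeric(t(A) %*% mult)
      if (any(G %*% v < h - 1e-8)) next
      mu <- mult[seq_len(size) + nrow(E)]
      if (length(mu) && any(mu < -1e-8)) next
      obj <- 0.5 * sum(v^2) - sum(d * v)
      if (is.null(best) || obj < best$obj - 1e-12) best <- list(v = v, obj = obj)
    }
  }
  if (is.null(best)) stop("KKT oracle found no feasible stationary point")
  best$v
}

combn_list <- function(m, k) {
  if (k == 0) return(list(integer(0)))
  apply(utils::combn(m, k), 2, identity, simplify = FALSE)
}

# KKT oracle applied to a model's stage-3 problem (given the staged optima)
kkt_stage3 <- function(model, pair, f = 1, eps2 = 1e-6, tol_feas = 1e-9,
                       Z1 = NULL, Z2 = NULL) {
  S <- as.matrix(model$S)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  n <- length(lb)
  c1 <- as.numeric(model$reactions$id == pair$primary)
  c2 <- as.numeric(model$reactions$id == pair$secondary)
  if (is.null(Z1)) Z1 <- solve_lp(S, lb, ub, c1)$optimum
  if (is.null(Z2))
    Z2 <- solve_lp(S, lb, ub, c2, Aineq = matrix(c1, 1),
                   bineq = f * Z1 - tol_feas * max(1, abs(Z1)))$optimum
  G <- rbind(diag(n), -diag(n), c1, c2)
  h <- c(lb, -ub, f * Z1 - tol_feas * max(1, abs(Z1)), Z2 - eps2)
  kkt_qp_oracle(S, rep(0, nrow(S)), G, h)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# tiny infeasible model: conversion forced on, uptake forbidden
make_infeasible_model <- function() {
  met <- data.frame(id = c("A", "B"), name = "", compartment = "c")
  rxn <- data.frame(id = c("EX_A", "CONV", "OUT"), name = "",
                    subsystem = "", lower_bound = c(0, 5, 0),
                    upper_bound = c(0, 1000, 1000), gpr = "",
                    objective_coefficient = c(0, 0, 1))
  S <- rbind(A = c(-1, -1, 0), B = c(0, 1, -1))
  metabolic_model("infeasible_toy", met, rxn, character(0), S)
}

# internal loop with an unbounded cycle
make_unbounded_model <- function() {
  met <- data.frame(id = c("A", "B"), name = "", compartment = "c")
  rxn <- data.frame(id = c("FWD", "BACK"), name = "", subsystem = "",
                    lower_bound = c(0, 0), upper_bound = c(Inf, Inf),
                    gpr = "", objective_coefficient = c(1, 0))
  S <- rbind(A = c(-1, 1), B = c(1, -1))
  metabolic_model("loop_toy", met, rxn, character(0), S)
}

expr_profile <- function(condition_id, values) {
  list(condition_id = condition_id, values = values)
}
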