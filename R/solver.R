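# Dense LP/QP solves on the flux polytope {v : S v = 0, lb <= v <= ub,
# A_ineq v >= b_ineq}. The QP engine is quadprog's dual active-set method
# (strictly convex objectives, exact within floating point). Equality
# constraints (mass balance plus any lb == ub fixed fluxes) are eliminated
# first by an orthonormal null-space reduction, leaving an inequality-only
# QP in the degrees of freedom — much better conditioned than feeding the
# equalities to the active-set method directly, and immune to the
# degenerate-vertex failures that arise when a condition pins most fluxes
# to zero. Linear programs are solved by exact quadratic regularization:
# for a bounded polyhedron there is a finite M* such that the minimizer of
# 1/2 ||v||^2 - M c'v for any M >= M* is the minimum-norm point of the LP
# optimal face, with c'v exactly the LP optimum (Mangasarian & Meyer 1979).
# M is escalated until the objective value stabilizes, certifying M >= M*.

.BIG_BOUND <- 1e6

# Reduce the polytope to its degrees of freedom.
# Returns x0 (particular solution of the equality system), N (orthonormal
# null-space basis, possibly 0 columns), and the inequality system in z.
qp_reduce <- function(S, lb, ub, Aineq = NULL, bineq = NULL) {
  n <- length(lb)
  Sd <- as.matrix(S)
  inf_lo <- !is.finite(lb); inf_hi <- !is.finite(ub)
  lb2 <- ifelse(inf_lo, -.BIG_BOUND, lb)
  ub2 <- ifelse(inf_hi, .BIG_BOUND, ub)
  fixed <- which(lb2 == ub2)
  eqA <- Sd
  eqb <- rep(0, nrow(Sd))
  if (length(fixed)) {
    E <- matrix(0, length(fixed), n)
    E[cbind(seq_along(fixed), fixed)] <- 1
    eqA <- rbind(eqA, E)
    eqb <- c(eqb, lb2[fixed])
  }
  if (nrow(eqA) == 0) {
    x0 <- rep(0, n)
    N <- diag(n)
  } else {
    qrT <- qr(t(eqA))
    r <- qrT$rank
    keep <- qrT$pivot[seq_len(r)]
    K <- eqA[keep, , drop = FALSE]
    x0 <- if (all(eqb == 0)) rep(0, n) else
      as.numeric(crossprod(K, solve(tcrossprod(K), eqb[keep])))
    if (r < nrow(eqA) && max(abs(eqA %*% x0 - eqb)) > 1e-8)
      stop("infeasible: the flux polytope is empty under the given bounds",
           call. = FALSE)
    Q <- qr.Q(qrT, complete = TRUE)
    N <- Q[, seq_len(n) > r, drop = FALSE]
  }
  G <- rbind(diag(n), -diag(n), Aineq)
  h <- c(lb2, -ub2, bineq)
  Gz <- G %*% N
  hz <- h - as.numeric(G %*% x0)
  # clean the reduced system: null-space projection leaves ~1e-17 noise in
  # rows whose constraint is orthogonal to the remaining degrees of freedom;
  # those rows are vacuous (or witness infeasibility) and their tiny
  # coefficients destabilize the active-set step computation
  Gz[abs(Gz) < 1e-11] <- 0
  nrm <- sqrt(rowSums(Gz^2))
  vac <- nrm == 0
  if (any(vac & hz > 1e-8))
    stop("infeasible: the flux polytope is empty under the given bounds",
         call. = FALSE)
  Gz <- Gz[!vac, , drop = FALSE] / nrm[!vac]
  hz <- hz[!vac] / nrm[!vac]
  list(x0 = x0, N = N, Gz = Gz, hz = hz,
       artificial = c(inf_lo, inf_hi))
}

# min 1/2 ||v||^2 - d'v over the reduced polytope; returns v.
qp_reduced_solve <- function(red, d) {
  k <- ncol(red$N)
  # k == 0: fully determined system; feasibility was checked during reduction
  if (k == 0) return(red$x0)
  dz <- as.numeric(crossprod(red$N, d))
  sol <- tryCatch(
    quadprog::solve.QP(diag(k), dz, t(red$Gz), red$hz),
    error = function(e) {
      msg <- conditionMessage(e)
      if (grepl("inconsisten|no solution", msg))
        stop("infeasible: the flux polytope is empty under the given bounds",
             call. = FALSE)
      stop("QP solver failure: ", msg, call. = FALSE)
    })
  as.numeric(red$x0 + red$N %*% sol$solution)
}

#' Solve a linear program over the flux polytope
#'
#' Maximizes or minimizes `c'v` subject to `S v = 0`, bounds, and optional
#' extra inequalities `Aineq v >= bineq`. Infinite bounds are treated as
#' +/-1e6 sentinels; an optimum escaping to a sentinel raises an
#' unboundedness error.
#'
#' @param S stoichiometric matrix (may be sparse).
#' @param lb,ub numeric bound vectors.
#' @param obj numeric objective coefficient vector.
#' @param maximize logical, default `TRUE`.
#' @param Aineq,bineq optional extra inequality system `Aineq v >= bineq`.
#' @param tol absolute stabilization tolerance on the optimum (default 1e-9).
#' @return list with `optimum` and `v` (the minimum-norm optimal point, so
#'   repeated solves are deterministic).
#' @export
solve_lp <- function(S, lb, ub, obj, maximize = TRUE, Aineq = NULL,
                     bineq = NULL, tol = 1e-9) {
  n <- length(lb)
  stopifnot(length(obj) == n, length(ub) == n)
  red <- qp_reduce(S, lb, ub, Aineq, bineq)
  sgn <- if (maximize) 1 else -1
  M <- 1e3 * max(1, max(abs(c(lb[is.finite(lb)], ub[is.finite(ub)], 1)))) /
    max(abs(obj))
  at_sentinel <- function(v) {
    any(red$artificial &
          abs(c(v, v) - c(rep(-.BIG_BOUND, n), rep(.BIG_BOUND, n))) <
          1e-3 * .BIG_BOUND)
  }
  unbounded_err <- function() {
    stop("unbounded: the objective increases without limit ",
         "(a reaction with an infinite bound carries the optimum)", call. = FALSE)
  }
  prev_z <- NULL; prev_v <- NULL
  for (k in 1:11) {
    v <- qp_reduced_solve(red, sgn * M * obj)
    z <- sum(obj * v)
    if (!is.null(prev_z) && abs(z - prev_z) <= tol * max(1, abs(z))) {
      # an optimum pinned at an infinite-bound sentinel is artificial
      if (at_sentinel(prev_v)) unbounded_err()
      return(list(optimum = prev_z, v = prev_v))
    }
    prev_z <- z; prev_v <- v
    M <- M * 10
  }
  if (at_sentinel(prev_v)) unbounded_err()
  stop("LP regularization did not stabilize; check problem scaling", call. = FALSE)
}

#' Minimum-norm (or general strictly convex) QP over the flux polytope
#'
#' Minimizes `1/2 ||v||^2 - d'v` subject to `S v = 0`, bounds and optional
#' inequalities `Aineq v >= bineq`. With `d = 0` this is the pure
#' minimum-norm flux problem whose solution is unique.
#'
#' @inheritParams solve_lp
#' @param d linear term (default all zeros).
#' @return list with `v` (unique minimizer) and `norm2` (`||v||^2`).
#' @export
solve_min_norm_qp <- function(S, lb, ub, Aineq = NULL, bineq = NULL, d = NULL) {
  n <- length(lb)
  if (is.null(d)) d <- rep(0, n)
  red <- qp_reduce(S, lb, ub, Aineq, bineq)
  v <- qp_reduced_solve(red, d)
  list(v = v, norm2 = sum(v^2))
}
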