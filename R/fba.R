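#' A primary/secondary objective pair for bilevel FBA
#'
#' The primary objective is the biomass reaction (growth); the secondary is
#' a cellular-energetics reaction traded off underneath it — here one of
#' ATP maintenance, photosystem I, or photosystem II.
#'
#' @param primary,secondary reaction ids; must differ.
#' @param model optional `metabolic_model` to validate the ids against.
#' @return list of class `objective_pair`.
#' @export
objective_pair <- function(primary, secondary, model = NULL) {
  if (identical(primary, secondary))
    stop("primary and secondary objectives must differ", call. = FALSE)
  if (!is.null(model)) {
    missing_ids <- setdiff(c(primary, secondary), model$reactions$id)
    if (length(missing_ids))
      stop("objective reaction(s) not in model: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  structure(list(primary = primary, secondary = secondary),
            class = "objective_pair")
}

#' Solver settings for regularized bilevel FBA
#'
#' @param fraction_of_optimum f in (0, 1]: the primary objective is held at
#'   `>= f * Z1` in the later stages. Default 1 (biomass at its optimum).
#' @param lambda regularization weight for the alternative single-QP mode
#'   (`max v_secondary - lambda * ||v||^2`); default 1e-6.
#' @param tol_feas feasibility tolerance (mass-balance residual, bound
#'   violations); default 1e-9.
#' @param tol_opt optimality tolerance; default 1e-6.
#' @param epsilon2 slack on the secondary optimum in stage 3; default 1e-6.
#' @param mode `"lexicographic"` (three-stage LP/LP/QP, the default) or
#'   `"penalized"` (single QP sensitivity-check mode).
#' @return list of class `solver_settings`.
#' @export
solver_settings <- function(fraction_of_optimum = 1, lambda = 1e-6,
                            tol_feas = 1e-9, tol_opt = 1e-6, epsilon2 = 1e-6,
                            mode = c("lexicographic", "penalized")) {
  stopifnot(fraction_of_optimum > 0, fraction_of_optimum <= 1,
            lambda >= 0, tol_feas > 0, tol_opt > 0, epsilon2 >= 0)
  structure(list(fraction_of_optimum = fraction_of_optimum, lambda = lambda,
                 tol_feas = tol_feas, tol_opt = tol_opt, epsilon2 = epsilon2,
                 mode = match.arg(mode)),
            class = "solver_settings")
}

obj_vector <- function(model, reaction_id) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) stop("objective reaction '", reaction_id, "' not in model",
                     call. = FALSE)
  v <- rep(0, n_reactions(model)); v[i] <- 1
  v
}

#' Plain flux balance analysis (single-objective LP)
#'
#' Maximize (or minimize) the flux of one reaction subject to steady-state
#' mass balance `S v = 0` and the model's bounds.
#'
#' @param model a `metabolic_model`.
#' @param objective reaction id to optimize.
#' @param sense `"max"` or `"min"`.
#' @return list with `optimum` and `v` (named flux vector; min-norm optimal
#'   point, hence deterministic).
#' @export
fba_lp <- function(model, objective, sense = c("max", "min")) {
  sense <- match.arg(sense)
  res <- tryCatch(
    solve_lp(model$S, model$reactions$lower_bound, model$reactions$upper_bound,
             obj_vector(model, objective), maximize = sense == "max"),
    error = function(e) stop("FBA on '", model$model_id, "' (objective ",
                             objective, "): ", conditionMessage(e), call. = FALSE))
  res$v <- stats::setNames(res$v, model$reactions$id)
  res
}

#' Bilevel L2-regularized flux balance analysis
#'
#' Three-stage lexicographic solve: (1) `Z1 = max v_primary` (LP);
#' (2) `Z2 = max v_secondary` subject to `v_primary >= f * Z1` (LP);
#' (3) `v* = argmin ||v||^2` subject to both objective constraints
#' (strictly convex QP, so `v*` is unique — alternate optima such as
#' symmetric parallel pathways collapse to the balanced flux routing).
#' In `"penalized"` mode stages 2-3 are replaced by the single QP
#' `max v_secondary - lambda * ||v||^2` under the stage-1 constraint.
#'
#' @param model a `metabolic_model` (already condition-specialized).
#' @param pair an [objective_pair()].
#' @param settings a [solver_settings()].
#' @param condition_id label recorded on the result (default the model id).
#' @return object of class `flux_distribution`: list with `condition_id`,
#'   `objective_pair`, `v` (named flux vector), `Z1`, `Z2`, `status`.
#' @export
regularized_bilevel_fba <- function(model, pair, settings = solver_settings(),
                                    condition_id = model$model_id) {
  pair <- objective_pair(pair$primary, pair$secondary, model)
  S <- model$S
  lb <- model$reactions$lower_bound; ub <- model$reactions$upper_bound
  c1 <- obj_vector(model, pair$primary)
  c2 <- obj_vector(model, pair$secondary)
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop("bilevel FBA stage ", label, " (", condition_id, "): ",
           conditionMessage(e), call. = FALSE))
  }
  s1 <- stage("1 (primary LP)",
              solve_lp(S, lb, ub, c1, maximize = TRUE, tol = settings$tol_feas))
  Z1 <- s1$optimum
  # tiny feasibility slack so the stage-1 optimum is numerically attainable
  slack1 <- settings$tol_feas * max(1, abs(Z1))
  keep1 <- matrix(c1, nrow = 1)
  b1 <- settings$fraction_of_optimum * Z1 - slack1
  if (settings$mode == "lexicographic") {
    s2 <- stage("2 (secondary LP)",
                solve_lp(S, lb, ub, c2, maximize = TRUE,
                         Aineq = keep1, bineq = b1, tol = settings$tol_feas))
    Z2 <- s2$optimum
    s3 <- stage("3 (min-norm QP)",
                solve_min_norm_qp(S, lb, ub,
                                  Aineq = rbind(keep1, matrix(c2, nrow = 1)),
                                  bineq = c(b1, Z2 - settings$epsilon2)))
    v <- s3$v
  } else {
    s3 <- stage("2 (penalized QP)",
                solve_min_norm_qp(S, lb, ub, Aineq = keep1, bineq = b1,
                                  d = c2 / (2 * settings$lambda)))
    v <- s3$v
    Z2 <- sum(c2 * v)
  }
  v <- stats::setNames(v, model$reactions$id)
  res <- structure(list(condition_id = condition_id, objective_pair = pair,
                        v = v, Z1 = Z1, Z2 = Z2, status = "optimal"),
                   class = "flux_distribution")
  check_flux_distribution(res, model, settings)
  res
}

# invariant guard: mass balance, bounds, primary optimality
check_flux_distribution <- function(fd, model, settings) {
  resid <- max(abs(as.numeric(model$S %*% fd$v)))
  if (resid > settings$tol_feas)
    stop("mass-balance residual ", format(resid), " exceeds tol_feas",
         call. = FALSE)
  lo_vio <- model$reactions$lower_bound - fd$v
  hi_vio <- fd$v - model$reactions$upper_bound
  if (max(c(lo_vio, hi_vio)) > settings$tol_feas + 1e-12)
    stop("flux bound violation exceeds tol_feas", call. = FALSE)
  vp <- fd$v[[fd$objective_pair$primary]]
  if (vp < settings$fraction_of_optimum * fd$Z1 - settings$tol_opt)
    stop("primary objective below f * Z1 - tol_opt", call. = FALSE)
  invisible(fd)
}

#' Snap numerically-zero fluxes to exact zero (report hygiene)
#' @param v numeric flux vector.
#' @param threshold magnitude below which a flux is reported as 0.
#' @return numeric vector.
#' @export
snap_fluxes <- function(v, threshold = 1e-9) {
  v[abs(v) < threshold] <- 0
  v
}

#' Regularized FBA across a set of condition-specific models
#'
#' @param models named list of condition-specific `metabolic_model`s (all
#'   sharing one reaction id set), e.g. from [condition_models()].
#' @param pair an [objective_pair()].
#' @param settings a [solver_settings()].
#' @return object of class `flux_matrix`: list with `fluxes` (conditions x
#'   reactions matrix, snapped for reporting), `objective_pair`, `Z1`, `Z2`
#'   (per-condition optima), `subsystems` (per reaction column), and
#'   `raw` (unsnapped matrix).
#' @export
batch_flux_matrix <- function(models, pair, settings = solver_settings()) {
  rids <- models[[1]]$reactions$id
  for (m in models)
    if (!identical(m$reactions$id, rids))
      stop("condition models do not share a reaction id set", call. = FALSE)
  dists <- lapply(names(models), function(cid) {
    tryCatch(
      regularized_bilevel_fba(models[[cid]], pair, settings, condition_id = cid),
      error = function(e) stop("condition '", cid, "': ", conditionMessage(e),
                               call. = FALSE))
  })
  raw <- do.call(rbind, lapply(dists, `[[`, "v"))
  rownames(raw) <- names(models)
  structure(list(fluxes = snap_fluxes(raw),
                 raw = raw,
                 objective_pair = pair,
                 Z1 = stats::setNames(vapply(dists, `[[`, numeric(1), "Z1"), names(models)),
                 Z2 = stats::setNames(vapply(dists, `[[`, numeric(1), "Z2"), names(models)),
                 subsystems = stats::setNames(models[[1]]$reactions$subsystem, rids)),
            class = "flux_matrix")
}
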