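#' Read a genes x conditions expression table
#'
#' First column: gene id; remaining columns: one nonnegative expression
#' value per condition (normalized read counts or similar).
#'
#' @param path CSV/TSV file path.
#' @return named list of expression profiles, one per condition column;
#'   each profile is a list with `condition_id` and `values` (named
#'   nonnegative numeric vector over genes).
#' @export
read_expression_table <- function(path) {
  tab <- read_delim_auto(path)
  if (ncol(tab) < 2L)
    stop("expression table needs a gene column plus >= 1 condition column",
         call. = FALSE)
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene id(s) in expression table: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
  profiles <- lapply(names(tab)[-1], function(cond) {
    v <- tab[[cond]]
    if (!is.numeric(v))
      stop("non-numeric expression values in column '", cond, "'", call. = FALSE)
    neg <- which(v < 0)
    if (length(neg))
      stop("negative expression value at row ", neg[1], " (gene '",
           genes[neg[1]], "'), column '", cond, "'", call. = FALSE)
    list(condition_id = cond, values = stats::setNames(as.numeric(v), genes))
  })
  stats::setNames(profiles, names(tab)[-1])
}

#' Expression profiles as a conditions x genes matrix
#' @param profiles list of profiles from [read_expression_table()] or
#'   [simulate_expression()].
#' @param log take natural log of `value + 1` (recommended before
#'   PCA/clustering of transcript features)? Default `FALSE`.
#' @return numeric matrix, rows = conditions, columns = genes.
#' @export
expression_matrix <- function(profiles, log = FALSE) {
  genes <- names(profiles[[1]]$values)
  X <- t(vapply(profiles, function(p) {
    if (!identical(names(p$values), genes))
      stop("profiles have inconsistent gene sets", call. = FALSE)
    p$values
  }, numeric(length(genes))))
  rownames(X) <- vapply(profiles, `[[`, character(1), "condition_id")
  colnames(X) <- genes
  if (log) X <- base::log(X + 1)
  X
}

#' Settings for expression-to-bound integration
#'
#' @param gamma integration strength, dimensionless, >= 0; `gamma = 0`
#'   disables integration (all scale factors 1).
#' @param epsilon pseudocount added to numerator and denominator of each
#'   fold change. `NULL` (default) resolves at use time to 1e-8 times the
#'   control profile's median expression (machine-scale).
#' @return list of class `integration_settings`.
#' @export
integration_settings <- function(gamma = 1, epsilon = NULL) {
  stopifnot(gamma >= 0, is.null(epsilon) || epsilon > 0)
  structure(list(gamma = gamma, epsilon = epsilon), class = "integration_settings")
}

#' Per-gene fold changes of a condition relative to the control
#'
#' theta_g = (x_g + eps) / (c_g + eps), guaranteed positive.
#'
#' @param profile condition expression profile (list with `condition_id`,
#'   `values`).
#' @param control control-condition profile over the same gene set.
#' @param epsilon pseudocount; `NULL` resolves to 1e-8 x median of the
#'   control values (floored at 1e-12 if that median is 0).
#' @return list with `condition_id` and `theta` (named positive numeric).
#' @export
fold_changes <- function(profile, control, epsilon = NULL) {
  gx <- names(profile$values); gc <- names(control$values)
  if (!setequal(gx, gc)) {
    diff <- c(setdiff(gx, gc), setdiff(gc, gx))
    stop("profiles have mismatched gene sets; symmetric difference: ",
         paste(diff, collapse = ", "), call. = FALSE)
  }
  ctrl <- control$values[gx]
  if (is.null(epsilon)) epsilon <- max(1e-8 * stats::median(ctrl), 1e-12)
  theta <- (profile$values + epsilon) / (ctrl + epsilon)
  list(condition_id = profile$condition_id, theta = theta)
}

#' Map gene fold changes to reaction activities through GPR rules
#'
#' `and` nodes (enzyme complexes) take the minimum child activity, `or`
#' nodes (isozymes) the maximum. Genes in the model but absent from the
#' fold-change map are neutral (theta = 1); reactions without a GPR get
#' theta_r = 1.
#'
#' @param fc fold-change map from [fold_changes()].
#' @param model a `metabolic_model`.
#' @return list with `condition_id`, `theta_r` (named positive numeric over
#'   reactions) and `neutral_genes` (model genes not covered by `fc`).
#' @export
reaction_activity <- function(fc, model) {
  stopifnot(all(fc$theta > 0))
  rxn <- model$reactions
  theta_r <- vapply(seq_len(nrow(rxn)), function(j) {
    eval_gpr(parse_gpr(rxn$gpr[j]), fc$theta, default = 1)
  }, numeric(1))
  names(theta_r) <- rxn$id
  list(condition_id = fc$condition_id, theta_r = theta_r,
       neutral_genes = setdiff(model$genes, names(fc$theta)))
}

#' Fold-change-symmetric bound scale factor
#'
#' f(theta) = (1 + gamma * |ln theta|) ^ sign(ln theta): up-regulation by a
#' factor theta widens bounds by the same amount that down-regulation by
#' 1/theta narrows them; f(1) = 1 and gamma = 0 gives f = 1 everywhere.
#'
#' @param theta positive fold change(s).
#' @param gamma integration strength >= 0.
#' @return numeric scale factor(s), same length as `theta`.
#' @export
bound_scale_factor <- function(theta, gamma = 1) {
  if (any(theta <= 0)) stop("theta must be > 0", call. = FALSE)
  lt <- base::log(theta)
  (1 + gamma * abs(lt))^sign(lt)
}

#' Modulate model bounds by reaction activity
#'
#' Multiplies both bounds of each reaction by the scale factor
#' `scale_fn(theta_r, gamma)`. Bounds never change sign and reversible
#' reactions are scaled symmetrically; lower <= upper is preserved because
#' the factor is positive.
#'
#' @param model a `metabolic_model`.
#' @param act reaction activity from [reaction_activity()].
#' @param settings an [integration_settings()] object.
#' @param scale_fn the activity-to-scale transform; pluggable, default
#'   [bound_scale_factor()].
#' @return the bound-modulated `metabolic_model`.
#' @export
modulate_bounds <- function(model, act, settings = integration_settings(),
                            scale_fn = bound_scale_factor) {
  theta_r <- act$theta_r[model$reactions$id]
  if (anyNA(theta_r))
    stop("activity map missing reaction(s): ",
         paste(setdiff(model$reactions$id, names(act$theta_r)), collapse = ", "),
         call. = FALSE)
  f <- scale_fn(theta_r, settings$gamma)
  if (any(f <= 0)) stop("bound scale factor must be positive", call. = FALSE)
  model$reactions$lower_bound <- model$reactions$lower_bound * f
  model$reactions$upper_bound <- model$reactions$upper_bound * f
  validate_model(model)
  model
}

#' Build condition-specific models for a whole study
#'
#' For each condition: fold changes vs the control profile, GPR-mapped
#' reaction activities, bound modulation, then the condition's explicit
#' bound overrides (overrides take final precedence).
#'
#' @param model base `metabolic_model`.
#' @param profiles named list of expression profiles.
#' @param control_id name of the control condition within `profiles`.
#' @param specs named list of [condition_spec()]s (matched by condition id;
#'   conditions without a spec get no overrides).
#' @param settings an [integration_settings()].
#' @return named list of condition-specific models (control included,
#'   integrated with theta = 1 throughout plus its own overrides).
#' @export
condition_models <- function(model, profiles, control_id, specs = list(),
                             settings = integration_settings()) {
  if (!control_id %in% names(profiles))
    stop("control condition '", control_id, "' not among profiles", call. = FALSE)
  control <- profiles[[control_id]]
  out <- lapply(profiles, function(p) {
    fc <- fold_changes(p, control, settings$epsilon)
    act <- reaction_activity(fc, model)
    m <- modulate_bounds(model, act, settings)
    if (p$condition_id %in% names(specs))
      m <- apply_condition(m, specs[[p$condition_id]])
    m
  })
  stats::setNames(out, names(profiles))
}
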