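#' Pearson correlation with a Fisher-z confidence interval
#'
#' Sample Pearson r, with the interval
#' `tanh(atanh(r) +/- z_level / sqrt(n - 3))`, clamped to [-1, 1].
#'
#' @param x,y numeric vectors of equal length, `n >= 4`, both non-constant.
#' @param level confidence level, default 0.95.
#' @return list with `r`, `ci_low`, `ci_high`, `n`.
#' @export
pearson_ci <- function(x, y, level = 0.95) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 4) stop("need n >= 4 for a Fisher confidence interval", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: constant input", call. = FALSE)
  r <- stats::cor(x, y)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  half <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  list(r = r,
       ci_low = max(tanh(z - half), -1),
       ci_high = min(tanh(z + half), 1),
       n = n)
}

#' Correlate every feature with experimental growth rates
#'
#' Restricted to the conditions that have growth rates (never imputed);
#' constant features over those conditions are skipped and reported.
#' Records are sorted by |r| descending (ties broken by feature id), so
#' the top-n positive and negative correlates can be read off directly.
#'
#' @param X a [feature_matrix()].
#' @param growth named numeric vector of growth rates (h^-1, >= 0), named
#'   by condition id; typically covers a subset of conditions.
#' @param level CI level, default 0.95.
#' @return data.frame of class `correlation_records` with columns
#'   `feature_id`, `omic_type`, `group`, `r`, `ci_low`, `ci_high`, `n`;
#'   skipped constant features in `attr(, "skipped")`.
#' @export
correlate_features <- function(X, growth, level = 0.95) {
  vals <- X$values
  shared <- intersect(rownames(vals), names(growth))
  if (length(shared) < 4)
    stop("need >= 4 conditions shared between features and growth rates; got ",
         length(shared), call. = FALSE)
  shared <- sort(shared)
  vals <- vals[shared, , drop = FALSE]
  y <- growth[shared]
  sds <- apply(vals, 2, stats::sd)
  skipped <- colnames(vals)[sds == 0]
  keep <- which(sds > 0)
  recs <- lapply(keep, function(j) {
    ci <- pearson_ci(vals[, j], y, level = level)
    data.frame(feature_id = colnames(vals)[j],
               omic_type = X$meta$omic_type[j], group = X$meta$group[j],
               r = ci$r, ci_low = ci$ci_low, ci_high = ci$ci_high, n = ci$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out <- out[order(-abs(out$r), out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("correlation_records", "data.frame")
  out
}

#' Top positively / negatively growth-correlated features
#' @param records output of [correlate_features()].
#' @param n_top how many of each sign, default 10.
#' @return list with data.frames `positive` and `negative`.
#' @export
top_correlates <- function(records, n_top = 10) {
  pos <- records[records$r > 0, , drop = FALSE]
  neg <- records[records$r < 0, , drop = FALSE]
  list(positive = utils::head(pos, n_top), negative = utils::head(neg, n_top))
}

#' Aggregate correlation records by metabolic subsystem
#'
#' `mean_abs`: mean |r| per group. `bin_counts`: per group, counts of r in
#' consecutive half-open intervals `[edge_i, edge_{i+1}[` (left-closed,
#' right-open).
#'
#' @param records output of [correlate_features()].
#' @param stat `"mean_abs"` or `"bin_counts"`.
#' @param bins strictly increasing bin edges (used for `bin_counts`);
#'   default `c(-0.3, -0.1, 0.1, 0.3, 0.5, 0.7)`.
#' @return `mean_abs`: data.frame `group`, `mean_abs_r`, `n`, sorted by
#'   decreasing mean. `bin_counts`: data.frame with `group` and one count
#'   column per interval.
#' @export
aggregate_by_subsystem <- function(records, stat = c("mean_abs", "bin_counts"),
                                   bins = c(-0.3, -0.1, 0.1, 0.3, 0.5, 0.7)) {
  stat <- match.arg(stat)
  grp <- records$group
  grp[is.na(grp) | !nzchar(grp)] <- "unassigned"
  if (stat == "mean_abs") {
    m <- tapply(abs(records$r), grp, mean)
    cnt <- tapply(records$r, grp, length)
    out <- data.frame(group = names(m), mean_abs_r = as.numeric(m),
                      n = as.integer(cnt), stringsAsFactors = FALSE)
    return(out[order(-out$mean_abs_r, out$group), , drop = FALSE])
  }
  if (is.unsorted(bins, strictly = TRUE))
    stop("bin edges must be strictly increasing", call. = FALSE)
  labs <- paste0("[", utils::head(bins, -1), ",", utils::tail(bins, -1), "[")
  binned <- cut(records$r, breaks = bins, right = FALSE, labels = labs)
  tab <- table(group = grp, bin = binned)
  out <- as.data.frame.matrix(tab)
  data.frame(group = rownames(out), out, check.names = FALSE,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' LASSO regression of growth rates on omic features
#'
#' L1-penalized least squares (via glmnet): features are standardized
#' internally and growth is centered; reported coefficients are on the
#' original feature scale (plus a standardized copy). The penalty is
#' selected on a log-spaced grid of 100 values spanning 4 decades below
#' `lambda_max` (the smallest penalty shrinking every coefficient to
#' zero), by cross-validated squared error — leave-one-out by default,
#' appropriate for a dozen to two dozen conditions. Both the minimum-CV
#' and the one-standard-error rule are available.
#'
#' @param X a [feature_matrix()].
#' @param growth named numeric vector of growth rates by condition id.
#' @param lambda_grid optional penalty grid (descending); default as above.
#' @param cv_folds number of folds; `NULL` (default) = leave-one-out.
#' @param seed RNG seed controlling the fold split (LOO is deterministic,
#'   but the seed is honoured and recorded for k-fold splits).
#' @param rule `"min"` (default) or `"1se"`.
#' @param lambda_fixed optional: skip cross-validation and fit at this
#'   penalty (e.g. `0` for the least-squares limit).
#' @return object of class `lasso_fit`: `lambda` (selected), `intercept`,
#'   `coefficients` (raw scale, named), `coefficients_std`, `nonzero`
#'   (data.frame feature_id/omic_type/group/coefficient), `cv` (data.frame
#'   lambda/cvm/cvsd), `path_nonzero` (nonzero count per grid lambda),
#'   `path_monotone` (is that count nonincreasing in lambda?), `seed`.
#' @export
fit_lasso <- function(X, growth, lambda_grid = NULL, cv_folds = NULL,
                      seed = 1, rule = c("min", "1se"), lambda_fixed = NULL) {
  rule <- match.arg(rule)
  shared <- sort(intersect(rownames(X$values), names(growth)))
  n <- length(shared)
  nfolds <- if (is.null(cv_folds)) n else cv_folds
  if (n < nfolds) stop("need >= ", nfolds, " conditions with growth rates", call. = FALSE)
  if (n / nfolds < 1) stop("degenerate folds", call. = FALSE)
  x <- X$values[shared, , drop = FALSE]
  y <- growth[shared]
  sds <- apply(x, 2, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  meta <- X$meta[sds > 0, , drop = FALSE]
  if (is.null(lambda_grid)) {
    xs <- scale(x) * sqrt(n / (n - 1))  # glmnet standardizes by 1/n sd
    # tiny headroom so the top of the grid sits at-or-above the exact
    # entry point of the first predictor
    lambda_max <- max(abs(crossprod(xs, y - mean(y)))) / n * (1 + 1e-6)
    lambda_grid <- exp(seq(log(lambda_max), log(lambda_max * 1e-4), length.out = 100))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(lambda_fixed)) {
    foldid <- if (nfolds == n) seq_len(n) else
      sample(rep(seq_len(nfolds), length.out = n))
    cv <- glmnet::cv.glmnet(x, y, lambda = lambda_grid, foldid = foldid,
                            standardize = TRUE, grouped = FALSE)
    lambda_sel <- if (rule == "min") cv$lambda.min else cv$lambda.1se
    cv_tab <- data.frame(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd)
  } else {
    lambda_sel <- lambda_fixed
    cv_tab <- data.frame(lambda = numeric(0), cvm = numeric(0), cvsd = numeric(0))
  }
  fit <- glmnet::glmnet(x, y, lambda = lambda_grid, standardize = TRUE,
                        thresh = 1e-12)
  # exact refit at the selected lambda; glmnet's interpolation step warns
  # about collapsing ties when the grid has near-duplicate values
  beta <- as.numeric(suppressWarnings(
    stats::coef(fit, s = lambda_sel, exact = TRUE, x = x, y = y)))
  names(beta) <- c("(Intercept)", colnames(x))
  coefs <- beta[-1]
  coefs[abs(coefs) <= 1e-10] <- 0
  nz <- which(coefs != 0)
  path_nonzero <- fit$df[match(lambda_grid, fit$lambda)]
  structure(list(
    lambda = lambda_sel,
    intercept = beta[[1]],
    coefficients = coefs,
    coefficients_std = coefs * apply(x, 2, stats::sd),
    nonzero = data.frame(feature_id = names(coefs)[nz],
                         omic_type = meta$omic_type[nz], group = meta$group[nz],
                         coefficient = unname(coefs[nz]), stringsAsFactors = FALSE),
    cv = cv_tab,
    path_nonzero = path_nonzero,
    # grid is lambda-descending, so "nonzeros nonincreasing in lambda" reads
    # as nondecreasing along the grid
    path_monotone = !is.unsorted(path_nonzero[!is.na(path_nonzero)]),
    n = n, seed = seed, rule = rule),
    class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat("<lasso_fit> n = ", x$n, ", lambda = ", signif(x$lambda, 4),
      " (", x$rule, " rule), nonzero coefficients: ", nrow(x$nonzero), "\n",
      sep = "")
  invisible(x)
}
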