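#' Principal-component analysis with cos2 and contribution bookkeeping
#'
#' Columns are centered (and unit-scaled when `scale = TRUE`, after
#' dropping zero-variance columns); the decomposition is by singular
#' values. Eigenvalue `lambda_k = sigma_k^2 / (n - 1)`; scores are the
#' observation coordinates (left singular vectors times sigma); loadings
#' are unit-norm per component. `cos2[i, k] = score[i, k]^2 /
#' sum_m score[i, m]^2` measures how much of condition i's squared distance
#' to the centroid the k-th component captures; `contribution[j, k] =
#' 100 * loading[j, k]^2` is feature j's percentage share of component k.
#' Component signs are canonicalized so the largest-magnitude loading of
#' each component is positive.
#'
#' @param X a [feature_matrix()] or plain numeric matrix (conditions x
#'   features, >= 2 rows, >= 1 non-constant column).
#' @param scale unit-scale columns (correlation PCA)? Default `TRUE`:
#'   transcript and flux features live on incommensurate scales.
#' @return object of class `pca_result`: `eigenvalues`, `percent_variance`
#'   (sums to 100), `scores`, `loadings`, `cos2` (rows sum to 1),
#'   `contributions` (columns sum to 100), `meta` (feature metadata for
#'   retained columns), `dropped`.
#' @export
run_pca <- function(X, scale = TRUE) {
  is_fm <- inherits(X, "feature_matrix")
  vals <- if (is_fm) X$values else X
  meta <- if (is_fm) X$meta else
    data.frame(feature_id = colnames(vals) %||% paste0("f", seq_len(ncol(vals))),
               omic_type = "flux", group = "", stringsAsFactors = FALSE)
  if (nrow(vals) < 2) stop("PCA needs >= 2 conditions", call. = FALSE)
  sds <- apply(vals, 2, stats::sd)
  dropped <- colnames(vals)[sds == 0]
  keep <- sds > 0
  if (!any(keep)) stop("all features are constant; PCA undefined", call. = FALSE)
  vals <- vals[, keep, drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  Z <- scale(vals, center = TRUE, scale = scale)
  n <- nrow(Z)
  sv <- svd(Z)
  ncomp <- sum(sv$d > max(sv$d) * 1e-12)
  d <- sv$d[seq_len(ncomp)]
  U <- sv$u[, seq_len(ncomp), drop = FALSE]
  V <- sv$v[, seq_len(ncomp), drop = FALSE]
  # canonical sign: largest |loading| positive per component
  flip <- vapply(seq_len(ncomp), function(k) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) -1 else 1
  }, numeric(1))
  U <- sweep(U, 2, flip, "*")
  V <- sweep(V, 2, flip, "*")
  eig <- d^2 / (n - 1)
  scores <- sweep(U, 2, d, "*")
  dimnames(scores) <- list(rownames(vals), paste0("PC", seq_len(ncomp)))
  dimnames(V) <- list(colnames(vals), paste0("PC", seq_len(ncomp)))
  cos2 <- scores^2 / rowSums(scores^2)
  contributions <- 100 * V^2
  structure(list(eigenvalues = stats::setNames(eig, colnames(scores)),
                 percent_variance = stats::setNames(100 * eig / sum(eig), colnames(scores)),
                 scores = scores, loadings = V,
                 cos2 = cos2, contributions = contributions,
                 meta = meta, dropped = dropped, scaled = scale),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$scores), " conditions, ", nrow(x$loadings),
      " features, ", length(x$eigenvalues), " components\n", sep = "")
  pv <- round(x$percent_variance[seq_len(min(3, length(x$eigenvalues)))], 2)
  cat("  % variance: ", paste(paste0(names(pv), "=", pv), collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' cos2 of conditions over a chosen component set
#'
#' The quantity used to color conditions in score plots: the share of each
#' condition's squared distance to the origin captured by the selected
#' components (always in [0, 1]; equals 1 when all components are chosen).
#'
#' @param result a `pca_result`.
#' @param dims integer component indices, default `c(1, 2)`.
#' @return named numeric vector over conditions.
#' @export
cos2_conditions <- function(result, dims = c(1, 2)) {
  rowSums(result$cos2[, dims, drop = FALSE])
}

#' Aggregate feature contributions by pathway / functional group
#'
#' Per feature, contributions are summed across the chosen components;
#' per group they are then summed (pathway total) or averaged (per-feature
#' mean — sensitive to single-feature pathways). Features without a group
#' label fall into `"unassigned"`.
#'
#' @param result a `pca_result`.
#' @param meta optional feature metadata (defaults to metadata carried by
#'   `result`); must contain `feature_id` and `group`.
#' @param dims nonempty component index set, default `c(1, 2)`.
#' @param stat `"sum"` or `"mean"`.
#' @return data.frame with columns `group`, `value`, `n_features`, sorted
#'   by decreasing value.
#' @export
pathway_aggregate <- function(result, meta = NULL, dims = c(1, 2),
                              stat = c("sum", "mean")) {
  stat <- match.arg(stat)
  if (length(dims) == 0) stop("dims must be nonempty", call. = FALSE)
  if (is.null(meta)) meta <- result$meta
  grp <- meta$group[match(rownames(result$contributions), meta$feature_id)]
  grp[is.na(grp) | !nzchar(grp)] <- "unassigned"
  per_feature <- rowSums(result$contributions[, dims, drop = FALSE])
  agg <- tapply(per_feature, grp, if (stat == "sum") sum else mean)
  cnt <- tapply(per_feature, grp, length)
  out <- data.frame(group = names(agg), value = as.numeric(agg),
                    n_features = as.integer(cnt), stringsAsFactors = FALSE)
  out[order(-out$value, out$group), , drop = FALSE]
}

#' Correlate component coordinates with a per-condition feature
#'
#' Pearson correlation between one score column and an external
#' per-condition value (e.g. a single reaction's flux), with a Fisher-z
#' 95\% confidence interval.
#'
#' @param result a `pca_result`.
#' @param component component index.
#' @param feature_values numeric vector, one value per condition in score
#'   row order (or named by condition id).
#' @param level confidence level, default 0.95.
#' @return list with `r`, `ci_low`, `ci_high`, `n`.
#' @export
pc_feature_correlation <- function(result, component, feature_values,
                                   level = 0.95) {
  s <- result$scores[, component]
  if (!is.null(names(feature_values)))
    feature_values <- feature_values[rownames(result$scores)]
  pearson_ci(s, feature_values, level = level)
}
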