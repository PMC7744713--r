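#' Construct a conditions x features matrix with per-feature metadata
#'
#' @param values numeric matrix, rows = condition ids, columns = features.
#' @param meta data.frame with columns `feature_id`, `omic_type`
#'   (`"transcript"` or `"flux"`), `group` (COG category for transcripts,
#'   model subsystem for fluxes; `""` allowed).
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, meta) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            all(c("feature_id", "omic_type", "group") %in% names(meta)),
            nrow(meta) == ncol(values))
  if (anyNA(values)) stop("feature matrix contains missing values", call. = FALSE)
  if (!all(meta$omic_type %in% c("transcript", "flux")))
    stop("omic_type must be 'transcript' or 'flux'", call. = FALSE)
  colnames(values) <- meta$feature_id
  structure(list(values = values, meta = meta), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$values), " conditions x ", ncol(x$values),
      " features (", sum(x$meta$omic_type == "transcript"), " transcript, ",
      sum(x$meta$omic_type == "flux"), " flux)\n", sep = "")
  invisible(x)
}

#' Assemble transcript-only, flux-only, or combined feature matrices
#'
#' Rows are canonicalized to a common condition order (sorted condition id).
#' In combined mode both omics must cover exactly the same conditions;
#' values are concatenated unchanged — any rescaling is left to the
#' downstream analysis so each method controls its own scaling.
#'
#' @param transcripts optional conditions x genes numeric matrix (e.g. from
#'   [expression_matrix()]).
#' @param fluxes optional `flux_matrix` from [batch_flux_matrix()] (its
#'   snapped `fluxes` entry is used) or a plain conditions x reactions
#'   matrix.
#' @param mode `"transcript"`, `"flux"`, or `"combined"`.
#' @param transcript_groups optional named character vector mapping gene id
#'   to COG category/functional group (unmapped genes get `""`).
#' @return a [feature_matrix()].
#' @export
assemble_features <- function(transcripts = NULL, fluxes = NULL,
                              mode = c("transcript", "flux", "combined"),
                              transcript_groups = NULL) {
  mode <- match.arg(mode)
  flux_groups <- NULL
  if (inherits(fluxes, "flux_matrix")) {
    flux_groups <- fluxes$subsystems
    fluxes <- fluxes$fluxes
  }
  part <- function(values, type, groups) {
    grp <- if (is.null(groups)) rep("", ncol(values)) else {
      g <- unname(groups[colnames(values)]); g[is.na(g)] <- ""; g
    }
    feature_matrix(values,
                   data.frame(feature_id = colnames(values), omic_type = type,
                              group = grp, stringsAsFactors = FALSE))
  }
  if (mode == "transcript") {
    if (is.null(transcripts)) stop("transcript mode needs a transcript matrix", call. = FALSE)
    tm <- transcripts[order(rownames(transcripts)), , drop = FALSE]
    return(part(tm, "transcript", transcript_groups))
  }
  if (mode == "flux") {
    if (is.null(fluxes)) stop("flux mode needs a flux matrix", call. = FALSE)
    fm <- fluxes[order(rownames(fluxes)), , drop = FALSE]
    return(part(fm, "flux", flux_groups))
  }
  if (is.null(transcripts) || is.null(fluxes))
    stop("combined mode needs both omics", call. = FALSE)
  if (!setequal(rownames(transcripts), rownames(fluxes))) {
    diff <- c(setdiff(rownames(transcripts), rownames(fluxes)),
              setdiff(rownames(fluxes), rownames(transcripts)))
    stop("condition sets differ between omics; symmetric difference: ",
         paste(diff, collapse = ", "), call. = FALSE)
  }
  ord <- sort(rownames(transcripts))
  ta <- part(transcripts[ord, , drop = FALSE], "transcript", transcript_groups)
  fl <- part(fluxes[ord, , drop = FALSE], "flux", flux_groups)
  feature_matrix(cbind(ta$values, fl$values), rbind(ta$meta, fl$meta))
}

#' Normalize each reaction's flux column by its maximum magnitude
#'
#' Per reaction, fluxes across conditions are divided by the maximum
#' absolute flux for that reaction, putting every column in [-1, 1] (the
#' condition carrying the maximum — the control, in a well-behaved study —
#' maps to 1). All-zero columns are left as zeros. Idempotent.
#'
#' @param fluxes a `flux_matrix` or plain numeric matrix.
#' @return object of the same kind with normalized values.
#' @export
normalize_by_reaction_max <- function(fluxes) {
  fm <- if (inherits(fluxes, "flux_matrix")) fluxes$fluxes else fluxes
  mx <- apply(abs(fm), 2, max)
  scale_by <- ifelse(mx == 0, 1, mx)
  out <- sweep(fm, 2, scale_by, "/")
  if (inherits(fluxes, "flux_matrix")) {
    fluxes$fluxes <- out
    fluxes$raw <- out
    fluxes
  } else out
}

#' Z-score feature columns, dropping constant ones
#'
#' Each retained column is centered and scaled to unit sample variance;
#' zero-variance columns are dropped and reported in the `dropped`
#' attribute of the result.
#'
#' @param X a [feature_matrix()] or plain numeric matrix with >= 2 rows.
#' @return standardized object of the same kind; `attr(, "dropped")` lists
#'   dropped feature ids (possibly empty).
#' @export
standardize_features <- function(X) {
  vals <- if (inherits(X, "feature_matrix")) X$values else X
  if (nrow(vals) < 2) stop("standardization needs >= 2 conditions", call. = FALSE)
  sds <- apply(vals, 2, stats::sd)
  dropped <- colnames(vals)[sds == 0]
  keep <- sds > 0
  out <- scale(vals[, keep, drop = FALSE])
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  if (inherits(X, "feature_matrix")) {
    res <- feature_matrix(out, X$meta[keep, , drop = FALSE])
  } else res <- out
  attr(res, "dropped") <- dropped
  res
}
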