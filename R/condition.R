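#' Per-condition bound overrides and growth metadata
#'
#' A condition spec records how a growth condition constrains the model:
#' explicit bound overrides on named reactions (growth medium, photon
#' availability, oxygen/CO2 supply) plus free-form metadata (light
#' intensity in umol photons m^-2 s^-1, salinity, temperature in degC,
#' optical density, energy mode).
#'
#' @param condition_id character scalar, unique within a study.
#' @param bound_overrides data.frame with columns `reaction_id`,
#'   `lower_bound`, `upper_bound` (mmol gDW^-1 h^-1); may have zero rows.
#' @param metadata named list of condition annotations (optional).
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(condition_id, bound_overrides = NULL, metadata = list()) {
  if (is.null(bound_overrides))
    bound_overrides <- data.frame(reaction_id = character(0),
                                  lower_bound = numeric(0), upper_bound = numeric(0))
  stopifnot(all(c("reaction_id", "lower_bound", "upper_bound") %in% names(bound_overrides)))
  bad <- bound_overrides$reaction_id[bound_overrides$lower_bound > bound_overrides$upper_bound]
  if (length(bad))
    stop("condition '", condition_id, "': lower_bound > upper_bound for ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(bound_overrides$reaction_id))
    stop("condition '", condition_id, "': duplicate override for reaction(s) ",
         paste(unique(bound_overrides$reaction_id[duplicated(bound_overrides$reaction_id)]),
               collapse = ", "), call. = FALSE)
  structure(list(condition_id = condition_id,
                 bound_overrides = bound_overrides,
                 metadata = metadata),
            class = "condition_spec")
}

#' Read condition specs from a delimited table
#'
#' Expected columns: `condition_id`, `reaction_id`, `lower_bound`,
#' `upper_bound`; one row per override, any number of rows per condition.
#'
#' @param path CSV/TSV file path (separator sniffed from the extension).
#' @return named list of [condition_spec()] objects, in first-appearance order.
#' @export
read_condition_specs <- function(path) {
  tab <- read_delim_auto(path)
  need <- c("condition_id", "reaction_id", "lower_bound", "upper_bound")
  if (!all(need %in% names(tab)))
    stop("condition spec table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ids <- unique(tab$condition_id)
  specs <- lapply(ids, function(cid) {
    condition_spec(cid, tab[tab$condition_id == cid,
                            c("reaction_id", "lower_bound", "upper_bound")])
  })
  stats::setNames(specs, ids)
}

#' Apply a condition's bound overrides to a model
#'
#' Returns a new model identical to the input except for the overridden
#' bounds; the input model is never modified. Overrides always take final
#' precedence in the pipeline: they are applied after expression-based
#' bound modulation.
#'
#' @param model a `metabolic_model`.
#' @param spec a [condition_spec()].
#' @return the condition-specialized `metabolic_model`.
#' @export
apply_condition <- function(model, spec) {
  ov <- spec$bound_overrides
  if (nrow(ov) == 0L) return(model)
  idx <- match(ov$reaction_id, model$reactions$id)
  if (anyNA(idx))
    stop("condition '", spec$condition_id, "': unknown reaction id(s) ",
         paste(ov$reaction_id[is.na(idx)], collapse = ", "), call. = FALSE)
  model$reactions$lower_bound[idx] <- ov$lower_bound
  model$reactions$upper_bound[idx] <- ov$upper_bound
  validate_model(model)
  model
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"", comment.char = "")
}
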