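#' Configuration for a full pipeline run
#'
#' @param model_path model file (SBML L3+FBC or cobra-style JSON).
#' @param expression_path genes x conditions CSV/TSV.
#' @param out_dir result bundle directory (created by [run_pipeline()]).
#' @param control_id condition id of the control column (named explicitly,
#'   never inferred).
#' @param conditions_path optional bound-override CSV.
#' @param growth_path optional growth-rate CSV (`condition_id`,
#'   `growth_rate`).
#' @param objective_pairs named list of [objective_pair()]s; default the
#'   three study pairs (biomass vs ATP maintenance / photosystem I /
#'   photosystem II) with the toy-model reaction ids.
#' @param integration an [integration_settings()].
#' @param solver a [solver_settings()].
#' @param modes feature modes to analyze.
#' @param analyses which analyses to run.
#' @param transcript_log analyze transcripts on the log(x + 1) scale?
#'   Default `TRUE`.
#' @param k_range candidate cluster counts for silhouette selection.
#' @param seed master seed recorded in the manifest and used for k-means
#'   and LASSO fold assignment.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(model_path, expression_path, out_dir, control_id,
                            conditions_path = NULL, growth_path = NULL,
                            objective_pairs = list(
                              atpm = objective_pair("BIOMASS", "ATPM"),
                              psi = objective_pair("BIOMASS", "PSI"),
                              psii = objective_pair("BIOMASS", "PSII")),
                            integration = integration_settings(),
                            solver = solver_settings(),
                            modes = c("transcript", "flux", "combined"),
                            analyses = c("pca", "cluster", "correlate", "lasso"),
                            transcript_log = TRUE,
                            k_range = 2:8, seed = 1) {
  for (p in c(model_path, expression_path, conditions_path, growth_path))
    if (!is.null(p) && !file.exists(p))
      stop("input path does not exist: ", p, call. = FALSE)
  if (length(objective_pairs) == 0)
    stop("at least one objective pair is required", call. = FALSE)
  modes <- match.arg(modes, several.ok = TRUE)
  analyses <- match.arg(analyses, several.ok = TRUE)
  structure(list(model_path = model_path, expression_path = expression_path,
                 conditions_path = conditions_path, growth_path = growth_path,
                 out_dir = out_dir, control_id = control_id,
                 objective_pairs = objective_pairs, integration = integration,
                 solver = solver, modes = modes, analyses = analyses,
                 transcript_log = transcript_log, k_range = k_range,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a growth-rate table
#' @param path CSV with columns `condition_id`, `growth_rate` (h^-1, >= 0).
#' @return named numeric vector.
#' @export
read_growth_table <- function(path) {
  tab <- read_delim_auto(path)
  if (!all(c("condition_id", "growth_rate") %in% names(tab)))
    stop("growth table needs columns condition_id, growth_rate", call. = FALSE)
  if (any(tab$growth_rate < 0)) stop("growth rates must be >= 0", call. = FALSE)
  stats::setNames(tab$growth_rate, tab$condition_id)
}

write_tab <- function(x, dir, name, row_label = NULL) {
  if (is.matrix(x)) {
    x <- data.frame(id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
    if (!is.null(row_label)) names(x)[1] <- row_label
  }
  utils::write.csv(x, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
}

#' Run the full condition-specific FBA + machine-learning pipeline
#'
#' Stages: (1) read model, expression, condition specs, growth rates;
#' (2) build condition-specific models (fold changes vs the control, GPR
#' activity mapping, bound modulation, explicit overrides last); (3) per
#' objective pair, bilevel regularized FBA over all conditions, raw and
#' reaction-max-normalized flux matrices; (4) assemble transcript / flux /
#' combined feature matrices; (5) per feature set: PCA tables (variance,
#' scores, cos2, contributions, pathway sums and means), silhouette-selected
#' k-means membership, growth-correlation tables (full, top-10, subsystem
#' mean |r|, PCC bins), LASSO coefficient table and CV curve. A manifest
#' (config echo, seeds, package version, per-stage status) makes the bundle
#' re-runnable bit-identically.
#'
#' @param config a [pipeline_config()].
#' @return the manifest list, invisibly; `manifest$status` is `"ok"` or
#'   `"failed"` (with `manifest$failed_stage` set). Partial outputs are
#'   retained on failure.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config = list(
      model_path = config$model_path, expression_path = config$expression_path,
      conditions_path = config$conditions_path, growth_path = config$growth_path,
      control_id = config$control_id,
      objective_pairs = lapply(config$objective_pairs, unclass),
      integration = unclass(config$integration), solver = unclass(config$solver),
      modes = config$modes, analyses = config$analyses,
      transcript_log = config$transcript_log, k_range = config$k_range,
      seed = config$seed),
    package_version = as.character(utils::packageVersion("cyanoflux")),
    status = "ok", stages = list())
  fail <- function(stage, err) {
    manifest$status <<- "failed"
    manifest$failed_stage <<- stage
    manifest$stages[[stage]] <<- paste("error:", conditionMessage(err))
  }
  done <- function(stage) manifest$stages[[stage]] <<- "ok"
  finish <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  }

  env <- new.env()
  ok <- tryCatch({
    env$model <- read_model(config$model_path)
    env$profiles <- read_expression_table(config$expression_path)
    if (!config$control_id %in% names(env$profiles))
      stop("control condition '", config$control_id,
           "' not in expression table", call. = FALSE)
    env$specs <- if (is.null(config$conditions_path)) list() else
      read_condition_specs(config$conditions_path)
    env$growth <- if (is.null(config$growth_path)) NULL else
      read_growth_table(config$growth_path)
    TRUE
  }, error = function(e) { fail("read_inputs", e); FALSE })
  if (!ok) return(finish())
  done("read_inputs")

  ok <- tryCatch({
    env$cmods <- condition_models(env$model, env$profiles, config$control_id,
                                  env$specs, config$integration)
    TRUE
  }, error = function(e) { fail("condition_models", e); FALSE })
  if (!ok) return(finish())
  done("condition_models")

  env$flux <- list()
  for (pname in names(config$objective_pairs)) {
    stage <- paste0("fba_", pname)
    ok <- tryCatch({
      fm <- batch_flux_matrix(env$cmods, config$objective_pairs[[pname]],
                              config$solver)
      env$flux[[pname]] <- fm
      write_tab(fm$fluxes, config$out_dir, paste0("flux_matrix_", pname),
                "condition_id")
      write_tab(normalize_by_reaction_max(fm$fluxes), config$out_dir,
                paste0("flux_matrix_normalized_", pname), "condition_id")
      write_tab(data.frame(condition_id = rownames(fm$fluxes),
                           Z1 = unname(fm$Z1), Z2 = unname(fm$Z2)),
                config$out_dir, paste0("fba_optima_", pname))
      TRUE
    }, error = function(e) { fail(stage, e); FALSE })
    if (!ok) return(finish())
    done(stage)
  }

  tr_mat <- expression_matrix(env$profiles, log = config$transcript_log)
  feature_sets <- list()
  if ("transcript" %in% config$modes)
    feature_sets$transcript <- assemble_features(transcripts = tr_mat,
                                                 mode = "transcript")
  for (pname in names(env$flux)) {
    if ("flux" %in% config$modes)
      feature_sets[[paste0("flux_", pname)]] <-
        assemble_features(fluxes = env$flux[[pname]], mode = "flux")
    if ("combined" %in% config$modes)
      feature_sets[[paste0("combined_", pname)]] <-
        assemble_features(transcripts = tr_mat, fluxes = env$flux[[pname]],
                          mode = "combined")
  }

  for (tag in names(feature_sets)) {
    fs <- feature_sets[[tag]]
    stage <- paste0("analysis_", tag)
    ok <- tryCatch({
      if ("pca" %in% config$analyses) {
        pr <- run_pca(fs, scale = TRUE)
        write_tab(data.frame(component = names(pr$eigenvalues),
                             eigenvalue = unname(pr$eigenvalues),
                             percent_variance = unname(pr$percent_variance)),
                  config$out_dir, paste0("pca_variance_", tag))
        write_tab(pr$scores, config$out_dir, paste0("pca_scores_", tag),
                  "condition_id")
        write_tab(pr$cos2, config$out_dir, paste0("pca_cos2_", tag),
                  "condition_id")
        write_tab(pr$contributions, config$out_dir,
                  paste0("pca_contributions_", tag), "feature_id")
        write_tab(pathway_aggregate(pr, dims = c(1, 2), stat = "sum"),
                  config$out_dir, paste0("pca_pathway_sum_", tag))
        write_tab(pathway_aggregate(pr, dims = c(1, 2), stat = "mean"),
                  config$out_dir, paste0("pca_pathway_mean_", tag))
      }
      if ("cluster" %in% config$analyses) {
        std <- standardize_features(fs)
        sel <- select_k(std, config$k_range, seed = config$seed)
        write_tab(sel$silhouette, config$out_dir, paste0("silhouette_", tag))
        best <- sel$fits[[paste0("k", sel$k)]]
        write_tab(data.frame(condition_id = names(best$assignments),
                             cluster = unname(best$assignments)),
                  config$out_dir, paste0("clusters_", tag))
      }
      if (!is.null(env$growth) && "correlate" %in% config$analyses) {
        recs <- correlate_features(fs, env$growth)
        write_tab(as.data.frame(recs), config$out_dir,
                  paste0("correlations_", tag))
        tops <- top_correlates(recs, 10)
        write_tab(tops$positive, config$out_dir,
                  paste0("correlations_top_positive_", tag))
        write_tab(tops$negative, config$out_dir,
                  paste0("correlations_top_negative_", tag))
        write_tab(aggregate_by_subsystem(recs, "mean_abs"), config$out_dir,
                  paste0("subsystem_mean_abs_pcc_", tag))
        write_tab(aggregate_by_subsystem(recs, "bin_counts"), config$out_dir,
                  paste0("subsystem_pcc_bins_", tag))
      }
      if (!is.null(env$growth) && "lasso" %in% config$analyses) {
        lf <- fit_lasso(fs, env$growth, seed = config$seed)
        write_tab(data.frame(feature_id = names(lf$coefficients),
                             coefficient = unname(lf$coefficients),
                             coefficient_std = unname(lf$coefficients_std)),
                  config$out_dir, paste0("lasso_coefficients_", tag))
        write_tab(lf$nonzero, config$out_dir, paste0("lasso_nonzero_", tag))
        write_tab(lf$cv, config$out_dir, paste0("lasso_cv_", tag))
      }
      TRUE
    }, error = function(e) { fail(stage, e); FALSE })
    if (!ok) return(finish())
    done(stage)
  }
  finish()
}
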