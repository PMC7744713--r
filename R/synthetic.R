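# Synthetic study generator: toy photoautotroph models, expression profiles
# with planted condition clusters, and growth rates from a planted sparse
# linear model. Every generator is a pure function of its arguments plus
# the seed, so fixtures are reproducible bit-exactly and ground truth is
# always carried alongside the data.

#' Build a toy constraint-based model
#'
#' `"photo"`: a small photoautotroph with photon/CO2/O2 exchanges,
#' photosystem-II-like and photosystem-I-like photoexcitation reactions
#' coupled through a plastoquinone-like carrier, an NADPH-dissipating
#' Mehler-like valve, Calvin-cycle-like carbon fixation, an ATP-maintenance
#' sink and a biomass drain. Feasible with positive biomass under default
#' bounds; fixing the photon exchange to zero forces zero biomass (dark
#' behavior). Contains alternate optima that the L2 regularization
#' resolves.
#'
#' `"minimal"`: a 4-reaction uptake-conversion-drain chain small enough for
#' exhaustive KKT-enumeration oracles.
#'
#' @param preset `"minimal"` or `"photo"`.
#' @return a `metabolic_model`.
#' @export
make_toy_model <- function(preset = c("minimal", "photo")) {
  preset <- match.arg(preset)
  if (preset == "minimal") {
    met <- data.frame(id = c("A", "B"), name = c("substrate A", "intermediate B"),
                      compartment = "c", stringsAsFactors = FALSE)
    rxn <- data.frame(
      id = c("EX_A", "CONV", "BIOMASS", "SINK"),
      name = c("A exchange", "A to B conversion", "biomass drain", "overflow drain"),
      subsystem = c("Exchange", "Central Metabolism", "Biomass", "Energy Metabolism"),
      lower_bound = c(-10, 0, 0, 0),
      upper_bound = c(0, 1000, 1000, 1000),
      gpr = c("", "g1", "", ""),
      objective_coefficient = c(0, 0, 1, 0),
      stringsAsFactors = FALSE)
    S <- rbind(A = c(-1, -1, 0, 0),
               B = c(0, 1, -1, -1))
    return(metabolic_model("toy_minimal", met, rxn, "g1", S))
  }
  met <- data.frame(
    id = c("photon", "pq", "nadph", "atp", "co2", "cfix", "o2"),
    name = c("photon", "plastoquinol pool", "NADPH", "ATP", "CO2",
             "fixed carbon", "O2"),
    compartment = "c", stringsAsFactors = FALSE)
  rxn <- data.frame(
    id = c("EX_PHOTON", "EX_CO2", "EX_O2", "PSII", "PSI", "MEHLER", "CBB",
           "ATPM", "BIOMASS"),
    name = c("photon exchange", "CO2 exchange", "O2 exchange",
             "photosystem II photoexcitation", "photosystem I photoexcitation",
             "Mehler-like NADPH dissipation", "carbon fixation",
             "ATP maintenance", "biomass drain"),
    subsystem = c("Exchange", "Exchange", "Exchange", "Photosynthesis",
                  "Photosynthesis", "Photosynthesis", "Carbon Fixation",
                  "Energy Metabolism", "Biomass"),
    lower_bound = c(-100, -10, 0, 0, 0, 0, 0, 0, 0),
    upper_bound = c(0, 0, 1000, 1000, 1000, 1000, 1000, 1000, 1000),
    gpr = c("", "", "", "psbA and psbD", "psaA and psaB", "flv1 or flv3",
            "rbcL and rbcS", "", ""),
    objective_coefficient = c(0, 0, 0, 0, 0, 0, 0, 0, 1),
    stringsAsFactors = FALSE)
  #            EX_PH EX_CO2 EX_O2 PSII  PSI MEHLER  CBB ATPM BIOMASS
  S <- rbind(
    photon = c(-1,    0,     0,   -1,  -1,   0,     0,   0,   0),
    pq     = c( 0,    0,     0,    1,  -1,   0,     0,   0,   0),
    nadph  = c( 0,    0,     0,    0,   1,  -1,    -2,   0,   0),
    atp    = c( 0,    0,     0,    0,   1,   0,    -3,  -1,  -1),
    co2    = c( 0,   -1,     0,    0,   0,   0,    -1,   0,   0),
    cfix   = c( 0,    0,     0,    0,   0,   0,     1,   0,  -1),
    o2     = c( 0,    0,    -1, 0.25,   0,   0,     0,   0,   0))
  metabolic_model("toy_photo", met, rxn,
                  c("psbA", "psbD", "psaA", "psaB", "rbcL", "rbcS",
                    "flv1", "flv3"), S)
}

#' Parallel-pathway model for regularizer-uniqueness checks
#'
#' `n_paths` identical routes between a fixed-rate uptake and the biomass
#' drain: the LP optimum is degenerate (any split of the uptake across the
#' routes is optimal) and the minimum-norm regularization must split the
#' flux exactly equally.
#'
#' @param n_paths number of parallel routes, >= 2.
#' @param uptake fixed uptake rate (mmol gDW^-1 h^-1), default 10.
#' @return a `metabolic_model`.
#' @export
make_parallel_paths_model <- function(n_paths, uptake = 10) {
  if (n_paths < 2) stop("n_paths must be >= 2", call. = FALSE)
  path_ids <- sprintf("PATH%d", seq_len(n_paths))
  met <- data.frame(id = c("A", "B"), name = c("A", "B"), compartment = "c",
                    stringsAsFactors = FALSE)
  rxn <- data.frame(
    id = c("EX_A", path_ids, "BIOMASS"),
    name = c("A exchange", sprintf("route %d", seq_len(n_paths)), "biomass drain"),
    subsystem = c("Exchange", rep("Central Metabolism", n_paths), "Biomass"),
    lower_bound = c(-uptake, rep(0, n_paths), 0),
    upper_bound = c(-uptake, rep(1000, n_paths), 1000),
    gpr = "", objective_coefficient = c(rep(0, n_paths + 1), 1),
    stringsAsFactors = FALSE)
  S <- rbind(A = c(-1, rep(-1, n_paths), 0),
             B = c(0, rep(1, n_paths), -1))
  metabolic_model(sprintf("parallel_%d", n_paths), met, rxn, character(0), S)
}

#' Simulate expression profiles with planted condition clusters
#'
#' Log-expression for condition i, gene g is
#' `baseline_g + mu_{g, cluster(i)} + N(0, 1)` with per-gene baselines
#' `N(log 50, 1)` and cluster centers `mu ~ N(0, effect_size^2)`; values
#' are exponentiated, so they are nonnegative and fold changes against the
#' control are well-defined on the scale the bound-modulation transform
#' expects. Conditions are assigned to clusters in contiguous blocks;
#' condition 1 is the designated control.
#'
#' @param n_genes,n_conditions dimensions.
#' @param n_clusters number of planted clusters (<= n_conditions).
#' @param effect_size between-cluster log-scale shift (sd of cluster
#'   centers); within-cluster log-scale sd is 1.
#' @param seed RNG seed.
#' @param gene_ids optional gene id vector of length `n_genes` (default
#'   `g001`, `g002`, ...).
#' @return list with `profiles` (named list of expression profiles; first
#'   one is the control) and `labels` (named planted cluster labels).
#' @export
simulate_expression <- function(n_genes, n_conditions, n_clusters = 3,
                                effect_size = 6, seed = 1, gene_ids = NULL) {
  if (n_clusters > n_conditions)
    stop("n_clusters must be <= n_conditions", call. = FALSE)
  if (n_genes < 1 || n_conditions < 2) stop("invalid sizes", call. = FALSE)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cond_ids <- sprintf("cond%02d", seq_len(n_conditions))
  labels <- sort(rep(seq_len(n_clusters), length.out = n_conditions))
  baseline <- stats::rnorm(n_genes, mean = log(50), sd = 1)
  centers <- matrix(stats::rnorm(n_genes * n_clusters, sd = effect_size),
                    n_genes, n_clusters)
  profiles <- lapply(seq_len(n_conditions), function(i) {
    lx <- baseline + centers[, labels[i]] + stats::rnorm(n_genes)
    list(condition_id = cond_ids[i],
         values = stats::setNames(exp(lx), gene_ids))
  })
  list(profiles = stats::setNames(profiles, cond_ids),
       labels = stats::setNames(labels, cond_ids))
}

#' Simulate growth rates from a planted sparse linear model
#'
#' `y = X_std beta + eps` with `eps ~ N(0, sigma^2)`; beta has exactly
#' `support_size` nonzero entries of magnitude `beta_magnitude` with random
#' signs at random positions. `y` is shifted to be nonnegative and reported
#' only for a random subset of conditions (emulating a study where only
#' some conditions have measured growth).
#'
#' @param X a [feature_matrix()] (standardized internally).
#' @param support_size number of truly predictive features.
#' @param beta_magnitude absolute value of nonzero coefficients, default 1.
#' @param sigma noise sd; `NULL` (default) derives it from `snr` as
#'   `sd(signal) / sqrt(snr)`.
#' @param snr signal-to-noise variance ratio used when `sigma` is `NULL`.
#' @param seed RNG seed.
#' @param rate_subset_size how many conditions receive a growth rate
#'   (default all).
#' @return list with `growth` (named nonnegative rates on the subset),
#'   `beta` (full named coefficient vector), `sigma`.
#' @export
simulate_growth <- function(X, support_size, beta_magnitude = 1, sigma = NULL,
                            snr = 10, seed = 1, rate_subset_size = NULL) {
  Xs <- standardize_features(X)
  vals <- Xs$values
  p <- ncol(vals); n <- nrow(vals)
  if (support_size > p) stop("support_size exceeds feature count", call. = FALSE)
  if (is.null(rate_subset_size)) rate_subset_size <- n
  if (rate_subset_size > n) stop("rate_subset_size exceeds condition count", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  beta <- stats::setNames(rep(0, p), colnames(vals))
  supp <- sample.int(p, support_size)
  beta[supp] <- beta_magnitude * sample(c(-1, 1), support_size, replace = TRUE)
  signal <- as.numeric(vals %*% beta)
  if (is.null(sigma)) sigma <- stats::sd(signal) / sqrt(snr)
  y <- signal + stats::rnorm(n, sd = sigma)
  y <- y - min(y)
  names(y) <- rownames(vals)
  keep <- sort(sample(rownames(vals), rate_subset_size))
  list(growth = y[keep], beta = beta, sigma = sigma)
}

#' Generate a complete paper-shaped synthetic study
#'
#' A bundle exercising every pipeline stage without downloads: the photo
#' toy model; 24 growth conditions with planted expression clusters
#' (condition 1 = control); per-condition bound overrides emulating
#' light/carbon availability, including a dark condition (photon exchange
#' fixed to 0) and a high-light condition; growth rates from a sparse
#' linear model over the log-transcript features, measured for 12 of the
#' 24 conditions. Ground truth (cluster labels, beta, sigma) is stored
#' alongside the data.
#'
#' @param seed master seed; every randomized piece derives from it.
#' @param n_conditions,n_genes,n_clusters,effect_size passed to
#'   [simulate_expression()] (defaults 24/50/6/6).
#' @param support_size,snr passed to [simulate_growth()] (defaults 3/10).
#' @param rate_subset_size conditions with measured growth (default 12).
#' @return object of class `synthetic_study`: `model`, `profiles`,
#'   `control_id`, `specs`, `growth`, `metadata` (per-condition
#'   light/energy-mode table), `truth`, `seed`.
#' @export
make_synthetic_study <- function(seed = 1, n_conditions = 24, n_genes = 50,
                                 n_clusters = 6, effect_size = 6,
                                 support_size = 3, snr = 10,
                                 rate_subset_size = 12) {
  model <- make_toy_model("photo")
  gene_ids <- c(model$genes, sprintf("g%03d", seq_len(max(0, n_genes - length(model$genes)))))
  expr <- simulate_expression(n_genes, n_conditions, n_clusters, effect_size,
                              seed = seed, gene_ids = gene_ids)
  cond_ids <- names(expr$profiles)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed + 1)
  # photon availability per condition: control 100, one high-light, one dark,
  # the rest spread over a realistic range
  photon_uptake <- stats::setNames(round(stats::runif(n_conditions, 60, 120), 1),
                                   cond_ids)
  photon_uptake[1] <- 100
  dark_id <- cond_ids[min(3, n_conditions)]
  high_id <- cond_ids[min(2, n_conditions)]
  photon_uptake[dark_id] <- 0
  photon_uptake[high_id] <- 150
  carbon_limited <- cond_ids[seq_len(n_conditions) %% 8 == 0]
  specs <- lapply(cond_ids, function(cid) {
    ov <- data.frame(reaction_id = "EX_PHOTON",
                     lower_bound = -photon_uptake[[cid]], upper_bound = 0,
                     stringsAsFactors = FALSE)
    if (cid %in% carbon_limited)
      ov <- rbind(ov, data.frame(reaction_id = "EX_CO2",
                                 lower_bound = -2, upper_bound = 0))
    condition_spec(cid, ov,
                   metadata = list(
                     light_intensity = 2.5 * photon_uptake[[cid]],
                     energy_mode = if (photon_uptake[[cid]] == 0) "dark"
                                   else "photoautotrophic"))
  })
  names(specs) <- cond_ids
  X_tr <- assemble_features(transcripts = expression_matrix(expr$profiles, log = TRUE),
                            mode = "transcript")
  gr <- simulate_growth(X_tr, support_size = support_size, snr = snr,
                        seed = seed + 2, rate_subset_size = rate_subset_size)
  metadata <- data.frame(
    condition_id = cond_ids,
    light_intensity = 2.5 * unname(photon_uptake),
    energy_mode = ifelse(photon_uptake == 0, "dark", "photoautotrophic"),
    carbon_limited = cond_ids %in% carbon_limited,
    planted_cluster = unname(expr$labels),
    stringsAsFactors = FALSE)
  structure(list(model = model, profiles = expr$profiles,
                 control_id = cond_ids[1], specs = specs, growth = gr$growth,
                 metadata = metadata,
                 truth = list(cluster_labels = expr$labels, beta = gr$beta,
                              sigma = gr$sigma),
                 seed = seed),
            class = "synthetic_study")
}

#' Write a synthetic study to the on-disk formats the pipeline reads
#'
#' Emits `model.json` (cobra-style dialect), `model.xml` (SBML L3 + FBC),
#' `expression.csv` (genes x conditions), `conditions.csv` (bound
#' overrides), `metadata.csv`, `growth.csv` and `truth.json`, so synthetic
#' fixtures and real data are interchangeable inputs.
#'
#' @param study a [make_synthetic_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model_json(study$model, file.path(dir, "model.json"))
  write_model_sbml(study$model, file.path(dir, "model.xml"))
  genes <- names(study$profiles[[1]]$values)
  expr_tab <- data.frame(gene_id = genes,
                         vapply(study$profiles, function(p) p$values[genes],
                                numeric(length(genes))),
                         check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(expr_tab, file.path(dir, "expression.csv"), row.names = FALSE)
  ov <- do.call(rbind, lapply(study$specs, function(sp) {
    cbind(condition_id = sp$condition_id, sp$bound_overrides)
  }))
  utils::write.csv(ov, file.path(dir, "conditions.csv"), row.names = FALSE)
  utils::write.csv(study$metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
  utils::write.csv(data.frame(condition_id = names(study$growth),
                              growth_rate = unname(study$growth)),
                   file.path(dir, "growth.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(control_id = study$control_id, seed = study$seed,
         cluster_labels = as.list(study$truth$cluster_labels),
         beta = as.list(study$truth$beta), sigma = study$truth$sigma),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
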