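#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study that stands in for the real inputs
# (a genome-scale model, 24-condition RNA-seq, per-condition constraint
# tables, and growth rates for a 12-condition subset) and write it to disk
# in the same formats the pipeline reads.

suppressPackageStartupMessages(library(cyanoflux))

seed <- 1
study_dir <- "results/study"

study <- make_synthetic_study(seed = seed)
write_study(study, study_dir)

cat("Synthetic study written to", study_dir, "\n")
cat(" conditions:          ", length(study$profiles),
    " (control:", study$control_id, ")\n")
cat(" genes:               ", length(study$profiles[[1]]$values), "\n")
cat(" planted clusters:    ", length(unique(study$truth$cluster_labels)), "\n")
cat(" growth rates for:    ", length(study$growth), "conditions\n")
dark <- study$metadata$condition_id[study$metadata$energy_mode == "dark"]
cat(" dark condition(s):   ", paste(dark, collapse = ", "), "\n")
cat(" planted growth model:", sum(study$truth$beta != 0), "nonzero coefficients,",
    "noise sd", signif(study$truth$sigma, 3), "\n")
cat("\nModel summary:\n")
print(study$model)
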