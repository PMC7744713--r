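#!/usr/bin/env Rscript
# Stage 4: PCA of the transcript, flux and combined feature matrices:
# variance decomposition, condition cos2 (score-plot coloring), feature
# contributions, and pathway-level contribution sums and means over the
# first two components.

suppressPackageStartupMessages(library(cyanoflux))

study_dir <- "results/study"
profiles <- read_expression_table(file.path(study_dir, "expression.csv"))
tr_mat <- expression_matrix(profiles, log = TRUE)

feature_sets <- list(transcript = assemble_features(transcripts = tr_mat,
                                                    mode = "transcript"))
for (pname in c("atpm", "psi", "psii")) {
  fl <- as.matrix(read.csv(sprintf("results/flux_matrix_%s.csv", pname),
                           row.names = 1, check.names = FALSE))
  feature_sets[[paste0("flux_", pname)]] <-
    assemble_features(fluxes = fl, mode = "flux")
  feature_sets[[paste0("combined_", pname)]] <-
    assemble_features(transcripts = tr_mat, fluxes = fl, mode = "combined")
}

for (tag in names(feature_sets)) {
  p <- run_pca(feature_sets[[tag]], scale = TRUE)
  write.csv(data.frame(component = names(p$eigenvalues),
                       eigenvalue = unname(p$eigenvalues),
                       percent_variance = unname(p$percent_variance)),
            sprintf("results/pca_variance_%s.csv", tag), row.names = FALSE)
  write.csv(data.frame(condition_id = rownames(p$scores), p$scores,
                       cos2_dim12 = cos2_conditions(p, 1:2),
                       check.names = FALSE),
            sprintf("results/pca_scores_%s.csv", tag), row.names = FALSE)
  write.csv(data.frame(feature_id = rownames(p$contributions),
                       p$contributions, check.names = FALSE),
            sprintf("results/pca_contributions_%s.csv", tag), row.names = FALSE)
  write.csv(pathway_aggregate(p, dims = 1:2, stat = "sum"),
            sprintf("results/pca_pathway_sum_%s.csv", tag), row.names = FALSE)
  write.csv(pathway_aggregate(p, dims = 1:2, stat = "mean"),
            sprintf("results/pca_pathway_mean_%s.csv", tag), row.names = FALSE)
  cat(sprintf("%-14s PC1 %5.1f%%  PC1+2 %5.1f%%  top cos2: %s\n", tag,
              p$percent_variance[1], sum(p$percent_variance[1:2]),
              names(sort(cos2_conditions(p, 1:2), decreasing = TRUE))[1]))
}
cat("PCA tables written under results/\n")
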