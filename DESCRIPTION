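Package: cyanoflux
Title: Condition-Specific Metabolic Modeling and Multi-Omic Machine Learning for Cyanobacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds condition-specific genome-scale metabolic models by mapping
    transcriptomic fold-changes onto reaction bounds through gene-protein-reaction
    rules, computes flux distributions with bilevel L2-regularized flux balance
    analysis for paired growth/energy objectives, and analyzes transcript, flux
    and combined feature matrices with PCA (cos2, contributions, pathway
    aggregation), silhouette-selected k-means clustering, LASSO regression
    against growth rates, and Pearson correlation with Fisher-z confidence
    intervals aggregated by metabolic subsystem. Includes a synthetic-data
    module (toy photoautotroph models, planted expression clusters, sparse
    growth models) so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    glmnet,
    jsonlite,
    methods,
    quadprog,
    stats,
    utils,
    xml2
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
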