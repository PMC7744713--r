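#' k-means clustering of growth conditions
#'
#' Lloyd-type k-means (via [stats::kmeans()], k-means++-quality results
#' obtained by taking the best of `n_init` random starts by within-cluster
#' sum of squares). Deterministic for a fixed `(seed, n_init)`. Cluster
#' labels are canonicalized by order of each cluster's first member
#' (condition row order), so outputs are diffable across runs.
#'
#' @param X a [feature_matrix()] or plain numeric matrix with condition
#'   row names (features should already be standardized).
#' @param k number of clusters, `2 <= k <= n_conditions` (k = n gives
#'   singleton clusters).
#' @param seed RNG seed.
#' @param n_init number of random starts, default 50.
#' @return object of class `cluster_result`: `k`, `assignments` (named
#'   integer vector), `centroids`, `inertia` (total within-cluster sum of
#'   squares), `mean_silhouette`, `seed`.
#' @export
kmeans_fit <- function(X, k, seed = 1, n_init = 50) {
  vals <- if (inherits(X, "feature_matrix")) X$values else X
  n <- nrow(vals)
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]", call. = FALSE)
  if (k < 2) stop("k = 1 carries no cluster structure; use k >= 2", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (k == n) {
    # every point its own cluster; stats::kmeans rejects this edge case
    km <- list(cluster = seq_len(n), centers = vals, tot.withinss = 0,
               totss = sum(scale(vals, scale = FALSE)^2))
  } else {
    km <- suppressWarnings(
      stats::kmeans(vals, centers = k, nstart = n_init, iter.max = 100))
  }
  if (km$tot.withinss > km$totss + 1e-8)
    stop("k-means inertia exceeds total sum of squares", call. = FALSE)
  relab <- canonical_labels(km$cluster)
  assignments <- stats::setNames(relab$labels, rownames(vals))
  centroids <- km$centers[relab$order, , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  ms <- if (k >= 2 && k < n) mean_silhouette(vals, assignments) else
    if (k == n) NA_real_ else NA_real_
  structure(list(k = k, assignments = assignments, centroids = centroids,
                 inertia = km$tot.withinss, mean_silhouette = ms, seed = seed),
            class = "cluster_result")
}

canonical_labels <- function(cluster) {
  first_seen <- unique(cluster)
  labels <- match(cluster, first_seen)
  list(labels = labels, order = first_seen)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Mean silhouette width of a clustering
#'
#' Per point, `(b - a) / max(a, b)` with Euclidean distances, where `a` is
#' the mean distance to the point's own cluster and `b` the mean distance
#' to the nearest other cluster; points in singleton clusters score 0
#' (the standard convention, as in `cluster::silhouette`). Averaged over
#' all points.
#'
#' @param X a [feature_matrix()] or numeric matrix.
#' @param assignments integer cluster labels (one per row of `X`).
#' @return mean silhouette width in [-1, 1].
#' @export
mean_silhouette <- function(X, assignments) {
  vals <- if (inherits(X, "feature_matrix")) X$values else X
  assignments <- as.integer(assignments)
  if (length(unique(assignments)) < 2)
    stop("silhouette needs >= 2 clusters", call. = FALSE)
  sil <- cluster::silhouette(assignments, stats::dist(vals))
  mean(sil[, "sil_width"])
}

#' Select the number of clusters by silhouette analysis
#'
#' Fits k-means for each candidate k and picks the k maximizing the mean
#' silhouette width; ties break toward smaller k (parsimony).
#'
#' @param X a [feature_matrix()] or numeric matrix.
#' @param k_range candidate k values, each in `[2, n - 1]`.
#' @param seed RNG seed (used for every k).
#' @param n_init random starts per k.
#' @return list with `k` (the selected value), `silhouette` (data.frame
#'   `k`, `mean_silhouette`), and `fits` (the per-k `cluster_result`s).
#' @export
select_k <- function(X, k_range = 2:8, seed = 1, n_init = 50) {
  vals <- if (inherits(X, "feature_matrix")) X$values else X
  n <- nrow(vals)
  if (length(k_range) == 0) stop("k_range is empty", call. = FALSE)
  bad <- k_range[k_range < 2 | k_range > n - 1]
  if (length(bad))
    stop("invalid k in range (need 2 <= k <= n - 1 = ", n - 1, "): ",
         paste(bad, collapse = ", "), call. = FALSE)
  k_range <- sort(unique(k_range))
  fits <- lapply(k_range, function(k) kmeans_fit(X, k, seed = seed, n_init = n_init))
  sil <- vapply(fits, `[[`, numeric(1), "mean_silhouette")
  best <- which.max(sil)  # which.max returns the first (smallest k) on ties
  list(k = k_range[best],
       silhouette = data.frame(k = k_range, mean_silhouette = sil),
       fits = stats::setNames(fits, paste0("k", k_range)))
}

#' Reduce conditions to leading principal-component scores
#'
#' Convenience for PCA-reduced clustering: clustering on the first few
#' score columns suppresses noise carried by minor components.
#'
#' @param X a [feature_matrix()] or numeric matrix.
#' @param d number of leading components to keep.
#' @param scale passed to [run_pca()].
#' @return numeric matrix of scores (conditions x d).
#' @export
pca_scores_matrix <- function(X, d = 2, scale = TRUE) {
  p <- run_pca(X, scale = scale)
  p$scores[, seq_len(min(d, ncol(p$scores))), drop = FALSE]
}
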