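#' Cluster subjects into learner subgroups
#'
#' K-means on z-scored (difference-mean, difference-SD) features, with the
#' number of clusters selected by the mean silhouette coefficient over a
#' candidate range. For each `k`, K-means is restarted `n_restarts` times
#' and the solution with the lowest within-cluster sum of squares is kept;
#' the `k` maximizing the mean silhouette wins, ties broken toward the
#' smallest `k`. Cluster labels are relabelled by descending cluster mean
#' of `diff_mean`, so cluster 1 always contains the subjects with the most
#' learning.
#'
#' @param features data frame with `subject_id`, `diff_mean`, `diff_sd`.
#' @param k_range candidate cluster numbers (default 3:7).
#' @param n_restarts random K-means initializations per `k`.
#' @param seed integer seed.
#' @return A `navlearn_subgroups`: `selected_k`, per-subject `labels`,
#'   `centroids` (on the original feature scale), `silhouette` per
#'   candidate `k`, and the feature scaling parameters.
#' @export
cluster_learners <- function(features, k_range = 3:7, n_restarts = 50L,
                             seed = 1L) {
  x <- as.matrix(features[, c("diff_mean", "diff_sd")])
  if (!all(is.finite(x))) stopf("features must be finite")
  n <- nrow(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl < 1e-12)) {
    if (all(scl < 1e-12)) stopf("degenerate features: all subjects identical")
    scl[scl < 1e-12] <- 1
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")

  usable <- k_range[k_range < n]
  if (length(usable) < length(k_range)) {
    warnf("skipping k >= n_subjects (%d)", n)
  }
  if (length(usable) == 0L) stopf("no usable k in k_range for %d subjects", n)

  fits <- list()
  sil <- stats::setNames(numeric(length(usable)), usable)
  with_local_seed(seed, {
    for (i in seq_along(usable)) {
      k <- usable[i]
      km <- stats::kmeans(z, centers = k, nstart = n_restarts,
                          iter.max = 100L)
      fits[[as.character(k)]] <- km
      sil[i] <- mean(cluster::silhouette(km$cluster, stats::dist(z))[, 3])
    }
  })
  selected_k <- usable[which.max(sil)]  # which.max takes the first maximum
  km <- fits[[as.character(selected_k)]]

  # relabel: cluster 1 = largest mean diff_mean (most learning)
  ord <- order(tapply(x[, "diff_mean"], km$cluster, mean),
               decreasing = TRUE)
  relabel <- match(km$cluster, ord)
  centroids <- sweep(sweep(km$centers[ord, , drop = FALSE], 2, scl, "*"),
                     2, ctr, "+")
  rownames(centroids) <- seq_len(selected_k)

  structure(list(selected_k = selected_k,
                 labels = stats::setNames(relabel, features$subject_id),
                 centroids = centroids,
                 silhouette = sil,
                 scaling = list(center = ctr, scale = scl)),
            class = "navlearn_subgroups")
}

#' @export
print.navlearn_subgroups <- function(x, ...) {
  cat(sprintf("<navlearn_subgroups> k = %d (silhouettes: %s)\n",
              x$selected_k,
              paste(sprintf("%s: %.3f", names(x$silhouette), x$silhouette),
                    collapse = ", ")))
  print(table(cluster = x$labels))
  invisible(x)
}
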