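#' Hierarchical agglomerative clustering from a precomputed distance matrix
#'
#' Builds the agglomerative merge tree under the chosen linkage and cuts it to
#' `k` clusters. Average linkage is the default, the standard choice for
#' precomputed non-Euclidean (here Wasserstein) distances.
#'
#' @param D symmetric nonnegative distance matrix with zero diagonal.
#' @param k number of clusters, `2 <= k <= nrow(D)`.
#' @param linkage `"average"`, `"complete"`, or `"single"`.
#' @return Integer cluster labels in `1..k`, named by the items.
#' @export
hierarchical_clusters <- function(D, k, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  check_square_dist(D)
  n <- nrow(D)
  if (k < 2 || k > n) stopf("k must be in [2, %d]", n)
  hc <- hclust(as.dist(D), method = linkage)
  cutree(hc, k = k)
}

#' Silhouette scores for a clustering
#'
#' For each item, \eqn{s_i = (b_i - a_i) / \max(a_i, b_i)} where \eqn{a_i} is
#' its average distance to the other members of its own cluster and
#' \eqn{b_i} the minimum over other clusters of the average distance to that
#' cluster's members. Members of singleton clusters get \eqn{s_i = 0} (the
#' formula is undefined there), as is an item with \eqn{a_i = b_i = 0}.
#'
#' @inheritParams hierarchical_clusters
#' @param labels integer cluster labels (at least two distinct values).
#' @return List with `s` (per-item scores in `[-1, 1]`) and `mean`.
#' @export
silhouette_scores <- function(D, labels) {
  check_square_dist(D)
  n <- nrow(D)
  stopifnot(length(labels) == n)
  cl <- unique(labels)
  if (length(cl) < 2) stopf("silhouette needs at least two clusters")
  members <- lapply(cl, function(c) which(labels == c))
  names(members) <- as.character(cl)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- members[[as.character(labels[i])]]
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(members[setdiff(names(members), as.character(labels[i]))],
                    function(m) mean(D[i, m]), 0))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  names(s) <- rownames(D)
  list(s = s, mean = mean(s))
}

#' Select the number of clusters by maximum average silhouette
#'
#' Runs [hierarchical_clusters()] and [silhouette_scores()] for every `k` in
#' `k_min:k_max` and returns the clustering with the highest mean silhouette;
#' ties go to the smallest `k`.
#'
#' @inheritParams hierarchical_clusters
#' @param k_min,k_max candidate range (capped at `n - 1`).
#' @return Object of class `clustering_result`: items, `labels`, selected
#'   `k`, per-item silhouette `s`, `mean_s`, and the profile `by_k`.
#' @export
select_k <- function(D, k_min = 2, k_max = 15, linkage = "average") {
  check_square_dist(D)
  n <- nrow(D)
  k_max <- min(k_max, n - 1)
  if (k_min > k_max) stopf("empty k range for %d items", n)
  ks <- seq(k_min, k_max)
  fits <- lapply(ks, function(k) {
    labels <- hierarchical_clusters(D, k, linkage)
    sil <- silhouette_scores(D, labels)
    list(k = k, labels = labels, s = sil$s, mean_s = sil$mean)
  })
  means <- vapply(fits, `[[`, 0, "mean_s")
  best <- fits[[which.max(means)]]   # which.max takes the first (smallest k) tie
  structure(list(ids = rownames(D) %||% as.character(seq_len(n)),
                 labels = best$labels, k = best$k,
                 s = best$s, mean_s = best$mean_s,
                 by_k = data.frame(k = ks, mean_silhouette = means)),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  sizes <- table(x$labels)
  cat(sprintf("clustering_result: k = %d (mean silhouette %.3f)\n",
              x$k, x$mean_s))
  cat("cluster sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  invisible(x)
}

cluster_members <- function(result) {
  split(result$ids, result$labels)
}
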