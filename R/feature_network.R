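#' Remove constant, near-constant, and incomplete descriptors
#'
#' Drops any descriptor with at least one missing value, and any descriptor
#' whose most frequent value occurs in at least `near_constant_frac` of the
#' drugs (constants are the `frac = 1` case).
#'
#' @param table drugs x descriptors numeric matrix, `NA` allowed.
#' @param near_constant_frac near-constancy threshold (default 0.95).
#' @return The filtered descriptor matrix.
#' @export
clean_descriptors <- function(table, near_constant_frac = 0.95) {
  stopifnot(is.matrix(table), nrow(table) >= 1, ncol(table) >= 1)
  has_na <- colSums(is.na(table)) > 0
  modal_frac <- apply(table, 2, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(1)
    max(tabulate(match(x, unique(x)))) / nrow(table)
  })
  near_const <- !has_na & modal_frac >= near_constant_frac
  keep <- !(has_na | near_const)
  if (!any(keep)) stopf("no descriptor survives cleaning")
  if (any(!keep))
    msgf("clean_descriptors: dropped %d with missing values, %d (near-)constant",
         sum(has_na), sum(near_const))
  table[, keep, drop = FALSE]
}

#' Reduce descriptor redundancy by Spearman-correlation clustering
#'
#' Descriptors are clustered by average-linkage hierarchical clustering on the
#' dissimilarity `1 - |Spearman rho|`, the tree is cut at exactly
#' `target_count` clusters, and each cluster is represented by the descriptor
#' with the highest average absolute correlation to the other members
#' (singletons represent themselves; ties go to the lowest column index).
#'
#' @param table drugs x descriptors numeric matrix without missing values.
#' @param target_count number of descriptors to keep.
#' @return List with `table` (reduced matrix) and `report` (cluster
#'   membership, representatives, and each representative's average
#'   intra-cluster correlation).
#' @export
spearman_reduce <- function(table, target_count = 500) {
  stopifnot(is.matrix(table), nrow(table) >= 3)
  p <- ncol(table)
  if (target_count > p) stopf("target_count exceeds descriptor count")
  if (any(apply(table, 2, sd) == 0))
    stopf("constant descriptor present; run clean_descriptors first")
  rho <- suppressWarnings(cor(table, method = "spearman"))
  if (anyNA(rho)) stopf("undefined Spearman correlation; clean the table first")
  if (target_count == p) {
    report <- list(membership = stats::setNames(seq_len(p), colnames(table)),
                   representatives = colnames(table),
                   avg_cor = stats::setNames(rep(NA_real_, p), colnames(table)))
    return(list(table = table, report = report))
  }
  diss <- 1 - abs(rho)
  diag(diss) <- 0
  hc <- hclust(as.dist(diss), method = "average")
  membership <- cutree(hc, k = target_count)
  reps <- integer(target_count)
  avg_cor <- rep(NA_real_, target_count)
  for (cl in seq_len(target_count)) {
    members <- which(membership == cl)
    if (length(members) == 1) {
      reps[cl] <- members
    } else {
      score <- vapply(members, function(m)
        mean(abs(rho[m, setdiff(members, m)])), 0)
      best <- members[score == max(score)]
      reps[cl] <- min(best)                       # tie -> lowest column index
      avg_cor[cl] <- max(score)
    }
  }
  keep <- sort(reps)
  list(table = table[, keep, drop = FALSE],
       report = list(membership = stats::setNames(membership, colnames(table)),
                     representatives = colnames(table)[reps],
                     avg_cor = stats::setNames(avg_cor, colnames(table)[reps])))
}

#' Graphical lasso estimate of a sparse precision matrix
#'
#' L1-penalized Gaussian maximum likelihood,
#' \deqn{\hat\Theta = \arg\max_\Theta \log\det\Theta - tr(S\Theta) -
#'   \lambda \|\Theta\|_{1,off}},
#' solved by block coordinate descent over columns with a lasso coordinate
#' descent inner loop (the standard glasso scheme). Nonzero off-diagonals of
#' \eqn{\hat\Theta} are the conditional-dependence edges.
#'
#' @param S sample covariance matrix (typically of standardized variables).
#' @param lambda penalty, `> 0`.
#' @param tol convergence tolerance on the average absolute change of the
#'   working covariance (relative to the average off-diagonal `|S|`).
#' @param max_iter maximum outer sweeps.
#' @return List with `Theta` (precision estimate), `W` (estimated
#'   covariance), `iterations`, and `lambda`.
#' @export
graphical_lasso <- function(S, lambda, tol = 1e-6, max_iter = 200) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), lambda > 0)
  p <- nrow(S)
  if (p < 2) stopf("need at least two variables")
  res <- .glasso_cpp(S, lambda, tol, as.integer(max_iter))
  dimnames(res$Theta) <- dimnames(S)
  dimnames(res$W) <- dimnames(S)
  list(Theta = res$Theta, W = res$W, iterations = res$iterations,
       lambda = lambda)
}

theta_edges <- function(Theta, eps = 1e-8) {
  p <- nrow(Theta)
  idx <- which(upper.tri(Theta) & abs(Theta) > eps, arr.ind = TRUE)
  cbind(rownames(Theta)[idx[, 1]], colnames(Theta)[idx[, 2]])
}

#' Build the cheminformatic feature network via the graphical lasso
#'
#' Standardizes descriptors, estimates the sparse precision matrix at
#' `lambda`, and turns its nonzero off-diagonals into an undirected feature
#' network. When `lambda` is `NULL` it is chosen as the smallest value on a
#' log-spaced grid whose network's largest connected component contains at
#' most `max_lcc_frac` of the descriptors (and at least 3 of them),
#' mirroring the intended strong reduction from descriptors to a compact
#' connected feature core; when the LCC-size profile jumps straight over
#' that budget, the grid value with LCC closest to the budget on a log scale
#' is used instead.
#'
#' @param table drugs x descriptors numeric matrix (cleaned, no missing
#'   values, at least 3 drugs).
#' @param lambda glasso penalty, or `NULL` for the grid rule.
#' @param max_lcc_frac LCC-size budget used by the grid rule (default 1/3).
#' @param grid_length,grid_min grid resolution and lower end (as a fraction
#'   of the maximum absolute off-diagonal covariance).
#' @inheritParams graphical_lasso
#' @return Object of class `feature_network`: list with `network`
#'   (a [gene_network()] over descriptors), `Theta`, `lambda`, and `S`.
#' @export
feature_network <- function(table, lambda = NULL, max_lcc_frac = 1 / 3,
                            grid_length = 25, grid_min = 0.02,
                            tol = 1e-6, max_iter = 200) {
  stopifnot(is.matrix(table))
  if (nrow(table) < 3) stopf("need at least 3 drugs")
  if (anyNA(table)) stopf("descriptor table contains missing values; clean first")
  X <- scale(table)
  if (anyNA(X)) stopf("constant descriptor present; clean first")
  S <- crossprod(X) / (nrow(X) - 1)
  p <- ncol(S)
  fit_at <- function(l) graphical_lasso(S, l, tol = tol, max_iter = max_iter)
  if (is.null(lambda)) {
    lmax <- max(abs(S[upper.tri(S)]))
    grid <- exp(seq(log(lmax), log(lmax * grid_min), length.out = grid_length))
    fits <- lapply(grid, fit_at)
    nets <- lapply(fits, function(f) network_from_theta(f$Theta))
    sizes <- vapply(nets, lcc_node_count, 0L)
    target <- max_lcc_frac * p
    ok <- which(sizes >= 3 & sizes <= target)
    pick <- if (length(ok)) {
      max(ok)  # grid is descending, so the last qualifying index = smallest lambda
    } else {
      # the size profile jumps over the budget: take the lambda whose LCC is
      # closest to it on a log scale (ties -> sparser network)
      which.min(abs(log(pmax(sizes, 1) / target)))
    }
    fit <- fits[[pick]]; net <- nets[[pick]]; lambda <- grid[pick]
  } else {
    fit <- fit_at(lambda)
    net <- network_from_theta(fit$Theta)
  }
  structure(list(network = net, Theta = fit$Theta, lambda = lambda, S = S),
            class = "feature_network")
}

network_from_theta <- function(Theta, eps = 1e-8) {
  el <- theta_edges(Theta, eps)
  suppressMessages(gene_network(el, nodes = rownames(Theta)))
}

lcc_node_count <- function(network) {
  if (!nrow(network$edges)) return(if (length(network$nodes)) 1L else 0L)
  lcc <- suppressMessages(restrict_to_lcc(network))
  length(lcc$nodes)
}

#' @export
print.feature_network <- function(x, ...) {
  cat(sprintf("feature_network: %d descriptors, %d edges, lambda = %.4g\n",
              length(x$network$nodes), nrow(x$network$edges), x$lambda))
  invisible(x)
}

#' Represent drugs as probability distributions on the feature network
#'
#' Restricts to the feature network's largest connected component, min-max
#' scales each descriptor to `[0, 1]` across drugs (descriptors can be
#' negative, while a probability vector cannot), then normalizes each drug's
#' scaled profile to sum to one over the component's nodes. Unlike the
#' cell-line side, no Markov invariant measure is taken: the feature network
#' encodes statistical association between descriptors, not a physical
#' interaction along which signal would propagate.
#'
#' @param table drugs x descriptors numeric matrix covering the feature
#'   network's nodes.
#' @param fnet a [feature_network()] (or a `gene_network` over descriptors).
#' @return List with `distributions` (named list of `mass_distribution`s, one
#'   per drug) and `network` (the LCC as a [gene_network()]).
#' @export
drug_distributions <- function(table, fnet) {
  net <- if (inherits(fnet, "feature_network")) fnet$network else fnet
  stopifnot(inherits(net, "gene_network"))
  lcc <- suppressMessages(restrict_to_lcc(net))
  missing <- setdiff(lcc$nodes, colnames(table))
  if (length(missing))
    stopf("descriptor value missing for network node(s): %s",
          paste(head(missing, 5), collapse = ", "))
  V <- table[, lcc$nodes, drop = FALSE]
  rng_lo <- apply(V, 2, min)
  rng_hi <- apply(V, 2, max)
  span <- rng_hi - rng_lo
  if (any(span == 0))
    stopf("constant descriptor on the network LCC: %s",
          paste(head(lcc$nodes[span == 0], 5), collapse = ", "))
  Vs <- sweep(sweep(V, 2, rng_lo, "-"), 2, span, "/")
  dists <- vector("list", nrow(Vs))
  names(dists) <- rownames(Vs)
  for (i in seq_len(nrow(Vs))) {
    tot <- sum(Vs[i, ])
    if (tot <= 0)
      stopf("drug %s scales to an all-zero profile", rownames(Vs)[i] %||% i)
    dists[[i]] <- mass_distribution(Vs[i, ] / tot, lcc$nodes, z = tot)
  }
  list(distributions = dists, network = lcc)
}
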