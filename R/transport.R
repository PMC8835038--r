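#' Shortest-path ground metric of a network
#'
#' All-pairs unweighted shortest-path (hop) distances, the ground cost under
#' which one unit of probability mass moved along one edge costs one. The
#' returned object keeps the graph so that [wasserstein1()] can solve the
#' transport problem as a min-cost flow on the (sparse) network itself; an
#' arbitrary symmetric cost matrix can be substituted via [as_ground_metric()].
#'
#' @param network a connected [gene_network()].
#' @return Object of class `ground_metric`: list with `d` (dense symmetric
#'   distance matrix), `ids`, and the graph's `edges`/`weights` when the
#'   metric is the graph metric.
#' @export
ground_metric <- function(network) {
  g <- as_igraph(network)
  d <- igraph::distances(g)
  if (any(!is.finite(d))) stopf("network is disconnected")
  d <- d[network$nodes, network$nodes]
  structure(list(d = d, ids = network$nodes,
                 edges = network$edges,
                 weights = rep(1, nrow(network$edges))),
            class = "ground_metric")
}

#' Wrap an arbitrary symmetric cost matrix as a ground metric
#'
#' @param d symmetric nonnegative matrix with zero diagonal and matching
#'   dimnames.
#' @return A `ground_metric` without an attached graph; [wasserstein1()] then
#'   solves the dense transportation problem instead of a graph flow.
#' @export
as_ground_metric <- function(d) {
  check_square_dist(d)
  if (is.null(rownames(d))) stopf("cost matrix needs dimnames")
  structure(list(d = d, ids = rownames(d), edges = NULL, weights = NULL),
            class = "ground_metric")
}

#' @export
print.ground_metric <- function(x, ...) {
  cat(sprintf("ground_metric on %d nodes (%s)\n", length(x$ids),
              if (is.null(x$edges)) "dense cost matrix" else "graph hop metric"))
  invisible(x)
}

check_measure <- function(mu, ids, what) {
  mu <- unclass(mu)
  if (is.null(names(mu))) {
    if (length(mu) != length(ids)) stopf("%s: index mismatch", what)
  } else {
    if (!setequal(names(mu), ids)) stopf("%s: index mismatch", what)
    mu <- mu[ids]
  }
  if (any(mu < -1e-12)) stopf("%s: negative mass", what)
  if (abs(sum(mu) - 1) > 1e-8) stopf("%s: mass must sum to 1", what)
  pmax(as.numeric(mu), 0)
}

#' Exact W1 (earth mover's) distance between two node distributions
#'
#' Minimum cost of transporting `mu` into `nu` under the ground metric:
#' \deqn{W_1(\mu,\nu) = \min_{T \ge 0} \sum_{ij} T_{ij} d_{ij}}
#' subject to row sums \eqn{\mu} and column sums \eqn{\nu}. Solved exactly by
#' successive-shortest-path min-cost flow: on the network itself when the
#' ground metric is the graph metric, otherwise as a dense bipartite
#' transportation problem between the surplus and deficit of \eqn{\mu-\nu}.
#'
#' @param mu,nu probability vectors on the metric's node set
#'   ([invariant_measure()] output or plain named vectors summing to 1).
#' @param d a [ground_metric()].
#' @param method `"auto"` (graph flow when available), `"flow"`, or `"dense"`.
#' @return Nonnegative scalar distance.
#' @export
wasserstein1 <- function(mu, nu, d, method = c("auto", "flow", "dense")) {
  method <- match.arg(method)
  stopifnot(inherits(d, "ground_metric"))
  mu <- check_measure(mu, d$ids, "mu")
  nu <- check_measure(nu, d$ids, "nu")
  use_flow <- switch(method,
    auto = !is.null(d$edges),
    flow = { if (is.null(d$edges)) stopf("no graph attached to this metric"); TRUE },
    dense = FALSE)
  if (use_flow) {
    .emd_graph_cpp(d$edges - 1L, d$weights, length(d$ids), mu, nu)
  } else {
    .emd_dense_cpp(d$d, mu, nu)
  }
}

#' Pairwise W1 distance matrix
#'
#' @param measures named list of probability vectors on a shared node set.
#' @inheritParams wasserstein1
#' @return Symmetric nonnegative matrix with zero diagonal, one row/column per
#'   measure, dimnames taken from the list names.
#' @export
pairwise_wasserstein <- function(measures, d, method = c("auto", "flow", "dense")) {
  method <- match.arg(method)
  if (length(measures) < 2) stopf("need at least two measures")
  ids <- names(measures) %||% as.character(seq_along(measures))
  n <- length(measures)
  mus <- lapply(seq_len(n), function(i)
    check_measure(measures[[i]], d$ids, paste0("measure ", ids[i])))
  use_flow <- switch(method,
    auto = !is.null(d$edges),
    flow = { if (is.null(d$edges)) stopf("no graph attached to this metric"); TRUE },
    dense = FALSE)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (use_flow) {
    e0 <- d$edges - 1L
    nn <- length(d$ids)
    for (i in seq_len(n - 1))
      for (j in seq((i + 1), n))
        D[i, j] <- D[j, i] <- .emd_graph_cpp(e0, d$weights, nn,
                                             mus[[i]], mus[[j]])
  } else {
    for (i in seq_len(n - 1))
      for (j in seq((i + 1), n))
        D[i, j] <- D[j, i] <- .emd_dense_cpp(d$d, mus[[i]], mus[[j]])
  }
  D
}
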