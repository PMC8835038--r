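#' Expression-weighted Markov transition matrix on a gene network
#'
#' Mass action makes the probability that gene i passes signal to a neighbor
#' j proportional to j's expression, so each row of the chain is the
#' neighborhood expression profile renormalized:
#' \deqn{p_{ij} = ge_j / \sum_{k \in N_i} ge_k \quad (j \in N_i).}
#'
#' @param expr_row named nonnegative numeric vector covering every network
#'   node (extra genes are ignored).
#' @param network a connected [gene_network()].
#' @param epsilon optional smoothing: when `> 0`, `epsilon * mean positive
#'   expression` is added to every gene before normalization, so zero
#'   neighborhoods cannot arise. Off (`0`) by default.
#' @return Row-stochastic matrix with node dimnames; `p[i, j] > 0` only for
#'   neighbors `j` of `i`.
#' @export
transition_matrix <- function(expr_row, network, epsilon = 0) {
  ge <- prepare_expression(expr_row, network, epsilon)
  n <- length(network$nodes)
  p <- matrix(0, n, n, dimnames = list(network$nodes, network$nodes))
  for (i in seq_len(n)) {
    nb <- network$adj[[i]]
    tot <- sum(ge[nb])
    if (tot <= 0)
      stopf("degenerate row: all neighbors of %s have zero expression (enable epsilon smoothing)",
            network$nodes[i])
    p[i, nb] <- ge[nb] / tot
  }
  p
}

prepare_expression <- function(expr_row, network, epsilon) {
  if (is.null(names(expr_row))) stopf("expression vector must be named")
  missing <- setdiff(network$nodes, names(expr_row))
  if (length(missing))
    stopf("expression value missing for node(s): %s",
          paste(head(missing, 5), collapse = ", "))
  ge <- as.numeric(expr_row[network$nodes])
  if (anyNA(ge)) stopf("expression contains NA on network nodes")
  if (any(ge < 0))
    stopf("negative expression value; the chain needs a nonnegative scale")
  if (any(lengths(network$adj) == 0))
    stopf("network has isolated node(s); restrict to a connected component first")
  if (epsilon > 0) {
    pos <- ge[ge > 0]
    if (length(pos)) ge <- ge + epsilon * mean(pos)
  }
  names(ge) <- network$nodes
  ge
}

#' Invariant measure of the expression chain
#'
#' The stationary distribution of the chain of [transition_matrix()] has the
#' closed form \deqn{\pi_i = \frac{1}{Z}\, ge_i \sum_{j \in N_i} ge_j,} with Z
#' normalizing \eqn{\pi} to a probability vector; \eqn{\pi p = \pi}. The
#' measure weights each gene by its own expression and by its neighborhood's
#' total expression, which is what the Wasserstein comparison between samples
#' transports.
#'
#' @inheritParams transition_matrix
#' @return A `mass_distribution`: named probability vector over the network
#'   nodes with the normalization constant in `attr(, "Z")`.
#' @export
invariant_measure <- function(expr_row, network, epsilon = 0) {
  ge <- prepare_expression(expr_row, network, epsilon)
  unnorm <- vapply(seq_along(ge), function(i) ge[i] * sum(ge[network$adj[[i]]]),
                   0)
  z <- sum(unnorm)
  if (z <= 0) stopf("total unnormalized mass is zero")
  mass_distribution(unnorm / z, network$nodes, z = z)
}

mass_distribution <- function(p, ids, z = NA_real_) {
  p <- as.numeric(p)
  names(p) <- ids
  if (any(p < 0)) stopf("mass distribution has negative entries")
  if (abs(sum(p) - 1) > 1e-12) p <- p / sum(p)
  structure(p, Z = z, class = "mass_distribution")
}

#' @export
print.mass_distribution <- function(x, ...) {
  cat(sprintf("mass_distribution on %d nodes (Z = %.6g)\n",
              length(x), attr(x, "Z")))
  print(utils::head(unclass(x)), ...)
  invisible(x)
}

#' Invariant measures for every sample of an expression matrix
#'
#' @param expr samples x genes nonnegative matrix; columns must cover the
#'   network nodes.
#' @inheritParams transition_matrix
#' @return Named list of `mass_distribution`s, in the sample order of `expr`.
#' @export
invariant_measures <- function(expr, network, epsilon = 0) {
  stopifnot(is.matrix(expr))
  out <- vector("list", nrow(expr))
  names(out) <- rownames(expr)
  for (s in seq_len(nrow(expr))) {
    out[[s]] <- tryCatch(
      invariant_measure(expr[s, ], network, epsilon = epsilon),
      error = function(e)
        stopf("sample %s: %s", rownames(expr)[s] %||% s, conditionMessage(e)))
  }
  out
}
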