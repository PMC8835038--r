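# Shared fixtures and independent oracles used across the suite.

path3 <- function() gene_network(rbind(c("g1", "g2"), c("g2", "g3")))

star4 <- function() gene_network(rbind(c("c", "l1"), c("c", "l2"), c("c", "l3")))

# Deterministic random connected graph (G(n, p) with seeded retries).
rand_connected_graph <- function(n, seed, p = NULL) {
  if (is.null(p)) p <- min(1, 2.5 * log(n) / n)
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  for (try in 1:100) {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) > 0) {
      el <- igraph::as_edgelist(g, names = FALSE)
      return(suppressMessages(
        gene_network(cbind(nodes[el[, 1]], nodes[el[, 2]]), nodes = nodes)))
    }
  }
  stop("could not draw a connected graph")
}

rand_measure <- function(n, ids) {
  x <- runif(n, 0.05, 1)
  stats::setNames(x / sum(x), ids)
}

# Brute-force transportation LP via boot::simplex: all n^2 coupling
# variables, equality-constrained marginals (last column constraint dropped
# as redundant). Independent of the package's min-cost-flow solver.
lp_wasserstein <- function(mu, nu, d) {
  n <- length(mu)
  cost <- as.vector(d)             # column-major: T[i, j] at (j-1)*n + i
  A3 <- matrix(0, 2 * n - 1, n * n)
  b3 <- numeric(2 * n - 1)
  for (i in seq_len(n)) {          # row sums = mu
    A3[i, (seq_len(n) - 1) * n + i] <- 1
    b3[i] <- mu[i]
  }
  for (j in seq_len(n - 1)) {      # column sums = nu (last dropped)
    A3[n + j, (j - 1) * n + seq_len(n)] <- 1
    b3[n + j] <- nu[j]
  }
  res <- boot::simplex(a = cost, A3 = A3, b3 = b3, maxi = FALSE,
                       eps = 1e-12, n.iter = 50 * n * n)
  unname(res$value)
}

# Direct transcription of the silhouette formula (triple loop, no reuse of
# package internals).
brute_silhouette <- function(D, labels) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- sum(D[i, setdiff(own, i)]) / (length(own) - 1)
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      mem <- which(labels == cl)
      b <- min(b, sum(D[i, mem]) / length(mem))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

# Exact hypergeometric upper tail by explicit choose() sums.
brute_hyper_tail <- function(overlap, set_size, universe, selection) {
  ks <- overlap:min(set_size, selection)
  sum(choose(set_size, ks) * choose(universe - set_size, selection - ks)) /
    choose(universe, selection)
}

rand_dist_matrix <- function(n) {
  pts <- matrix(runif(n * 3), n)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(sprintf("i%02d", 1:n), sprintf("i%02d", 1:n))
  D
}

# Block-structured distance matrix with planted clusters.
planted_dist_matrix <- function(sizes, within = 1, between = 10, noise = 0.05) {
  labels <- rep(seq_along(sizes), sizes)
  n <- length(labels)
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    base <- if (labels[i] == labels[j]) within else between
    D[i, j] <- D[j, i] <- base * (1 + noise * runif(1, -1, 1))
  }
  dimnames(D) <- list(sprintf("i%03d", 1:n), sprintf("i%03d", 1:n))
  list(D = D, labels = labels)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# One-drug design whose response is driven by a single gene; used for
# importance-ranking checks.
importance_fixture <- function(seed, n = 80, informative = "g05",
                               noise_sd = 0.2) {
  set.seed(seed)
  cells <- sprintf("c%03d", seq_len(n))
  genes <- sprintf("g%02d", 1:10)
  expr <- matrix(runif(n * 10, 1, 3), n, 10, dimnames = list(cells, genes))
  desc <- matrix(0.5, 1, 2, dimnames = list("d1", c("x1", "x2")))
  y <- matrix(2 * expr[, informative] + rnorm(n, 0, noise_sd), n, 1,
              dimnames = list(cells, "d1"))
  assemble_design(cells, "d1", expr, desc, y)
}
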