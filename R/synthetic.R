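#' Define a synthetic drug-sensitivity study
#'
#' Bundles the sizes and effect parameters of the seeded generators that
#' emulate the four study inputs: expression with planted cell-line clusters,
#' descriptors with planted drug clusters from a sparse Gaussian graphical
#' model, a scale-free interaction network, and a log(IC50) response surface
#' whose informative features differ per (cell cluster, drug cluster) pair —
#' the mechanism that makes per-cluster modeling genuinely better than
#' pooled modeling.
#'
#' @param n_cells,n_drugs,n_genes,n_descriptors table sizes.
#' @param k_cells,k_drugs number of planted clusters.
#' @param delta multiplicative expression shift (log scale) of a cell
#'   cluster's gene module.
#' @param sigma response noise standard deviation (log(IC50) units).
#' @param descriptor_offset drug-cluster mean shift on its descriptor block,
#'   in marginal standard deviations.
#' @param base_sd standard deviation of the per-paired-cluster baseline
#'   log(IC50) levels.
#' @param effect_size coefficient magnitude of the cluster-specific feature
#'   effects (applied to standardized features).
#' @param n_effect_genes,n_effect_descriptors number of informative features
#'   drawn per paired cluster.
#' @param missing_rate completely-at-random missingness of the response table.
#' @param attachment edges added per node in the preferential-attachment
#'   network.
#' @param n_constant,n_near_constant,n_missing junk descriptors injected to
#'   exercise [clean_descriptors()].
#' @param seed master seed; every generator derives its own stream from it.
#' @return Object of class `synthetic_scenario` (a validated list).
#' @export
synthetic_scenario <- function(n_cells = 120, n_drugs = 40, n_genes = 60,
                               n_descriptors = 45, k_cells = 4, k_drugs = 3,
                               delta = 1.0, sigma = 0.5,
                               descriptor_offset = 2, base_sd = 2,
                               effect_size = 1, n_effect_genes = 3,
                               n_effect_descriptors = 2, missing_rate = 0.1,
                               attachment = 2, n_constant = 2,
                               n_near_constant = 2, n_missing = 2, seed = 1) {
  sc <- list(n_cells = n_cells, n_drugs = n_drugs, n_genes = n_genes,
             n_descriptors = n_descriptors, k_cells = k_cells,
             k_drugs = k_drugs, delta = delta, sigma = sigma,
             descriptor_offset = descriptor_offset, base_sd = base_sd,
             effect_size = effect_size, n_effect_genes = n_effect_genes,
             n_effect_descriptors = n_effect_descriptors,
             missing_rate = missing_rate, attachment = attachment,
             n_constant = n_constant, n_near_constant = n_near_constant,
             n_missing = n_missing, seed = seed)
  stopifnot(n_cells >= 2, n_drugs >= 2, n_genes >= 2, n_descriptors >= 2,
            k_cells >= 2, k_drugs >= 2, sigma > 0, missing_rate >= 0,
            missing_rate < 1, n_genes >= attachment + 1,
            k_cells <= n_cells, k_drugs <= n_drugs,
            k_cells <= n_genes, k_drugs <= n_descriptors)
  structure(sc, class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(
    "synthetic_scenario: %d cells x %d drugs, %d genes, %d descriptors, %dx%d clusters, seed %d\n",
    x$n_cells, x$n_drugs, x$n_genes, x$n_descriptors,
    x$k_cells, x$k_drugs, x$seed))
  invisible(x)
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  expr
}

gene_names <- function(n) sprintf("g%03d", seq_len(n))
cell_names <- function(n) sprintf("cell%03d", seq_len(n))
drug_names <- function(n) sprintf("drug%03d", seq_len(n))
desc_names <- function(n) sprintf("x%03d", seq_len(n))

#' Generate a connected scale-free interaction network
#'
#' Preferential attachment: each new node attaches to `attachment` existing
#' nodes, so the graph is connected by construction and has the heavy-tailed
#' degree profile typical of protein-interaction networks.
#'
#' @param n_genes number of nodes.
#' @param attachment edges per new node.
#' @param seed integer seed.
#' @return A [gene_network()] with nodes `g001 ...`.
#' @export
make_ppi <- function(n_genes, attachment = 2, seed = 1) {
  stopifnot(n_genes >= attachment + 1)
  g <- with_seed(seed,
    igraph::sample_pa(n_genes, power = 1, m = attachment, directed = FALSE))
  el <- igraph::as_edgelist(g, names = FALSE)
  nms <- gene_names(n_genes)
  suppressMessages(
    gene_network(cbind(nms[el[, 1]], nms[el[, 2]]), nodes = nms))
}

planted_modules <- function(n_genes, k) {
  # round-robin so every module holds a comparable mix of hub and leaf genes
  rep_len(seq_len(k), n_genes)
}

#' Generate expression with planted cell-line clusters
#'
#' Baseline expression is LogNormal(0, 0.25); the genes are split round-robin
#' into `k_cells` modules and cells of cluster g carry a multiplicative
#' `exp(delta)` shift on module g. All values are strictly positive.
#'
#' @param scenario a [synthetic_scenario()].
#' @return List with `expr` (cells x genes matrix), `labels` (planted cell
#'   clusters), and `modules` (gene-to-cluster module map).
#' @export
make_expression <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  n <- scenario$n_cells; g <- scenario$n_genes; k <- scenario$k_cells
  labels <- stats::setNames(rep_len(seq_len(k), n), cell_names(n))
  modules <- stats::setNames(planted_modules(g, k), gene_names(g))
  expr <- with_seed(derive_seed(scenario$seed, "expression"), {
    m <- matrix(rlnorm(n * g, meanlog = 0, sdlog = 0.25), n, g,
                dimnames = list(cell_names(n), gene_names(g)))
    for (cl in seq_len(k)) {
      rows <- labels == cl
      cols <- modules == cl
      m[rows, cols] <- m[rows, cols] * exp(scenario$delta)
    }
    m
  })
  list(expr = expr, labels = labels, modules = modules)
}

chain_precision <- function(p, rho = 0.25) {
  Theta <- diag(1, p)
  for (i in seq_len(p - 1)) Theta[i, i + 1] <- Theta[i + 1, i] <- -rho
  Theta
}

#' Generate descriptors with planted drug clusters
#'
#' Informative descriptors follow a zero-mean Gaussian graphical model with a
#' known chain precision matrix (every consecutive pair conditionally
#' dependent), so the feature network is connected and its support is known
#' for recovery experiments. Drug clusters get a mean offset of
#' `descriptor_offset` marginal standard deviations on a contiguous
#' descriptor block. Constant, near-constant, and missing-value junk
#' descriptors are appended to exercise [clean_descriptors()].
#'
#' @inheritParams make_expression
#' @return List with `descriptors` (drugs x descriptors, junk included),
#'   `labels` (planted drug clusters), `precision` (true precision matrix of
#'   the informative part), `informative` and `junk` descriptor names.
#' @export
make_descriptors <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  n <- scenario$n_drugs; p <- scenario$n_descriptors; k <- scenario$k_drugs
  labels <- stats::setNames(rep_len(seq_len(k), n), drug_names(n))
  Theta <- chain_precision(p)
  Sigma <- solve(Theta)
  sd_marg <- sqrt(diag(Sigma))
  block <- floor(p / k)
  out <- with_seed(derive_seed(scenario$seed, "descriptors"), {
    X <- matrix(rnorm(n * p), n, p) %*% chol(Sigma)
    dimnames(X) <- list(drug_names(n), desc_names(p))
    for (cl in seq_len(k)) {
      cols <- seq((cl - 1) * block + 1, cl * block)
      X[labels == cl, cols] <- X[labels == cl, cols] +
        rep(scenario$descriptor_offset * sd_marg[cols],
            each = sum(labels == cl))
    }
    junk <- list()
    if (scenario$n_constant > 0)
      for (i in seq_len(scenario$n_constant))
        junk[[paste0("junk_const", i)]] <- rep(1, n)
    if (scenario$n_near_constant > 0)
      for (i in seq_len(scenario$n_near_constant)) {
        v <- rep(0, n); v[sample.int(n, 1)] <- 1
        junk[[paste0("junk_nc", i)]] <- v
      }
    if (scenario$n_missing > 0)
      for (i in seq_len(scenario$n_missing)) {
        v <- rnorm(n); v[sample.int(n, 1)] <- NA
        junk[[paste0("junk_na", i)]] <- v
      }
    if (length(junk)) X <- cbind(X, do.call(cbind, junk))
    X
  })
  dimnames(Theta) <- list(desc_names(p), desc_names(p))
  list(descriptors = out, labels = labels, precision = Theta,
       informative = desc_names(p),
       junk = setdiff(colnames(out), desc_names(p)))
}

#' Generate the cluster-dependent log(IC50) response surface
#'
#' \eqn{y(c,d) = B[g_c, g_d] + \sum \beta\, z(features) + N(0, \sigma^2)}
#' where B is a `k_cells x k_drugs` baseline drawn once per seed and the
#' informative genes/descriptors (and their signs) are drawn separately for
#' every paired cluster, so no single pooled model matches all pairs.
#' Missingness is completely at random at `missing_rate`.
#'
#' @param cell_labels,drug_labels planted cluster labels.
#' @param expr cells x genes expression matrix.
#' @param descriptors drugs x descriptors matrix (junk columns ignored).
#' @inheritParams make_expression
#' @return Cells x drugs numeric matrix with `NA` for missing entries; the
#'   baseline matrix and per-paired-cluster effects are attached as
#'   attributes `B` and `effects`.
#' @export
make_responses <- function(cell_labels, drug_labels, expr, descriptors,
                           scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  cells <- names(cell_labels); drugs <- names(drug_labels)
  stopifnot(all(cells %in% rownames(expr)),
            all(drugs %in% rownames(descriptors)))
  informative <- intersect(desc_names(scenario$n_descriptors),
                           colnames(descriptors))
  Zg <- scale(expr[cells, , drop = FALSE])
  Zd <- scale(descriptors[drugs, informative, drop = FALSE])
  Zg[is.na(Zg)] <- 0; Zd[is.na(Zd)] <- 0
  kc <- scenario$k_cells; kd <- scenario$k_drugs
  with_seed(derive_seed(scenario$seed, "responses"), {
    B <- matrix(rnorm(kc * kd, 0, scenario$base_sd), kc, kd)
    effects <- list()
    Y <- matrix(0, length(cells), length(drugs),
                dimnames = list(cells, drugs))
    for (gc in seq_len(kc)) {
      for (gd in seq_len(kd)) {
        eg <- sample(colnames(Zg), scenario$n_effect_genes)
        ed <- sample(colnames(Zd), scenario$n_effect_descriptors)
        bg <- sample(c(-1, 1), length(eg), replace = TRUE) * scenario$effect_size
        bd <- sample(c(-1, 1), length(ed), replace = TRUE) * scenario$effect_size
        rows <- cell_labels == gc
        cols <- drug_labels == gd
        contrib <- outer(as.numeric(Zg[rows, eg, drop = FALSE] %*% bg),
                         rep(1, sum(cols))) +
                   outer(rep(1, sum(rows)),
                         as.numeric(Zd[cols, ed, drop = FALSE] %*% bd))
        Y[rows, cols] <- B[gc, gd] + contrib
        effects[[paste0("c", gc, ".d", gd)]] <-
          list(genes = eg, gene_beta = bg, descriptors = ed,
               descriptor_beta = bd)
      }
    }
    Y <- Y + matrix(rnorm(length(Y), 0, scenario$sigma), nrow(Y), ncol(Y))
    if (scenario$missing_rate > 0) {
      drop <- matrix(runif(length(Y)) < scenario$missing_rate,
                     nrow(Y), ncol(Y))
      Y[drop] <- NA_real_
    }
    attr(Y, "B") <- B
    attr(Y, "effects") <- effects
    Y
  })
}

#' Generate a complete synthetic study
#'
#' Runs all four generators of a scenario and returns the tables together
#' with the planted truth.
#'
#' @inheritParams make_expression
#' @return List with `network`, `expr`, `descriptors`, `responses`,
#'   `cell_labels`, `drug_labels`, `modules`, `precision`, and the
#'   `scenario` itself.
#' @export
simulate_study <- function(scenario = synthetic_scenario()) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  network <- make_ppi(scenario$n_genes, scenario$attachment,
                      seed = derive_seed(scenario$seed, "ppi"))
  ex <- make_expression(scenario)
  de <- make_descriptors(scenario)
  responses <- make_responses(ex$labels, de$labels, ex$expr, de$descriptors,
                              scenario)
  list(network = network, expr = ex$expr, descriptors = de$descriptors,
       responses = responses, cell_labels = ex$labels,
       drug_labels = de$labels, modules = ex$modules,
       precision = de$precision, scenario = scenario)
}
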