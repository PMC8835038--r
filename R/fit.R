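#' Fit the network-based clustered drug-sensitivity model
#'
#' End-to-end fit: filters the response table, represents each cell line as
#' the invariant measure of its expression-weighted Markov chain on the
#' interaction network, clusters cell lines by pairwise exact W1 distances
#' (silhouette-selected k), builds the graphical-lasso feature network and
#' drug distributions, clusters drugs the same way, then fits a
#' cross-validated random-forest regression of log(IC50) inside every
#' (cell cluster, drug cluster) pair and concatenates the out-of-fold
#' evaluations.
#'
#' @param expr samples x genes nonnegative expression matrix.
#' @param network a [gene_network()]; it is restricted to the largest
#'   connected component of the genes present in `expr`.
#' @param descriptors drugs x descriptors matrix (missing values allowed;
#'   cleaned internally).
#' @param responses cell-line x drug log(IC50) matrix, `NA` = unmeasured.
#' @param k_cells,k_drugs fixed cluster counts, or `NULL` (default) to select
#'   by maximum mean silhouette over `k_range`.
#' @param k_range candidate k range for [select_k()].
#' @param lambda graphical-lasso penalty; `NULL` uses the LCC-budget grid
#'   rule of [feature_network()].
#' @param spearman_target optional redundancy-reduction target for
#'   [spearman_reduce()] (applied when below the cleaned descriptor count).
#' @param folds,trees,min_leaf random-forest cross-validation settings.
#' @param min_pairs minimum observed pairs for a paired cluster to be
#'   modeled (smaller ones are skipped and recorded).
#' @param max_missing,min_coverage,near_constant_frac filtering thresholds
#'   (see [filter_cell_lines()], [filter_drugs()], [clean_descriptors()]).
#' @param epsilon zero-expression smoothing for [invariant_measure()].
#' @param linkage clustering linkage.
#' @param filter set `FALSE` to skip the response-table filters.
#' @param seed master seed; all randomness is derived from it.
#' @return Object of class `drugsense_fit`. Key components: `cells` and
#'   `drugs` (`clustering_result`s), `distances` (cell and drug W1
#'   matrices), `feature_network`, `cv` (per-paired-cluster out-of-fold
#'   predictions and evaluations), `evaluation` (concatenated), `tables`
#'   (the aligned model tables), `skipped`, `settings`.
#' @seealso [summary.drugsense_fit()], [pooled_crossval()],
#'   [cdcn_evaluate()], [simulate_study()]
#' @export
drugsense <- function(expr, network, descriptors, responses,
                      k_cells = NULL, k_drugs = NULL, k_range = c(2, 15),
                      lambda = NULL, spearman_target = NULL,
                      folds = 3, trees = 100, min_leaf = 5,
                      min_pairs = 2 * folds,
                      max_missing = 0.8, min_coverage = 0.5,
                      near_constant_frac = 0.95, epsilon = 0,
                      linkage = "average", filter = TRUE, seed = 1) {
  cl <- match.call()
  stopifnot(is.matrix(expr), is.matrix(descriptors), is.matrix(responses),
            inherits(network, "gene_network"))
  if (filter) {
    responses <- filter_cell_lines(responses, max_missing)
    responses <- filter_drugs(responses, min_coverage)
  }
  cells <- c_sort(intersect(rownames(responses), rownames(expr)))
  drugs <- c_sort(intersect(colnames(responses), rownames(descriptors)))
  if (length(cells) < 4) stopf("fewer than 4 cell lines with expression")
  if (length(drugs) < 4) stopf("fewer than 4 drugs with descriptors")
  responses <- responses[cells, drugs, drop = FALSE]

  # --- cell-line side: invariant measures and W1 distances on the network
  network <- suppressMessages(restrict_to_lcc(network, colnames(expr)))
  expr <- expr[cells, , drop = FALSE]
  measures <- invariant_measures(expr, network, epsilon = epsilon)
  gm_cells <- ground_metric(network)
  D_cells <- pairwise_wasserstein(measures, gm_cells)
  cell_clusters <- cluster_or_select(D_cells, k_cells, k_range, linkage)

  # --- drug side: feature network and normalized descriptor distributions
  desc_clean <- clean_descriptors(descriptors[drugs, , drop = FALSE],
                                  near_constant_frac)
  reduction <- NULL
  if (!is.null(spearman_target) && spearman_target < ncol(desc_clean)) {
    red <- spearman_reduce(desc_clean, spearman_target)
    desc_clean <- red$table
    reduction <- red$report
  }
  fnet <- feature_network(desc_clean, lambda = lambda)
  dd <- drug_distributions(desc_clean, fnet)
  gm_drugs <- ground_metric(dd$network)
  D_drugs <- pairwise_wasserstein(dd$distributions, gm_drugs)
  drug_clusters <- cluster_or_select(D_drugs, k_drugs, k_range, linkage)

  # --- design tables: expression on network genes, scaled LCC descriptors
  expr_block <- expr[, network$nodes, drop = FALSE]
  desc_block <- minmax_scale(desc_clean[, dd$network$nodes, drop = FALSE])

  # --- per-paired-cluster random forests
  cm <- cluster_members(cell_clusters)
  dm <- cluster_members(drug_clusters)
  cv <- list(); skipped <- character(0)
  idx <- 0
  for (gc in names(cm)) {
    for (gd in names(dm)) {
      idx <- idx + 1
      key <- paste0("c", gc, ".d", gd)
      design <- tryCatch(
        assemble_design(cm[[gc]], dm[[gd]], expr_block, desc_block, responses),
        error = function(e) NULL)
      if (is.null(design) || nrow(design$X) < max(min_pairs, 2 * folds) ||
          sd(design$y) == 0) {
        skipped <- c(skipped, key)
        next
      }
      res <- crossval_rf(design, folds = folds, trees = trees,
                         min_leaf = min_leaf,
                         seed = derive_seed(seed, "rf") + idx)
      cv[[key]] <- list(
        cell_cluster = as.integer(gc), drug_cluster = as.integer(gd),
        pairs = design$pairs,
        predictions = res$predictions, observed = res$observed,
        fold = res$fold,
        evaluation = evaluate_predictions(res$predictions, res$observed))
    }
  }
  if (!length(cv)) stopf("every paired cluster was too small to model")
  overall <- concat_evaluations(lapply(cv, `[[`, "evaluation"))

  structure(list(
    call = cl,
    cells = cell_clusters, drugs = drug_clusters,
    distances = list(cells = D_cells, drugs = D_drugs),
    measures = measures, feature_network = fnet, reduction = reduction,
    drug_measures = dd$distributions,
    network = network, drug_network = dd$network,
    tables = list(expr = expr_block, descriptors = desc_block,
                  responses = responses),
    cv = cv, evaluation = overall, skipped = skipped,
    settings = list(folds = folds, trees = trees, min_leaf = min_leaf,
                    min_pairs = min_pairs, epsilon = epsilon,
                    linkage = linkage, k_range = k_range,
                    lambda = fnet$lambda, seed = seed)),
    class = "drugsense_fit")
}

cluster_or_select <- function(D, k, k_range, linkage) {
  if (is.null(k)) {
    select_k(D, k_min = k_range[1], k_max = k_range[2], linkage = linkage)
  } else {
    labels <- hierarchical_clusters(D, k, linkage)
    sil <- silhouette_scores(D, labels)
    structure(list(ids = rownames(D), labels = labels, k = k,
                   s = sil$s, mean_s = sil$mean,
                   by_k = data.frame(k = k, mean_silhouette = sil$mean)),
              class = "clustering_result")
  }
}

minmax_scale <- function(M) {
  lo <- apply(M, 2, min); hi <- apply(M, 2, max)
  span <- hi - lo
  span[span == 0] <- 1
  sweep(sweep(M, 2, lo, "-"), 2, span, "/")
}

#' @export
print.drugsense_fit <- function(x, ...) {
  cat("Network-based clustered drug-sensitivity model\n")
  cat(sprintf("  cell lines: %d in %d clusters (mean silhouette %.3f)\n",
              length(x$cells$ids), x$cells$k, x$cells$mean_s))
  cat(sprintf("  drugs:      %d in %d clusters (mean silhouette %.3f)\n",
              length(x$drugs$ids), x$drugs$k, x$drugs$mean_s))
  cat(sprintf("  feature network: %d descriptors in LCC (lambda = %.4g)\n",
              length(x$drug_network$nodes), x$feature_network$lambda))
  cat(sprintf("  paired clusters modeled: %d (skipped: %d)\n",
              length(x$cv), length(x$skipped)))
  cat(sprintf("  concatenated out-of-fold: n = %d, R = %.3f, R^2 = %.3f\n",
              x$evaluation$n, x$evaluation$r, x$evaluation$r2))
  invisible(x)
}

#' Summarize a fitted clustered drug-sensitivity model
#'
#' @param object a [drugsense()] fit.
#' @param ... unused.
#' @return Object of class `summary.drugsense_fit` with the per-paired-cluster
#'   evaluation table (`pairs`) and the concatenated evaluation (`overall`).
#' @export
summary.drugsense_fit <- function(object, ...) {
  tab <- do.call(rbind, lapply(names(object$cv), function(key) {
    z <- object$cv[[key]]
    data.frame(pair = key, cell_cluster = z$cell_cluster,
               drug_cluster = z$drug_cluster, n = z$evaluation$n,
               r = z$evaluation$r, r2 = z$evaluation$r2,
               stringsAsFactors = FALSE)
  }))
  structure(list(pairs = tab[c_order(tab$pair), , drop = FALSE],
                 overall = object$evaluation,
                 k_cells = object$cells$k, k_drugs = object$drugs$k,
                 skipped = object$skipped),
            class = "summary.drugsense_fit")
}

#' @export
print.summary.drugsense_fit <- function(x, ...) {
  cat(sprintf("%d cell clusters x %d drug clusters, %d paired models\n",
              x$k_cells, x$k_drugs, nrow(x$pairs)))
  print(x$pairs, row.names = FALSE, digits = 3)
  cat(sprintf("concatenated: n = %d, R = %.3f, R^2 = %.3f\n",
              x$overall$n, x$overall$r, x$overall$r2))
  if (length(x$skipped))
    cat("skipped paired clusters:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
fitted.drugsense_fit <- function(object, ...) {
  unlist(lapply(object$cv, `[[`, "predictions"))
}

#' @export
residuals.drugsense_fit <- function(object, ...) {
  obs <- unlist(lapply(object$cv, `[[`, "observed"))
  obs - fitted(object)
}

#' @export
plot.drugsense_fit <- function(x, ...) {
  obs <- unlist(lapply(x$cv, `[[`, "observed"))
  pred <- unlist(lapply(x$cv, `[[`, "predictions"))
  graphics::plot(obs, pred, xlab = "observed log(IC50)",
                 ylab = "out-of-fold predicted log(IC50)",
                 main = sprintf("R = %.3f, R^2 = %.3f",
                                x$evaluation$r, x$evaluation$r2), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Predict log(IC50) for (cell line, drug) pairs from a fitted model
#'
#' Each requested pair is routed to its (cell cluster, drug cluster) model; a
#' forest is trained on that paired cluster's full design (no
#' cross-validation holdout) and applied to the pair's feature vector. Pairs
#' falling in a skipped paired cluster get `NA`.
#'
#' @param object a [drugsense()] fit.
#' @param pairs data frame with columns `cell` and `drug`, both known to the
#'   fit.
#' @param ... unused.
#' @return Numeric vector of predictions, one per row of `pairs`.
#' @export
predict.drugsense_fit <- function(object, pairs, ...) {
  stopifnot(is.data.frame(pairs), all(c("cell", "drug") %in% names(pairs)))
  cell_lab <- stats::setNames(object$cells$labels, object$cells$ids)
  drug_lab <- stats::setNames(object$drugs$labels, object$drugs$ids)
  unknown_c <- setdiff(pairs$cell, names(cell_lab))
  unknown_d <- setdiff(pairs$drug, names(drug_lab))
  if (length(unknown_c) || length(unknown_d))
    stopf("unknown cell line(s) or drug(s): %s",
          paste(head(c(unknown_c, unknown_d), 5), collapse = ", "))
  key <- paste0("c", cell_lab[pairs$cell], ".d", drug_lab[pairs$drug])
  out <- rep(NA_real_, nrow(pairs))
  st <- object$settings
  for (k in unique(key)) {
    if (!k %in% names(object$cv)) next
    z <- object$cv[[k]]
    cm <- object$cells$ids[object$cells$labels == z$cell_cluster]
    dm <- object$drugs$ids[object$drugs$labels == z$drug_cluster]
    design <- assemble_design(cm, dm, object$tables$expr,
                              object$tables$descriptors,
                              object$tables$responses)
    fit <- rf_fit(design$X, design$y, st$trees, st$min_leaf,
                  seed = derive_seed(st$seed, "rf"))
    rows <- which(key == k)
    Xnew <- cbind(object$tables$expr[pairs$cell[rows], , drop = FALSE],
                  object$tables$descriptors[pairs$drug[rows], , drop = FALSE])
    colnames(Xnew) <- colnames(design$X)
    out[rows] <- predict_ranger(fit, Xnew)
  }
  out
}

#' Pooled whole-table random-forest baseline
#'
#' The same cross-validated random forest, but fitted once on all observed
#' (cell line, drug) pairs with no prior clustering — the comparison that
#' shows what the clustering buys.
#'
#' @param fit a [drugsense()] fit (its aligned tables and settings are
#'   reused), or `NULL` when the tables are given directly.
#' @param expr,descriptors,responses tables to use when `fit` is `NULL`.
#' @param folds,trees,min_leaf,seed settings when `fit` is `NULL`.
#' @return List with `evaluation` (a `ds_evaluation`), `predictions`, and
#'   `observed`.
#' @export
pooled_crossval <- function(fit = NULL, expr = NULL, descriptors = NULL,
                            responses = NULL, folds = 3, trees = 100,
                            min_leaf = 5, seed = 1) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "drugsense_fit"))
    expr <- fit$tables$expr
    descriptors <- fit$tables$descriptors
    responses <- fit$tables$responses
    st <- fit$settings
    folds <- st$folds; trees <- st$trees; min_leaf <- st$min_leaf
    seed <- st$seed
  }
  design <- assemble_design(rownames(responses), colnames(responses),
                            expr, descriptors, responses)
  res <- crossval_rf(design, folds = folds, trees = trees,
                     min_leaf = min_leaf, seed = derive_seed(seed, "rf"))
  list(evaluation = evaluate_predictions(res$predictions, res$observed),
       predictions = res$predictions, observed = res$observed)
}

#' Dual-layer CDCN baseline for a fitted model
#'
#' Runs the closed-form dual-layer prediction inside every paired cluster of
#' the fit, under either the Wasserstein-kernel or the Pearson similarity.
#'
#' @param fit a [drugsense()] fit.
#' @param mode `"wasserstein"` or `"pearson"`.
#' @param alpha optional layer-mixing weight (see [cdcn_predict()]).
#' @return As [cdcn_evaluate()].
#' @export
cdcn_baseline <- function(fit, mode = c("wasserstein", "pearson"),
                          alpha = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "drugsense_fit"))
  w <- if (mode == "wasserstein") {
    similarity_weights(D_cells = fit$distances$cells,
                       D_drugs = fit$distances$drugs, mode = mode)
  } else {
    similarity_weights(expr = fit$tables$expr,
                       descriptors = fit$tables$descriptors, mode = mode)
  }
  cdcn_evaluate(fit$tables$responses, w, fit$cells, fit$drugs, alpha = alpha)
}
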