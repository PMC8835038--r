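#' Rank genes by random-forest permutation importance
#'
#' Trains a forest on the full paired-cluster design (same hyperparameters as
#' [crossval_rf()]) and ranks the gene features by permutation importance:
#' the mean increase in out-of-bag squared error when the feature's values
#' are permuted, averaged over trees. Descriptor features take part in the
#' forest but are excluded from the gene ranking.
#'
#' @inheritParams crossval_rf
#' @param mode `"permutation"` (accuracy-based, default) or `"impurity"`.
#' @return Data frame with `gene`, `importance`, `rank` (1 = most important),
#'   sorted by rank. Importance ties are broken by column order.
#' @export
importance_rank <- function(design, trees = 100, min_leaf = 5, seed = 1,
                            mode = c("permutation", "impurity")) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "paired_design"))
  fit <- rf_fit(design$X, design$y, trees, min_leaf,
                seed = derive_seed(seed, "importance"), importance = mode)
  imp <- fit$variable.importance[design$gene_cols]
  ord <- order(-imp, seq_along(imp))
  data.frame(gene = sub("^ge\\.", "", design$gene_cols)[ord],
             importance = as.numeric(imp[ord]),
             rank = seq_along(imp),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Split a paired cluster's cell lines into sensitive and resistant halves
#'
#' Each cell line is scored by its mean observed log(IC50) over the drugs of
#' the paired drug cluster and the lines are split at the median score
#' (lower log(IC50) = more sensitive). This provides the two-group contrast
#' for the differential-expression t-test of [select_significant()].
#'
#' @param responses cell-line x drug log(IC50) matrix.
#' @param cells,drugs members of the paired cluster.
#' @return List with `sensitive` and `resistant` cell-line vectors.
#' @export
response_groups <- function(responses, cells = rownames(responses),
                            drugs = colnames(responses)) {
  cells <- intersect(cells, rownames(responses))
  drugs <- intersect(drugs, colnames(responses))
  score <- rowMeans(responses[cells, drugs, drop = FALSE], na.rm = TRUE)
  score <- score[is.finite(score)]
  if (length(score) < 4) stopf("too few scored cell lines to split")
  m <- median(score)
  sensitive <- names(score)[score <= m]
  resistant <- names(score)[score > m]
  if (length(resistant) < 2) {  # heavy ties at the median
    ord <- names(score)[c_order(score, names(score))]
    half <- floor(length(ord) / 2)
    sensitive <- ord[seq_len(half)]
    resistant <- ord[-seq_len(half)]
  }
  list(sensitive = sensitive, resistant = resistant)
}

#' Significant genes among the top-ranked by importance
#'
#' Takes the `top_n` genes of an importance ranking, runs a Welch two-sample
#' two-sided t-test per gene between the two cell-line groups, applies a
#' Bonferroni correction over exactly the number of tested genes, and flags
#' genes with adjusted p below `alpha`.
#'
#' @param ranked data frame from [importance_rank()] (or a character vector
#'   of genes already in rank order).
#' @param expr samples x genes expression matrix covering both groups.
#' @param groups list of two disjoint cell-line sets (each of size >= 2),
#'   e.g. from [response_groups()].
#' @param top_n number of top-ranked genes to test.
#' @param alpha familywise significance level.
#' @return List with `table` (gene, importance rank, t, p, p_adjusted,
#'   selected for all tested genes) and `significant` (the selected subset).
#' @export
select_significant <- function(ranked, expr, groups, top_n = 200,
                               alpha = 0.05) {
  genes <- if (is.data.frame(ranked)) ranked$gene else as.character(ranked)
  genes <- head(genes, top_n)
  genes <- intersect(genes, colnames(expr))
  if (!length(genes)) stopf("no ranked gene found in the expression matrix")
  stopifnot(length(groups) == 2)
  g1 <- intersect(groups[[1]], rownames(expr))
  g2 <- intersect(groups[[2]], rownames(expr))
  if (length(intersect(g1, g2))) stopf("groups must be disjoint")
  if (length(g1) < 2 || length(g2) < 2) stopf("each group needs >= 2 cell lines")
  n_tests <- length(genes)
  tt <- lapply(genes, function(g) {
    x <- expr[g1, g]; y <- expr[g2, g]
    if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y))
      return(list(statistic = 0, p.value = 1))
    t.test(x, y, var.equal = FALSE)
  })
  p <- vapply(tt, function(z) as.numeric(z$p.value), 0)
  out <- data.frame(
    gene = genes,
    rank = seq_len(n_tests),
    t = vapply(tt, function(z) as.numeric(z$statistic), 0),
    p = p,
    p_adjusted = pmin(1, p * n_tests),
    stringsAsFactors = FALSE)
  out$selected <- out$p_adjusted < alpha
  list(table = out, significant = out[out$selected, , drop = FALSE])
}

#' Hypergeometric gene-set enrichment with BH-FDR
#'
#' For each annotation set, the upper tail
#' \eqn{P[X \ge overlap]} of the hypergeometric distribution (drawing
#' `|selection|` genes from the universe, of which `|set|` are in the set)
#' gives the unadjusted p-value; Benjamini-Hochberg FDR is applied across all
#' tested sets.
#'
#' @param selection character vector of selected genes (must lie inside
#'   `universe`).
#' @param gene_sets named list of character vectors (e.g. [read_gene_sets()]).
#' @param universe character vector of all candidate genes; sets are
#'   intersected with it before testing.
#' @return Data frame with `set`, `overlap`, `set_size`, `universe_size`,
#'   `selection_size`, `p`, `q`, sorted by `q` then `p` then name.
#' @export
hypergeom_enrich <- function(selection, gene_sets, universe) {
  universe <- unique(universe)
  selection <- unique(selection)
  if (!length(universe)) stopf("empty universe")
  if (!length(selection)) stopf("empty selection")
  extra <- setdiff(selection, universe)
  if (length(extra))
    stopf("selection gene(s) outside the universe: %s",
          paste(head(extra, 5), collapse = ", "))
  N <- length(universe)
  n <- length(selection)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(set)
    ov <- length(intersect(set, selection))
    p <- phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = K, universe_size = N,
               selection_size = n, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out[c_order(out$q, out$p, out$set), , drop = FALSE]
}
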