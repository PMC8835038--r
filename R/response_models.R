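#' Assemble the regression design for one paired cluster
#'
#' One row per observed (cell line, drug) pair in the cross product of a cell
#' cluster and a drug cluster; the feature vector is the cell's expression
#' profile concatenated with the drug's descriptor profile. Rows are in
#' canonical (cell, drug) order so downstream fold assignment is invariant to
#' the order in which members are supplied.
#'
#' @param cell_members,drug_members character vectors of cluster members.
#' @param expr samples x genes matrix covering `cell_members`.
#' @param descriptors drugs x descriptors matrix covering `drug_members`
#'   (typically the min-max scaled feature-LCC block).
#' @param responses cell-line x drug log(IC50) matrix with `NA` for missing.
#' @return Object of class `paired_design`: `pairs` (data frame of cell/drug),
#'   feature matrix `X`, target `y`, and the gene/descriptor column split.
#' @export
assemble_design <- function(cell_members, drug_members, expr, descriptors,
                            responses) {
  cell_members <- c_sort(intersect(cell_members, rownames(responses)))
  drug_members <- c_sort(intersect(drug_members, colnames(responses)))
  if (!length(cell_members) || !length(drug_members))
    stopf("cluster members absent from the response table")
  missing_expr <- setdiff(cell_members, rownames(expr))
  if (length(missing_expr))
    stopf("no expression profile for cell line(s): %s",
          paste(head(missing_expr, 5), collapse = ", "))
  missing_desc <- setdiff(drug_members, rownames(descriptors))
  if (length(missing_desc))
    stopf("no descriptors for drug(s): %s",
          paste(head(missing_desc, 5), collapse = ", "))

  Y <- responses[cell_members, drug_members, drop = FALSE]
  obs <- which(!is.na(Y), arr.ind = TRUE)
  if (!nrow(obs)) stopf("no observed (cell, drug) pair in this paired cluster")
  ord <- c_order(cell_members[obs[, 1]], drug_members[obs[, 2]])
  obs <- obs[ord, , drop = FALSE]
  cells <- cell_members[obs[, 1]]
  drugs <- drug_members[obs[, 2]]

  Xg <- expr[cells, , drop = FALSE]
  Xd <- descriptors[drugs, , drop = FALSE]
  colnames(Xg) <- paste0("ge.", colnames(expr))
  colnames(Xd) <- paste0("dx.", colnames(descriptors))
  X <- cbind(Xg, Xd)
  if (anyNA(X)) stopf("missing feature values in the assembled design")
  rownames(X) <- paste(cells, drugs, sep = "|")
  structure(list(pairs = data.frame(cell = cells, drug = drugs,
                                    stringsAsFactors = FALSE),
                 X = X, y = Y[obs],
                 gene_cols = colnames(Xg), descriptor_cols = colnames(Xd)),
            class = "paired_design")
}

#' @export
print.paired_design <- function(x, ...) {
  cat(sprintf("paired_design: %d pairs (%d cells x %d drugs), %d features\n",
              nrow(x$X), length(unique(x$pairs$cell)),
              length(unique(x$pairs$drug)), ncol(x$X)))
  invisible(x)
}

rf_fit <- function(X, y, trees, min_leaf, seed, importance = "none") {
  p <- ncol(X)
  ranger::ranger(
    x = as.data.frame(X), y = y,
    num.trees = trees, min.node.size = min_leaf,
    mtry = max(1L, floor(p / 3)),
    importance = importance,
    seed = seed, num.threads = 1)
}

#' Out-of-fold random-forest predictions for a paired-cluster design
#'
#' Pairs are randomly partitioned into `folds` folds (at the pair level),
#' each fold is predicted by a forest trained on the remaining folds
#' (100 trees, terminal node size 5, `mtry = floor(p/3)` by default), and
#' every pair receives exactly one out-of-fold prediction. Fold assignment
#' and tree growing are reproducible from `seed`.
#'
#' @param design a [assemble_design()] result.
#' @param folds number of cross-validation folds.
#' @param trees,min_leaf forest size and minimum terminal-node size.
#' @param seed integer seed for fold assignment and tree growing.
#' @return List with `predictions`, `observed`, `fold` (all aligned with
#'   `design$pairs`), and the settings used.
#' @export
crossval_rf <- function(design, folds = 3, trees = 100, min_leaf = 5,
                        seed = 1) {
  stopifnot(inherits(design, "paired_design"))
  n <- nrow(design$X)
  if (n < folds * 2)
    stopf("too few pairs (%d) for %d-fold CV in this paired cluster", n, folds)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "folds"))
  fold <- sample(rep_len(seq_len(folds), n))
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    test <- fold == f
    fit <- rf_fit(design$X[!test, , drop = FALSE], design$y[!test],
                  trees, min_leaf, seed = derive_seed(seed, "rf") + f)
    pred[test] <- predict_ranger(fit, design$X[test, , drop = FALSE])
  }
  list(predictions = stats::setNames(pred, rownames(design$X)),
       observed = stats::setNames(design$y, rownames(design$X)),
       fold = fold,
       settings = list(folds = folds, trees = trees, min_leaf = min_leaf,
                       mtry = max(1L, floor(ncol(design$X) / 3)), seed = seed))
}

predict_ranger <- function(fit, X) {
  as.numeric(predict(fit, data = as.data.frame(X), num.threads = 1)$predictions)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Evaluate predictions against observations
#'
#' Pearson correlation R and coefficient of determination
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}. A constant prediction vector has no
#' defined correlation (R is `NA`) but still gets an \eqn{R^2}.
#'
#' @param predicted,observed numeric vectors of equal length (at least 3);
#'   `observed` must not be constant.
#' @return Object of class `ds_evaluation`: `predicted`, `observed`, `r`,
#'   `r2`, `n`.
#' @export
evaluate_predictions <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  if (length(observed) < 3) stopf("need at least 3 pairs to evaluate")
  if (anyNA(predicted) || anyNA(observed)) stopf("NA in evaluation vectors")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stopf("constant observed vector")
  r <- if (sd(predicted) == 0) NA_real_ else cor(predicted, observed)
  r2 <- 1 - sum((observed - predicted)^2) / ss_tot
  structure(list(predicted = predicted, observed = observed,
                 r = r, r2 = r2, n = length(observed)),
            class = "ds_evaluation")
}

#' @export
print.ds_evaluation <- function(x, ...) {
  cat(sprintf("n = %d, R = %s, R^2 = %.4f\n", x$n,
              if (is.na(x$r)) "NA" else sprintf("%.4f", x$r), x$r2))
  invisible(x)
}

#' Pooled evaluation over several paired clusters
#'
#' Concatenates the per-cluster predicted and observed vectors and evaluates
#' the concatenation once; R and R^2 are invariant to the concatenation
#' order.
#'
#' @param results nonempty list of [evaluate_predictions()] results (or lists
#'   with `predicted`/`observed`).
#' @return A `ds_evaluation` over the concatenated vectors.
#' @export
concat_evaluations <- function(results) {
  if (!length(results)) stopf("no evaluations to concatenate")
  pred <- unlist(lapply(results, `[[`, "predicted"), use.names = FALSE)
  obs <- unlist(lapply(results, `[[`, "observed"), use.names = FALSE)
  evaluate_predictions(pred, obs)
}

#' Similarity weights for the dual-layer (CDCN) baseline
#'
#' Converts cell-line and drug dissimilarity into nonnegative similarity
#' weights. In `"wasserstein"` mode a Gaussian kernel is applied to the W1
#' distances, \eqn{w = \exp(-d^2 / 2\sigma^2)}, with the bandwidth
#' \eqn{\sigma} set per matrix by the median heuristic (median off-diagonal
#' distance). In `"pearson"` mode weights are Pearson correlations of the raw
#' profiles (expression for cells, descriptors for drugs), negatively
#' correlated pairs clipped to 0.
#'
#' @param D_cells,D_drugs distance matrices (wasserstein mode).
#' @param expr,descriptors raw profile matrices (pearson mode).
#' @param mode `"wasserstein"` or `"pearson"`.
#' @return Object of class `similarity_weights`: `w` (cells), `v` (drugs),
#'   bandwidths, and the mode. Diagonals are zeroed; predictions never use
#'   self-similarity.
#' @export
similarity_weights <- function(D_cells = NULL, D_drugs = NULL,
                               expr = NULL, descriptors = NULL,
                               mode = c("wasserstein", "pearson")) {
  mode <- match.arg(mode)
  if (mode == "wasserstein") {
    if (is.null(D_cells) || is.null(D_drugs))
      stopf("wasserstein mode needs both distance matrices")
    wk <- function(D) {
      check_square_dist(D)
      sigma <- median(D[upper.tri(D)])
      if (sigma <= 0) sigma <- 1  # degenerate all-identical case
      W <- exp(-D^2 / (2 * sigma^2))
      diag(W) <- 0
      list(W = W, sigma = sigma)
    }
    cw <- wk(D_cells); dw <- wk(D_drugs)
    out <- list(w = cw$W, v = dw$W, sigma_c = cw$sigma, sigma_d = dw$sigma,
                mode = mode)
  } else {
    if (is.null(expr) || is.null(descriptors))
      stopf("pearson mode needs the raw expression and descriptor tables")
    pw <- function(M) {
      W <- suppressWarnings(cor(t(M)))
      W[is.na(W)] <- 0
      W <- pmax(W, 0)
      diag(W) <- 0
      W
    }
    out <- list(w = pw(expr), v = pw(descriptors),
                sigma_c = NA_real_, sigma_d = NA_real_, mode = mode)
  }
  for (nm in c("w", "v")) {
    M <- out[[nm]]
    dead <- rownames(M)[rowSums(M) == 0 & nrow(M) > 1]
    if (length(dead))
      stopf("all-zero similarity row for %s: %s",
            if (nm == "w") "cell line(s)" else "drug(s)",
            paste(head(dead, 5), collapse = ", "))
  }
  structure(out, class = "similarity_weights")
}

#' Dual-layer closed-form response prediction (CDCN)
#'
#' Leave-one-out prediction of each observed pair as the similarity-weighted
#' average over the cell-line layer (other cell lines' responses to the same
#' drug) and the drug layer (the same cell line's responses to other drugs):
#' \deqn{\hat y(c,d) = \frac{\sum_{c' \ne c} w_{cc'} y(c',d) +
#'   \sum_{d' \ne d} v_{dd'} y(c,d')}{\sum_{c' \ne c} w_{cc'} +
#'   \sum_{d' \ne d} v_{dd'}}}
#' with sums over observed entries only. With `alpha` set, the two layers are
#' instead averaged separately and mixed as
#' `alpha * cell_layer + (1 - alpha) * drug_layer` (a layer without observed
#' neighbors cedes its share to the other).
#'
#' @param responses cell-line x drug log(IC50) matrix with `NA` for missing.
#' @param weights a [similarity_weights()] object whose matrices cover the
#'   cluster members.
#' @param cell_members,drug_members the paired cluster; defaults to the whole
#'   table.
#' @param alpha optional layer-mixing weight in `[0, 1]`; `NULL` (default)
#'   uses the pooled single-ratio form.
#' @return Matrix of predictions over the paired cluster: leave-one-out for
#'   observed entries and imputation for missing ones (the closed form never
#'   uses the target's own value). `NA` where no observed neighbor exists;
#'   such observed pairs are counted in a message.
#' @export
cdcn_predict <- function(responses, weights,
                         cell_members = rownames(responses),
                         drug_members = colnames(responses),
                         alpha = NULL) {
  stopifnot(inherits(weights, "similarity_weights"))
  cell_members <- intersect(cell_members, rownames(responses))
  drug_members <- intersect(drug_members, colnames(responses))
  Y <- responses[cell_members, drug_members, drop = FALSE]
  W <- weights$w[cell_members, cell_members, drop = FALSE]
  V <- weights$v[drug_members, drug_members, drop = FALSE]
  diag(W) <- 0; diag(V) <- 0
  obs <- !is.na(Y)
  Y0 <- Y; Y0[!obs] <- 0
  # cell layer: for target (c, d), sum over other cells c' with observed y(c', d)
  num_c <- W %*% Y0
  den_c <- W %*% obs
  num_d <- Y0 %*% V
  den_d <- obs %*% V
  if (is.null(alpha)) {
    den <- den_c + den_d
    pred <- (num_c + num_d) / den
    pred[den == 0] <- NA_real_
  } else {
    stopifnot(alpha >= 0, alpha <= 1)
    mc <- num_c / den_c; md <- num_d / den_d
    pred <- matrix(NA_real_, nrow(Y), ncol(Y), dimnames = dimnames(Y))
    both <- den_c > 0 & den_d > 0
    pred[both] <- alpha * mc[both] + (1 - alpha) * md[both]
    only_c <- den_c > 0 & den_d == 0
    pred[only_c] <- mc[only_c]
    only_d <- den_c == 0 & den_d > 0
    pred[only_d] <- md[only_d]
  }
  n_failed <- sum(obs & is.na(pred))
  if (n_failed)
    msgf("cdcn_predict: %d observed pair(s) had no observed neighbor", n_failed)
  dimnames(pred) <- dimnames(Y)
  pred
}

#' Evaluate the CDCN baseline per paired cluster
#'
#' Runs [cdcn_predict()] inside every (cell cluster, drug cluster) pair and
#' concatenates the evaluations, mirroring the per-paired-cluster evaluation
#' of the random-forest model.
#'
#' @inheritParams cdcn_predict
#' @param cell_clusters,drug_clusters `clustering_result`s (or named label
#'   vectors) for cell lines and drugs.
#' @return List with `per_cluster` evaluations and the `overall` concatenated
#'   `ds_evaluation`.
#' @export
cdcn_evaluate <- function(responses, weights, cell_clusters, drug_clusters,
                          alpha = NULL) {
  cm <- members_of(cell_clusters)
  dm <- members_of(drug_clusters)
  per <- list()
  for (gc in names(cm)) {
    for (gd in names(dm)) {
      cells <- intersect(cm[[gc]], rownames(responses))
      drugs <- intersect(dm[[gd]], colnames(responses))
      if (!length(cells) || !length(drugs)) next
      pred <- suppressMessages(
        cdcn_predict(responses, weights, cells, drugs, alpha = alpha))
      Y <- responses[cells, drugs, drop = FALSE]
      ok <- !is.na(pred) & !is.na(Y)
      if (sum(ok) < 3 || sd(Y[ok]) == 0) next
      per[[paste0("c", gc, ".d", gd)]] <- evaluate_predictions(pred[ok], Y[ok])
    }
  }
  if (!length(per)) stopf("no paired cluster had enough predictable pairs")
  list(per_cluster = per, overall = concat_evaluations(per))
}

members_of <- function(x) {
  if (inherits(x, "clustering_result")) return(cluster_members(x))
  if (!is.null(names(x))) return(split(names(x), x))
  stopf("need a clustering_result or a named label vector")
}
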