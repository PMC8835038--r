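test_that("permutation importance puts the informative gene first", {
  for (seed in 1:5) {
    d <- importance_fixture(seed)
    ranked <- importance_rank(d, trees = 100, seed = seed)
    expect_equal(ranked$gene[1], "g05")
    expect_equal(nrow(ranked), 10)
    expect_equal(ranked$rank, 1:10)
  }
})

test_that("pure-noise targets give no gene a calibrated-significant importance", {
  set.seed(21)
  n <- 80
  cells <- sprintf("c%03d", seq_len(n))
  expr <- matrix(runif(n * 10, 1, 3), n, 10,
                 dimnames = list(cells, sprintf("g%02d", 1:10)))
  desc <- matrix(0.5, 1, 2, dimnames = list("d1", c("x1", "x2")))
  y <- matrix(rnorm(n), n, 1, dimnames = list(cells, "d1"))
  d <- assemble_design(cells, "d1", expr, desc, y)
  obs_max <- max(importance_rank(d, trees = 100, seed = 1)$importance)
  null_max <- vapply(1:19, function(s) {
    set.seed(100 + s)
    yp <- matrix(sample(as.numeric(y)), n, 1, dimnames = list(cells, "d1"))
    dp <- assemble_design(cells, "d1", expr, desc, yp)
    max(importance_rank(dp, trees = 100, seed = s)$importance)
  }, 0)
  expect_lte(obs_max, quantile(null_max, 0.95) + 1e-9)
})

test_that("a duplicated informative gene shares the top ranks", {
  set.seed(31)
  n <- 100
  cells <- sprintf("c%03d", seq_len(n))
  genes <- sprintf("g%02d", 1:20)
  expr <- matrix(runif(n * 20, 1, 3), n, 20, dimnames = list(cells, genes))
  expr[, "g02"] <- expr[, "g01"]          # duplicate of the informative gene
  desc <- matrix(0.5, 1, 2, dimnames = list("d1", c("x1", "x2")))
  y <- matrix(3 * expr[, "g01"] + rnorm(n, 0, 0.2), n, 1,
              dimnames = list(cells, "d1"))
  d <- assemble_design(cells, "d1", expr, desc, y)
  ranked <- importance_rank(d, trees = 200, seed = 2)
  expect_true(all(c("g01", "g02") %in% ranked$gene[1:2]))
})

test_that("significance selection applies Welch tests with Bonferroni", {
  set.seed(5)
  cells <- sprintf("c%02d", 1:40)
  gA <- cells[1:20]; gB <- cells[21:40]
  expr <- matrix(rnorm(40 * 6), 40, 6,
                 dimnames = list(cells, sprintf("g%d", 1:6)))
  expr[gA, "g1"] <- rnorm(20, 5, 1)       # strong shift
  expr[gB, "g1"] <- rnorm(20, 0, 1)
  res <- select_significant(paste0("g", 1:6), expr, list(gA, gB), top_n = 6)
  expect_true("g1" %in% res$significant$gene)
  g1row <- res$table[res$table$gene == "g1", ]
  expect_equal(g1row$p_adjusted, min(1, g1row$p * 6))

  # identical groups: t = 0, p = 1, nothing selected
  expr2 <- expr; expr2[gB, ] <- expr2[gA, ]
  res2 <- select_significant(paste0("g", 1:6), expr2,
                             list(gA, gB), top_n = 6)
  expect_equal(nrow(res2$significant), 0)

  expect_error(select_significant(paste0("g", 1:6), expr,
                                  list(gA[1], gB), top_n = 6), ">= 2")
  expect_error(select_significant(paste0("g", 1:6), expr,
                                  list(gA, c(gA[1], gB)), top_n = 6),
               "disjoint")
})

test_that("Bonferroni arithmetic matches the fixed-top-n convention", {
  # raw p 1e-4 over 200 tests -> adjusted 0.02, selected at 0.05
  expect_lt(1e-4 * 200, 0.05)
  set.seed(6)
  cells <- sprintf("c%02d", 1:30)
  expr <- matrix(rnorm(30 * 300), 30,
                 dimnames = list(cells, sprintf("g%03d", 1:300)))
  res <- select_significant(sprintf("g%03d", 1:300), expr,
                            list(cells[1:15], cells[16:30]), top_n = 200)
  expect_equal(nrow(res$table), 200)   # only top_n genes tested
  expect_equal(res$table$p_adjusted, pmin(1, res$table$p * 200))
})

test_that("hypergeometric enrichment is exact and BH-monotone", {
  # worked example: universe 20, set 5, selection 5, overlap 4
  sel <- paste0("g", 1:5)
  universe <- paste0("g", 1:20)
  sets <- list(hit = c(paste0("g", 2:5), "g10"),
               all = universe,
               none = paste0("g", 15:18))
  out <- hypergeom_enrich(sel, sets, universe)
  expect_equal(out$p[out$set == "hit"], 76 / 15504)
  expect_equal(out$p[out$set == "all"], 1)
  expect_equal(out$overlap[out$set == "none"], 0)
  expect_equal(out$p[out$set == "none"], 1)
  expect_true(all(diff(out$q[order(out$p)]) >= -1e-15))
  expect_error(hypergeom_enrich(c("zz"), sets, universe), "outside")
})

test_that("hypergeometric tail matches exhaustive enumeration (small universes)", {
  for (seed in 1:10) {
    set.seed(seed)
    N <- sample(6:12, 1)
    universe <- paste0("g", seq_len(N))
    K <- sample(2:(N - 1), 1)
    n_sel <- sample(2:(N - 1), 1)
    gene_set <- sample(universe, K)
    selection <- sample(universe, n_sel)
    out <- hypergeom_enrich(selection, list(s = gene_set), universe)
    ov <- length(intersect(gene_set, selection))
    expect_equal(out$p, brute_hyper_tail(ov, K, N, n_sel), tolerance = 1e-12)
  }
})

test_that("response groups split cell lines at the median mean response", {
  set.seed(7)
  y <- matrix(rnorm(20 * 4), 20, 4,
              dimnames = list(sprintf("c%02d", 1:20), paste0("d", 1:4)))
  y[1:10, ] <- y[1:10, ] - 5       # clearly sensitive half
  g <- response_groups(y)
  expect_setequal(g$sensitive, sprintf("c%02d", 1:10))
  expect_setequal(g$resistant, sprintf("c%02d", 11:20))
  expect_length(intersect(g$sensitive, g$resistant), 0)
})
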