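test_that("descriptor cleaning drops missing and (near-)constant columns", {
  set.seed(1)
  X <- matrix(rnorm(100 * 4), 100, 4,
              dimnames = list(sprintf("d%03d", 1:100), paste0("x", 1:4)))
  X[5, 2] <- NA                                   # missing -> dropped
  X[, 3] <- 7                                     # constant -> dropped
  X[, 4] <- c(rep(1, 96), rnorm(4))               # 96% modal -> dropped at 0.95
  out <- suppressMessages(clean_descriptors(X))
  expect_identical(colnames(out), "x1")
  # 94% modal survives the default threshold
  X2 <- cbind(x1 = rnorm(100), x2 = c(rep(1, 94), rnorm(6)))
  rownames(X2) <- sprintf("d%03d", 1:100)
  expect_equal(ncol(suppressMessages(clean_descriptors(X2))), 2)
  expect_error(suppressMessages(clean_descriptors(X[, 3, drop = FALSE])),
               "survives")
})

test_that("spearman reduction keeps one representative per correlated pair", {
  set.seed(2)
  base1 <- rnorm(50); base2 <- rnorm(50)
  X <- cbind(a = base1, b = base1 + rnorm(50, 0, 1e-6),
             c = base2, d = base2 + rnorm(50, 0, 1e-6))
  rownames(X) <- sprintf("d%02d", 1:50)
  red <- spearman_reduce(X, 2)
  expect_equal(ncol(red$table), 2)
  expect_true(xor("a" %in% colnames(red$table), "b" %in% colnames(red$table)))
  expect_true(xor("c" %in% colnames(red$table), "d" %in% colnames(red$table)))

  # identity reduction
  red_id <- spearman_reduce(X, 4)
  expect_identical(red_id$table, X)

  # two near-duplicates plus an independent column, target 2
  X3 <- cbind(p = base1, q = base1 + rnorm(50, 0, 1e-4), r = base2)
  rownames(X3) <- rownames(X)
  red3 <- spearman_reduce(X3, 2)
  expect_true("r" %in% colnames(red3$table))
  expect_equal(ncol(red3$table), 2)

  Xc <- cbind(X, e = rep(1, 50))
  expect_error(spearman_reduce(Xc, 2), "constant")
})

test_that("graphical lasso obeys the 2x2 closed form and monotone sparsity", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  for (l in c(0.9, 0.7, 0.51, 0.501)) {
    expect_equal(graphical_lasso(S, l)$Theta["a", "b"], 0)
  }
  for (l in c(0.45, 0.3, 0.1, 0.01)) {
    expect_gt(abs(graphical_lasso(S, l)$Theta["a", "b"]), 1e-8)
  }
  S0 <- diag(2); dimnames(S0) <- dimnames(S)
  expect_equal(graphical_lasso(S0, 0.2)$Theta["a", "b"], 0)

  # edge count non-increasing in lambda on random Gaussian data
  set.seed(3)
  X <- matrix(rnorm(80 * 8), 80, 8)
  S8 <- cor(X); dimnames(S8) <- list(paste0("v", 1:8), paste0("v", 1:8))
  counts <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.4), function(l) {
    sum(abs(graphical_lasso(S8, l)$Theta[upper.tri(S8)]) > 1e-8)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("glasso recovers a known sparse support", {
  sc <- synthetic_scenario(n_drugs = 500, n_descriptors = 10,
                           descriptor_offset = 0, n_constant = 0,
                           n_near_constant = 0, n_missing = 0, seed = 5)
  de <- make_descriptors(sc)
  truth <- abs(de$precision[upper.tri(de$precision)]) > 1e-8
  f1_at <- function(l) {
    fn <- feature_network(de$descriptors, lambda = l)
    est <- abs(fn$Theta[upper.tri(fn$Theta)]) > 1e-8
    tp <- sum(truth & est)
    2 * tp / (2 * tp + sum(!truth & est) + sum(truth & !est))
  }
  # oracle lambda: the grid value with the best support recovery
  expect_gte(max(vapply(c(0.02, 0.05, 0.08, 0.12, 0.2), f1_at, 0)), 0.8)
})

test_that("auto lambda keeps the feature-network core within its budget", {
  set.seed(8)
  # loosely coupled blocks so the LCC shrinks gradually with lambda
  X <- do.call(cbind, lapply(1:6, function(b) {
    z <- rnorm(60)
    sapply(1:5, function(j) 0.6 * z + rnorm(60))
  }))
  colnames(X) <- sprintf("x%02d", 1:30)
  rownames(X) <- sprintf("d%02d", 1:60)
  fn <- feature_network(X)
  expect_lte(drugsense:::lcc_node_count(fn$network), 10)
  expect_gte(drugsense:::lcc_node_count(fn$network), 3)
})

test_that("drug distributions scale and normalize onto the network core", {
  net <- gene_network(rbind(c("f1", "f2")))
  # both descriptors range over [0, 4] across drugs
  X <- rbind(d1 = c(0, 4), d2 = c(4, 0), d3 = c(1, 3), d4 = c(4, 4))
  colnames(X) <- c("f1", "f2")
  dd <- drug_distributions(X, net)
  expect_equal(unclass(dd$distributions$d4), c(f1 = 0.5, f2 = 0.5),
               ignore_attr = "Z")
  expect_equal(unclass(dd$distributions$d3), c(f1 = 0.25, f2 = 0.75),
               ignore_attr = "Z")
  for (m in dd$distributions) {
    expect_true(all(m >= 0))
    expect_equal(sum(m), 1)
  }
  expect_error(drug_distributions(rbind(d1 = c(0, 0), d2 = c(1, 1),
                                        d3 = c(2, 3)) |>
                                    `colnames<-`(c("f1", "f2")), net),
               "all-zero")
})
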