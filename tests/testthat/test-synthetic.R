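test_that("generators are bit-exact functions of the seed", {
  s1 <- simulate_study(synthetic_scenario(n_cells = 20, n_drugs = 12,
                                          n_genes = 20, n_descriptors = 12,
                                          seed = 9))
  s2 <- simulate_study(synthetic_scenario(n_cells = 20, n_drugs = 12,
                                          n_genes = 20, n_descriptors = 12,
                                          seed = 9))
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$descriptors, s2$descriptors)
  expect_identical(s1$responses, s2$responses)
  expect_identical(s1$network$edges, s2$network$edges)

  s3 <- simulate_study(synthetic_scenario(n_cells = 20, n_drugs = 12,
                                          n_genes = 20, n_descriptors = 12,
                                          seed = 10))
  expect_false(identical(s1$expr, s3$expr))
})

test_that("the interaction network is connected with the requested size", {
  for (seed in c(0, 1, 2)) {
    net <- make_ppi(10, 2, seed = seed)
    expect_length(net$nodes, 10)
    expect_true(igraph::is_connected(drugsense:::as_igraph(net)))
  }
  expect_identical(make_ppi(10, 2, seed = 0)$edges,
                   make_ppi(10, 2, seed = 0)$edges)
  big <- make_ppi(635, 3, seed = 1)
  expect_length(big$nodes, 635)
  expect_true(igraph::is_connected(drugsense:::as_igraph(big)))
})

test_that("expression is strictly positive with module shifts only under delta > 0", {
  sc <- synthetic_scenario(n_cells = 30, n_genes = 24, k_cells = 3, seed = 2)
  ex <- make_expression(sc)
  expect_true(all(ex$expr > 0))
  expect_equal(dim(ex$expr), c(30, 24))
  # module genes really are shifted for their cluster's cells
  m1 <- names(ex$modules)[ex$modules == 1]
  c1 <- names(ex$labels)[ex$labels == 1]
  c2 <- names(ex$labels)[ex$labels == 2]
  expect_gt(mean(ex$expr[c1, m1]), exp(0.5) * mean(ex$expr[c2, m1]))

  sc0 <- synthetic_scenario(n_cells = 30, n_genes = 24, k_cells = 3,
                            delta = 0, seed = 2)
  ex0 <- make_expression(sc0)
  expect_equal(mean(ex0$expr[c1, m1]) / mean(ex0$expr[c2, m1]), 1,
               tolerance = 0.1)
})

test_that("a null expression signal leaves clusters undetectable", {
  aris <- vapply(1:3, function(seed) {
    sc <- synthetic_scenario(n_cells = 24, n_genes = 30, k_cells = 3,
                             delta = 0, seed = seed)
    net <- make_ppi(sc$n_genes, sc$attachment,
                    seed = drugsense:::derive_seed(seed, "ppi"))
    ex <- make_expression(sc)
    D <- pairwise_wasserstein(invariant_measures(ex$expr, net),
                              ground_metric(net))
    res <- select_k(D, 2, 8)
    ari(res$labels, ex$labels)
  }, 0)
  expect_lt(mean(aris), 0.3)
})

test_that("descriptor junk columns exist and are removed by cleaning", {
  sc <- synthetic_scenario(n_drugs = 30, n_descriptors = 12, seed = 3)
  de <- make_descriptors(sc)
  expect_length(de$junk, sc$n_constant + sc$n_near_constant + sc$n_missing)
  cleaned <- suppressMessages(clean_descriptors(de$descriptors))
  expect_length(intersect(colnames(cleaned), de$junk), 0)
  expect_setequal(colnames(cleaned), de$informative)
})

test_that("responses carry cluster baselines, feature effects and missingness", {
  sc <- synthetic_scenario(n_cells = 40, n_drugs = 18, n_genes = 20,
                           n_descriptors = 12, k_cells = 2, k_drugs = 2,
                           missing_rate = 0.2, seed = 4)
  study <- simulate_study(sc)
  y <- study$responses
  expect_equal(dim(y), c(40, 18))
  expect_equal(mean(is.na(y)), 0.2, tolerance = 0.08)
  effects <- attr(y, "effects")
  expect_length(effects, sc$k_cells * sc$k_drugs)
  # effect identities differ across paired clusters
  keys <- vapply(effects, function(e)
    paste(sort(c(e$genes, e$descriptors)), collapse = "+"), "")
  expect_gt(length(unique(keys)), 1)

  # with sigma -> 0 and no feature effects, y depends only on the cluster pair
  sc0 <- synthetic_scenario(n_cells = 12, n_drugs = 8, n_genes = 12,
                            n_descriptors = 9, k_cells = 2, k_drugs = 2,
                            sigma = 1e-9, effect_size = 0, missing_rate = 0,
                            seed = 5)
  st0 <- simulate_study(sc0)
  B <- attr(st0$responses, "B")
  for (gc in 1:2) for (gd in 1:2) {
    block <- st0$responses[st0$cell_labels == gc, st0$drug_labels == gd]
    expect_lt(max(abs(block - B[gc, gd])), 1e-6)
  }
})

test_that("a near-fully-missing cell line is removed by the filter", {
  sc <- synthetic_scenario(n_cells = 20, n_drugs = 20, n_genes = 12,
                           n_descriptors = 9, missing_rate = 0, seed = 6)
  study <- simulate_study(sc)
  y <- study$responses
  y["cell001", 1:19] <- NA     # 95% missing
  kept <- suppressMessages(filter_cell_lines(y, 0.8))
  expect_false("cell001" %in% rownames(kept))
})
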