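tiny_tables <- function(seed = 1) {
  set.seed(seed)
  cells <- paste0("c", 1:6); drugs <- paste0("d", 1:4)
  genes <- paste0("g", 1:5); descs <- paste0("x", 1:3)
  list(
    expr = matrix(runif(6 * 5, 1, 5), 6, 5, dimnames = list(cells, genes)),
    desc = matrix(runif(4 * 3), 4, 3, dimnames = list(drugs, descs)),
    resp = matrix(rnorm(6 * 4), 6, 4, dimnames = list(cells, drugs)))
}

test_that("design assembly follows the missingness mask and concatenates blocks", {
  tt <- tiny_tables()
  tt$resp[1, 2] <- NA
  d <- assemble_design(c("c1", "c2"), c("d1", "d2", "d3"),
                       tt$expr, tt$desc, tt$resp)
  expect_equal(nrow(d$X), 5)                      # 6 cross pairs, 1 missing
  expect_equal(ncol(d$X), 5 + 3)
  expect_equal(length(d$gene_cols), 5)
  expect_equal(length(d$descriptor_cols), 3)
  expect_equal(d$y, tt$resp[cbind(d$pairs$cell, d$pairs$drug)],
               ignore_attr = TRUE)
  # feature rows really are the concatenated profiles
  expect_equal(unname(d$X[1, d$gene_cols]), unname(tt$expr[d$pairs$cell[1], ]))
  expect_equal(unname(d$X[1, d$descriptor_cols]),
               unname(tt$desc[d$pairs$drug[1], ]))

  # member order does not matter: canonical row order
  d3 <- assemble_design(c("c2", "c1"), c("d3", "d2", "d1"),
                        tt$expr, tt$desc, tt$resp)
  expect_identical(d3$pairs, d$pairs)

  # a fully missing drug contributes no rows
  tt$resp[, 4] <- NA
  d2 <- assemble_design(c("c1", "c2"), c("d3", "d4"), tt$expr, tt$desc, tt$resp)
  expect_true(all(d2$pairs$drug == "d3"))
  tt$resp[, 3] <- NA
  expect_error(assemble_design(c("c1", "c2"), c("d3", "d4"),
                               tt$expr, tt$desc, tt$resp), "no observed")
})

test_that("cross-validated forests predict every pair exactly once, reproducibly", {
  set.seed(42)
  n <- 120
  cells <- sprintf("c%03d", 1:n)
  expr <- matrix(runif(n * 4, 1, 3), n, 4,
                 dimnames = list(cells, paste0("g", 1:4)))
  desc <- matrix(0.5, 1, 2, dimnames = list("d1", paste0("x", 1:2)))
  resp <- matrix(expr[, 1] * 2 + rnorm(n, 0, 0.05), n, 1,
                 dimnames = list(cells, "d1"))
  d <- assemble_design(cells, "d1", expr, desc, resp)
  cv <- crossval_rf(d, folds = 3, trees = 50, seed = 7)
  expect_equal(length(cv$predictions), n)
  expect_equal(sort(table(cv$fold)), sort(table(rep_len(1:3, n))),
               ignore_attr = TRUE)
  cv2 <- crossval_rf(d, folds = 3, trees = 50, seed = 7)
  expect_identical(cv$predictions, cv2$predictions)
  cv3 <- crossval_rf(d, folds = 3, trees = 50, seed = 8)
  expect_false(identical(cv$predictions, cv3$predictions))

  # constant target -> constant predictions (tree mean rule)
  resp_c <- matrix(3.3, n, 1, dimnames = list(cells, "d1"))
  dc <- assemble_design(cells, "d1", expr, desc, resp_c)
  cvc <- crossval_rf(dc, folds = 3, trees = 20, seed = 1)
  expect_true(all(abs(cvc$predictions - 3.3) < 1e-12))

  expect_error(crossval_rf(assemble_design(cells[1:4], "d1", expr, desc, resp),
                           folds = 3), "too few")
})

test_that("forest CV finds real signal and no phantom signal", {
  set.seed(0)
  n <- 300
  cells <- sprintf("c%03d", 1:n)
  X <- matrix(rnorm(n * 11), n, 11,
              dimnames = list(cells, paste0("g", 1:11)))
  desc <- matrix(0.5, 1, 2, dimnames = list("d1", paste0("x", 1:2)))
  y_sig <- matrix(X[, 1] + rnorm(n, 0, 0.1), n, 1,
                  dimnames = list(cells, "d1"))
  d_sig <- assemble_design(cells, "d1", X - min(X), desc, y_sig)
  ev <- evaluate_predictions(crossval_rf(d_sig, seed = 0)$predictions,
                             d_sig$y)
  expect_gte(ev$r2, 0.8)

  r2_null <- vapply(1:10, function(s) {
    set.seed(s)
    y0 <- matrix(rnorm(n), n, 1, dimnames = list(cells, "d1"))
    d0 <- assemble_design(cells, "d1", X - min(X), desc, y0)
    evaluate_predictions(crossval_rf(d0, seed = s)$predictions, d0$y)$r2
  }, 0)
  expect_lte(mean(r2_null), 0.1)
})

test_that("evaluation computes R and R-squared by their definitions", {
  ev <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ev$r, 1); expect_equal(ev$r2, 1)

  ev2 <- evaluate_predictions(c(1, 2, 4), c(1, 2, 3))
  expect_equal(ev2$r2, 0.5)
  expect_equal(ev2$r, cor(c(1, 2, 4), c(1, 2, 3)))
  expect_equal(round(ev2$r, 4), 0.982)

  obs <- c(1, 2, 3, 4)
  ev3 <- evaluate_predictions(rep(mean(obs), 4), obs)
  expect_equal(ev3$r2, 0)
  expect_true(is.na(ev3$r))

  expect_error(evaluate_predictions(c(1, 2, 3), c(2, 2, 2)), "constant")
  expect_error(evaluate_predictions(c(1, 2), c(1, 3)), "at least 3")
})

test_that("concatenated evaluation pools clusters order-invariantly", {
  e1 <- evaluate_predictions(c(1, 2, 3), c(1.1, 1.9, 3.2))
  expect_equal(concat_evaluations(list(e1))$r2, e1$r2)

  p1 <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  p2 <- evaluate_predictions(c(5, 6, 7), c(5, 6, 7))
  cc <- concat_evaluations(list(p1, p2))
  expect_equal(cc$r, 1); expect_equal(cc$r2, 1)

  # two mean-predicting models (each R2 = 0) with different means pool to R2 > 0
  o1 <- c(-1, 0, 1); o2 <- c(9, 10, 11)
  m1 <- evaluate_predictions(rep(0, 3), o1)
  m2 <- evaluate_predictions(rep(10, 3), o2)
  expect_equal(m1$r2, 0); expect_equal(m2$r2, 0)
  pooled <- concat_evaluations(list(m1, m2))
  expect_gt(pooled$r2, 0.9)
  expect_equal(pooled$r2, concat_evaluations(list(m2, m1))$r2)
})

test_that("similarity weights follow the kernel and clipping rules", {
  D <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
              dimnames = list(paste0("c", 1:3), paste0("c", 1:3)))
  sw <- similarity_weights(D_cells = D, D_drugs = D, mode = "wasserstein")
  expect_equal(sw$sigma_c, 2)  # median of (1, 2, 3)
  expect_equal(sw$w["c1", "c2"], exp(-1 / (2 * 4)))
  expect_equal(sw$w["c1", "c3"], exp(-4 / (2 * 4)))
  expect_equal(unname(diag(sw$w)), rep(0, 3))
  # d = sigma -> exp(-1/2)
  expect_equal(exp(-sw$sigma_c^2 / (2 * sw$sigma_c^2)), exp(-0.5))

  set.seed(3)
  E <- matrix(rnorm(4 * 10), 4, 10, dimnames = list(paste0("c", 1:4), NULL))
  E[2, ] <- -E[1, ] + rnorm(10, 0, 0.1)    # anti-correlated pair
  E[4, ] <- E[1, ] + rnorm(10, 0.1)        # keeps c1's weight row alive
  X <- matrix(rnorm(4 * 8), 4, 8, dimnames = list(paste0("d", 1:4), NULL))
  X[2, ] <- X[1, ] + rnorm(8, 0, 0.2)
  X[4, ] <- X[3, ] + rnorm(8, 0, 0.2)
  swp <- similarity_weights(expr = E, descriptors = X, mode = "pearson")
  expect_equal(swp$w["c1", "c2"], 0)
  expect_true(all(swp$w >= 0))
})

test_that("dual-layer closed form matches hand computation", {
  y <- matrix(c(1, 3, 2, NA), 2, 2,
              dimnames = list(c("c1", "c2"), c("d1", "d2")))
  W <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("c1", "c2"), c("c1", "c2")))
  V <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("d1", "d2"), c("d1", "d2")))
  sw <- structure(list(w = W, v = V, mode = "wasserstein"),
                  class = "similarity_weights")
  pred <- cdcn_predict(y, sw)
  # the missing (c2, d2) entry: cell layer y(c1, d2) = 2, drug layer y(c2, d1) = 3
  expect_equal(pred["c2", "d2"], (2 + 3) / 2)
  # the observed (c1, d2) entry is predicted leave-one-out from y(c1, d1) = 1
  expect_equal(pred["c1", "d2"], 1)

  # uniform weights, fully observed -> mean of row and column responses
  set.seed(4)
  cells <- paste0("c", 1:3); drugs <- paste0("d", 1:3)
  y3 <- matrix(rnorm(9), 3, 3, dimnames = list(cells, drugs))
  onesC <- matrix(1, 3, 3, dimnames = list(cells, cells)); diag(onesC) <- 0
  onesD <- matrix(1, 3, 3, dimnames = list(drugs, drugs)); diag(onesD) <- 0
  swu <- structure(list(w = onesC, v = onesD), class = "similarity_weights")
  pu <- cdcn_predict(y3, swu)
  expect_equal(pu["c2", "d3"],
               mean(c(y3["c1", "d3"], y3["c3", "d3"], y3["c2", "d1"], y3["c2", "d2"])))

  # constant surface is reproduced for any positive weights
  yc <- matrix(7, 3, 3, dimnames = dimnames(y3))
  wc <- onesC * matrix(runif(9, 0.2, 2), 3); wc <- (wc + t(wc)) / 2
  diag(wc) <- 0; dimnames(wc) <- list(cells, cells)
  wd <- onesD * matrix(runif(9, 0.2, 2), 3); wd <- (wd + t(wd)) / 2
  diag(wd) <- 0; dimnames(wd) <- list(drugs, drugs)
  swr <- structure(list(w = wc, v = wd), class = "similarity_weights")
  expect_true(all(abs(cdcn_predict(yc, swr) - 7) < 1e-12))

  # invariant to a common positive rescaling of all weights
  sws <- structure(list(w = wc * 13, v = wd * 13), class = "similarity_weights")
  expect_equal(cdcn_predict(y3, swr), cdcn_predict(y3, sws))
})

test_that("cdcn reports unpredictable pairs as NA", {
  y <- matrix(c(1, NA, NA, 5), 2, 2,
              dimnames = list(c("c1", "c2"), c("d1", "d2")))
  W <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("c1", "c2"), c("c1", "c2")))
  sw <- structure(list(w = W, v = W * 0, mode = "wasserstein"),
                  class = "similarity_weights")
  dimnames(sw$v) <- list(c("d1", "d2"), c("d1", "d2"))
  expect_message(pred <- cdcn_predict(y, sw), "no observed neighbor")
  expect_true(is.na(pred["c1", "d1"]))
})
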