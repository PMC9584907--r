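test_that("feature matrix equals a brute-force per-cell recomputation", {
  # 3 samples, 5 genes, 2 TFs, hand-built topologies
  expr <- matrix(c(4, 1, 0, 10, 2,
                   1, 8, 3, 5, 0,
                   2, 2, 2, 2, 2), 5, 3,
                 dimnames = list(c("T1", "T2", "g1", "g2", "g3"),
                                 c("sA", "sB", "sC")))
  nets <- list(
    toy_network("sA", data.frame(parent_tf = c("T1", "T1", "T2"),
                                 child_gene = c("g1", "g2", "g1"))),
    toy_network("sB", data.frame(parent_tf = c("T1", "T2"),
                                 child_gene = c("g1", "g3"))),
    toy_network("sC", data.frame(parent_tf = "T2", child_gene = "g2")))
  design <- validation_design(n_top = 5, floor = 1e-2, folds = 2)
  fm <- build_feature_matrix(nets, expr, design, tfs = c("T1", "T2"))
  expect_equal(ncol(fm$X), 2L)
  expect_equal(nrow(fm$X), 3 * 5) # 3 pairs x union of all 5 genes

  present <- list(
    sA = c("T1|g1", "T1|g2", "T2|g1"),
    sB = c("T1|g1", "T2|g3"),
    sC = c("T2|g2"))
  fl <- 1e-2
  pairs <- combn(c("sA", "sB", "sC"), 2)
  for (r in seq_len(nrow(fm$index))) {
    p <- fm$index$sample_p[r]; q <- fm$index$sample_q[r]; g <- fm$index$gene[r]
    for (tf in c("T1", "T2")) {
      ep <- if (paste0(tf, "|", g) %in% present[[p]])
        max(expr[tf, p], fl) else fl
      eq <- if (paste0(tf, "|", g) %in% present[[q]])
        max(expr[tf, q], fl) else fl
      expect_equal(unname(fm$X[r, tf]), log2(ep / eq), tolerance = 1e-12,
                   label = sprintf("row %d tf %s", r, tf))
    }
    expect_equal(unname(fm$y[r]), log2(max(expr[g, p], fl) / max(expr[g, q], fl)),
                 tolerance = 1e-12)
  }
})

test_that("flooring rules reproduce the worked ratios", {
  expr <- matrix(c(4, 7, 1, 3), 2, 2,
                 dimnames = list(c("T1", "g1"), c("sA", "sB")))
  both <- list(
    toy_network("sA", data.frame(parent_tf = "T1", child_gene = "g1")),
    toy_network("sB", data.frame(parent_tf = "T1", child_gene = "g1")))
  fm <- build_feature_matrix(both, expr, validation_design(n_top = 2, folds = 2),
                             tfs = "T1")
  r <- which(fm$index$gene == "g1")
  expect_equal(unname(fm$X[r, "T1"]), log2(4 / 1), tolerance = 1e-12)

  # edge missing in the second topology: denominator floored to 1e-2
  one <- list(
    toy_network("sA", data.frame(parent_tf = "T1", child_gene = "g1")),
    toy_network("sB", data.frame(parent_tf = "T1", child_gene = "gX")))
  expr2 <- rbind(expr, gX = c(1, 1))
  fm2 <- build_feature_matrix(one, expr2, validation_design(n_top = 3, folds = 2),
                              tfs = "T1")
  r <- which(fm2$index$gene == "g1")
  expect_equal(unname(fm2$X[r, "T1"]), log2(4 / 1e-2), tolerance = 1e-12) # ~8.6439

  # absent in both topologies: log2(floor/floor) = 0
  none <- list(
    toy_network("sA", data.frame(parent_tf = "T1", child_gene = "gX")),
    toy_network("sB", data.frame(parent_tf = "T1", child_gene = "gX")))
  fm3 <- build_feature_matrix(none, expr2, validation_design(n_top = 3, folds = 2),
                              tfs = "T1")
  r <- which(fm3$index$gene == "g1")
  expect_equal(unname(fm3$X[r, "T1"]), 0)
})

test_that("cross-validated RF recovers a noiseless linear response", {
  set.seed(41)
  X <- matrix(rnorm(2000 * 3), 2000, 3)
  y <- 2 * X[, 1] - X[, 2] + 0.5 * X[, 3]
  rep <- crossval_rf(X, y, validation_design(trees = 100, seed = 2))
  expect_gte(rep$mean_r, 0.95)
  expect_equal(length(rep$fold_r), 10L)
  expect_true(all(abs(rep$fold_r) <= 1, na.rm = TRUE))
})

test_that("pure-noise response gives |mean R| <= 0.1; reports are deterministic", {
  set.seed(42)
  X <- matrix(rnorm(1500 * 5), 1500, 5)
  y <- rnorm(1500)
  rep1 <- crossval_rf(X, y, validation_design(trees = 60, seed = 3))
  expect_lte(abs(rep1$mean_r), 0.1)
  rep2 <- crossval_rf(X, y, validation_design(trees = 60, seed = 3))
  expect_identical(rep1, rep2)
})

test_that("duplicating every row changes mean R by < 0.02", {
  set.seed(43)
  X <- matrix(rnorm(800 * 4), 800, 4)
  y <- X[, 1] + 0.5 * X[, 2] + rnorm(800, sd = 0.05)
  r1 <- crossval_rf(X, y, validation_design(trees = 60, seed = 5))$mean_r
  r2 <- crossval_rf(rbind(X, X), c(y, y),
                    validation_design(trees = 60, seed = 5))$mean_r
  expect_lt(abs(r1 - r2), 0.02)
})

test_that("row shuffling destroys coordinate-linked signal", {
  # balanced coefficients, so no signal survives in permutation-invariant
  # row statistics (an unbalanced coefficient sum would leak through the
  # row mean even after shuffling)
  set.seed(44)
  X <- matrix(rnorm(1500 * 6), 1500, 6)
  y <- X[, 1] - X[, 2] + 2 * X[, 3] - 2 * X[, 4]
  des <- validation_design(trees = 60, seed = 6)
  true_r <- crossval_rf(X, y, des)$mean_r
  shuf_r <- shuffled_baseline(X, y, des)$mean_r
  expect_gte(true_r, 0.9)
  expect_lte(abs(shuf_r), 0.15)
  # determinism of the shuffle
  expect_identical(shuffled_baseline(X, y, des), shuffled_baseline(X, y, des))
})

test_that("all-constant features make the shuffle a no-op", {
  set.seed(45)
  X <- matrix(1, 200, 4)
  y <- rnorm(200)
  des <- validation_design(trees = 20, seed = 7)
  expect_equal(shuffled_baseline(X, y, des)$fold_r,
               crossval_rf(X, y, des)$fold_r)
})

test_that("constant-response folds are excluded and reported", {
  set.seed(46)
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(1, 20) # every fold has zero response variance
  rep <- crossval_rf(X, y, validation_design(trees = 10, folds = 4, seed = 8))
  expect_equal(length(rep$excluded_folds), 4L)
  expect_true(is.nan(rep$mean_r))
})
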