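#' Design settings for topology validation
#'
#' @param n_top per-sample count of top expressed genes whose union (per
#'   sample pair) defines the rows (default 500).
#' @param floor replacement for zero expression and for TF expression in a
#'   topology lacking the TF -> gene edge (default 1e-2).
#' @param folds cross-validation folds (default 10).
#' @param trees random-forest size (default 100).
#' @param mtry features tried per split; NULL = max(1, p/3).
#' @param min_node minimum node size (default 5).
#' @param seed seed for fold assignment, forest and shuffling (default 1).
#' @return a `ValidationDesign` list.
#' @export
validation_design <- function(n_top = 500, floor = 1e-2, folds = 10,
                              trees = 100, mtry = NULL, min_node = 5,
                              seed = 1) {
  assert_that(n_top >= 1, "n_top must be >= 1")
  assert_that(floor > 0, "floor must be positive")
  assert_that(folds >= 2, "folds must be >= 2")
  structure(as.list(environment()), class = "ValidationDesign")
}

#' Build the pairwise expression-ratio feature matrix
#'
#' For every unordered sample pair (p, q) and every gene in the union of
#' the two samples' top-`n_top` expressed genes: one feature per TF equal
#' to `log2(e_tp / e_tq)`, where a TF's expression is replaced by the
#' floor in a sample whose topology lacks the TF -> gene edge, and any
#' value below the floor is floored before the ratio. The response is the
#' gene's own floored log2 expression ratio.
#'
#' @param networks list of per-sample `RegulatoryNetwork`s; their
#'   sample ids must appear in `expression`.
#' @param expression genes x samples TPM matrix.
#' @param design a `ValidationDesign`.
#' @param tfs TF feature set (default: union of parents across networks).
#' @return list with `X` (rows x TFs), `y`, and `index` (data.frame
#'   sample_p, sample_q, gene).
#' @export
build_feature_matrix <- function(networks, expression, design = validation_design(),
                                 tfs = NULL) {
  ids <- vapply(networks, `[[`, "", "sample_id")
  names(networks) <- ids
  assert_that(length(ids) >= 2L, "need >= 2 samples")
  assert_that(all(ids %in% colnames(expression)),
              "network sample ids missing from expression matrix")
  tfs <- sort(tfs %||% unique(unlist(lapply(networks, function(n)
    n$edges$parent_tf))))
  assert_that(length(tfs) >= 1L, "no TF features")
  miss <- setdiff(tfs, rownames(expression))
  assert_that(length(miss) == 0L, "TF '%s' missing from expression matrix",
              if (length(miss)) miss[1] else "")
  fl <- design$floor
  top <- lapply(ids, function(s) {
    v <- expression[, s]
    rownames(expression)[order(-v, rownames(expression))][seq_len(
      min(design$n_top, nrow(expression)))]
  })
  names(top) <- ids
  # per-sample edge presence, keyed tf|gene
  present <- lapply(networks, function(n) {
    e <- n$edges[n$edges$parent_tf %in% tfs, , drop = FALSE]
    unique(paste(e$parent_tf, e$child_gene, sep = "\r"))
  })
  pairs <- utils::combn(ids, 2)
  blocks <- vector("list", ncol(pairs))
  idx <- vector("list", ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    p <- pairs[1, c]; q <- pairs[2, c]
    genes <- sort(unique(c(top[[p]], top[[q]])))
    miss <- setdiff(genes, rownames(expression))
    assert_that(length(miss) == 0L, "gene '%s' missing from expression matrix",
                if (length(miss)) miss[1] else "")
    key <- outer(tfs, genes, paste, sep = "\r")
    ep <- matrix(rep(pmax(expression[tfs, p], fl), length(genes)),
                 nrow = length(tfs))
    eq <- matrix(rep(pmax(expression[tfs, q], fl), length(genes)),
                 nrow = length(tfs))
    ep[!key %in% present[[p]]] <- fl
    eq[!key %in% present[[q]]] <- fl
    blocks[[c]] <- t(log2(ep / eq))
    idx[[c]] <- data.frame(sample_p = p, sample_q = q, gene = genes,
                           stringsAsFactors = FALSE)
    attr(blocks[[c]], "y") <- log2(pmax(expression[genes, p], fl) /
                                     pmax(expression[genes, q], fl))
  }
  X <- do.call(rbind, blocks)
  colnames(X) <- tfs
  y <- unlist(lapply(blocks, attr, "y"), use.names = FALSE)
  index <- do.call(rbind, idx)
  rownames(X) <- rownames(index) <- NULL
  list(X = X, y = y, index = index)
}

#' Cross-validated random-forest regression with per-fold Pearson R
#'
#' Rows are randomly partitioned into `design$folds` folds (seeded); for
#' each fold a forest is fit on the remaining rows and the Pearson
#' correlation between held-out predictions and the true response is
#' recorded. Folds with zero response or prediction variance are excluded
#' from the mean and reported.
#'
#' @param X rows x features matrix.
#' @param y response vector.
#' @param design a `ValidationDesign`.
#' @param shuffled flag recorded in the report (set by
#'   [shuffled_baseline()]).
#' @return a `ValidationReport`: list with `fold_r`, `mean_r`, `n_rows`,
#'   `n_features`, `excluded_folds`, `shuffled`.
#' @export
crossval_rf <- function(X, y, design = validation_design(), shuffled = FALSE) {
  n <- nrow(X)
  assert_that(n == length(y), "X and y disagree")
  assert_that(n >= design$folds, "fewer rows than folds")
  set.seed(design$seed)
  fold <- sample(rep(seq_len(design$folds), length.out = n))
  mtry <- design$mtry %||% max(1L, ncol(X) %/% 3L)
  fold_r <- rep(NA_real_, design$folds)
  for (f in seq_len(design$folds)) {
    te <- fold == f
    pred <- cpp_rf_fit_predict(X[!te, , drop = FALSE], y[!te],
                               X[te, , drop = FALSE],
                               as.integer(design$trees), as.integer(mtry),
                               as.integer(design$min_node),
                               design$seed * 1000 + f)
    if (sd(y[te]) > 0 && sd(pred) > 0) fold_r[f] <- cor(pred, y[te])
  }
  structure(list(fold_r = fold_r, mean_r = mean(fold_r, na.rm = TRUE),
                 n_rows = n, n_features = ncol(X),
                 excluded_folds = which(is.na(fold_r)), shuffled = shuffled),
            class = "ValidationReport")
}

#' Row-shuffled topology baseline
#'
#' Independently permutes the feature values within each row (seeded),
#' breaking the feature-to-TF correspondence while preserving each row's
#' value multiset, then runs the identical cross-validation.
#'
#' @inheritParams crossval_rf
#' @return a `ValidationReport` with `shuffled = TRUE`.
#' @export
shuffled_baseline <- function(X, y, design = validation_design()) {
  set.seed(design$seed + 777L)
  keys <- matrix(runif(length(X)), nrow(X), ncol(X))
  ord <- t(apply(keys, 1, order))
  Xs <- matrix(X[cbind(rep(seq_len(nrow(X)), ncol(X)), as.vector(ord))],
               nrow(X), ncol(X))
  colnames(Xs) <- colnames(X)
  crossval_rf(Xs, y, design, shuffled = TRUE)
}
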