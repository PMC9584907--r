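#' Expression-derived node weights and seed vector
#'
#' Node weight is `exp(z_i)` where `z_i` is the gene's cross-sample
#' expression z-score in this sample; the seed vector is the weights
#' normalized to sum to 1.
#'
#' @param z named numeric vector of per-node z-scores (finite).
#' @return list with `weights` and `seed` (both named, seed sums to 1).
#' @export
node_weights <- function(z) {
  assert_that(length(z) > 0L, "network has no nodes")
  assert_that(all(is.finite(z)), "non-finite z-scores")
  w <- exp(z)
  list(weights = w, seed = w / sum(w))
}

#' Weight a regulatory network for Personalized PageRank
#'
#' The raw weight of an edge TF -> gene is
#' `exp(z_parent) * (peak intensity / max intensity in the sample) *
#' (motif score / max achievable PWM score)`, each factor clipped from
#' below at 1e-6; the clipped product is stored on the edges as their
#' weight. The random walk then runs along the reversed edges — a child
#' gene distributes its mass to its parent TFs in proportion to the raw
#' weights — so regulators of globally important targets accumulate rank.
#' Each walk-node's outgoing probabilities sum to 1; nodes without parents
#' in the regulatory network are dangling and their mass is redistributed
#' according to the seed.
#'
#' @param net a `RegulatoryNetwork` (from [build_network()] or
#'   [read_network()]).
#' @param expression genes x samples TPM matrix.
#' @param peaks the sample's `PeakSet` (for the intensity normalizer);
#'   NULL uses the maximum intensity stored on the edges.
#' @param log2_expression z-score on log2(TPM+1) (default TRUE).
#' @param clip lower clip applied to each weight factor (default 1e-6).
#' @return a `WeightedNetwork`: list with `sample_id`, `nodes`, `seed`,
#'   dense transition matrix `W` (`W[i, j]` = probability of stepping from
#'   node j to node i), logical `dangling`, and the weighted `edges`.
#' @export
edge_weights <- function(net, expression, peaks = NULL,
                         log2_expression = TRUE, clip = 1e-6) {
  nodes <- net$nodes
  assert_that(length(nodes) > 0L, "network has no nodes")
  if (is.null(net$node_z)) {
    zmat <- expression_zscores(expression, log2 = log2_expression)
    z <- setNames(rep(0, length(nodes)), nodes)
    common <- intersect(nodes, rownames(zmat))
    z[common] <- zmat[common, net$sample_id]
  } else {
    z <- net$node_z[nodes]
  }
  nw <- node_weights(z)
  e <- net$edges
  if (nrow(e)) {
    max_int <- if (!is.null(peaks)) max(peaks$intensity) else max(e$intensity)
    assert_that(is.finite(max_int) && max_int > 0, "no positive peak intensity")
    raw <- pmax(exp(z[e$parent_tf]), clip) *
      pmax(e$intensity / max_int, clip) *
      pmax(e$motif_frac, clip)
    e$weight <- as.vector(raw)
  }
  W <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  if (nrow(e)) {
    # reversed walk: child -> parent, normalized per child
    tot <- tapply(e$weight, e$child_gene, sum)
    W[cbind(match(e$parent_tf, nodes), match(e$child_gene, nodes))] <-
      e$weight / as.vector(tot[e$child_gene])
  }
  dangling <- colSums(W) == 0
  structure(list(sample_id = net$sample_id, nodes = nodes, seed = nw$seed,
                 W = W, dangling = dangling, edges = e),
            class = "WeightedNetwork")
}

#' Personalized PageRank by power iteration
#'
#' Iterates `v <- (1 - d) s + d (W v + m s)` from `v0 = s`, where `m` is
#' the probability mass sitting on dangling nodes (redistributed according
#' to the seed), until the L1 change per iteration drops below `tol`.
#' The iterate sums to 1 at every step; this is asserted to 1e-8.
#'
#' @param wnet a `WeightedNetwork` from [edge_weights()].
#' @param damping damping factor d in \[0, 1) (default 0.85); d = 0
#'   returns the seed vector exactly.
#' @param tol L1 convergence tolerance (default 1e-8).
#' @param max_iter iteration cap (default 1000); non-convergence is an
#'   error carrying the last residual.
#' @return named score vector over the nodes, summing to 1, with
#'   attribute `iterations`.
#' @export
personalized_pagerank <- function(wnet, damping = 0.85, tol = 1e-8,
                                  max_iter = 1000L) {
  assert_that(damping >= 0 && damping < 1, "damping must be in [0, 1)")
  assert_that(tol > 0, "tolerance must be positive")
  s <- wnet$seed
  assert_that(length(s) > 0L, "network has no nodes")
  if (damping == 0) {
    v <- s
    attr(v, "iterations") <- 0L
    return(v)
  }
  W <- wnet$W
  dang <- wnet$dangling
  v <- s
  for (it in seq_len(max_iter)) {
    m <- sum(v[dang])
    v_new <- (1 - damping) * s + damping * (as.vector(W %*% v) + m * s)
    names(v_new) <- names(s)
    assert_that(abs(sum(v_new) - 1) <= 1e-8,
                "probability mass not conserved (sum = %.12f)", sum(v_new))
    delta <- sum(abs(v_new - v))
    v <- v_new
    if (delta < tol) {
      attr(v, "iterations") <- it
      return(v)
    }
  }
  stop_pprnet("PageRank did not converge in %d iterations (last L1 residual %.3e)",
              max_iter, delta)
}

#' Assemble per-sample PageRank scores into a matrix with z-scores
#'
#' Node universes are unioned across samples; a node absent from a sample
#' gets score 0 there. z-scores are per node across samples, using the
#' sample standard deviation; zero-variance nodes get z = 0.
#'
#' @param scores named list (by sample) of named score vectors.
#' @param tfs character vector of TF names (the TF-restricted view).
#' @return a `PPRMatrix`: list with `raw` and `z` (nodes x samples
#'   matrices) and `tfs` (TFs present in the matrix).
#' @export
ppr_matrix <- function(scores, tfs) {
  assert_that(length(scores) >= 2L, "z-scores need >=2 samples")
  assert_that(!is.null(names(scores)), "scores list must be named by sample")
  nodes <- sort(unique(unlist(lapply(scores, names))))
  raw <- matrix(0, length(nodes), length(scores),
                dimnames = list(nodes, names(scores)))
  for (s in names(scores)) raw[names(scores[[s]]), s] <- scores[[s]]
  mu <- rowMeans(raw)
  sdv <- apply(raw, 1, sd)
  z <- (raw - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  structure(list(raw = raw, z = z, tfs = intersect(tfs, nodes)),
            class = "PPRMatrix")
}
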