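#' Select the most variable expressed TFs
#'
#' TFs are filtered to those expressed (TPM >= `expressed_min_tpm` in at
#' least one sample), ranked by the cross-sample variance of their raw
#' PageRank scores, and the top `n_top` returned. Variance ties are broken
#' lexicographically by TF name. Ranking is done on raw scores, before any
#' z-scoring, because z-scoring equalizes per-TF variance.
#'
#' @param ppr a `PPRMatrix` (see [ppr_matrix()]).
#' @param expression genes x samples TPM matrix.
#' @param n_top how many TFs to keep (default 350).
#' @param expressed_min_tpm expression filter threshold (default 1).
#' @return character vector of TF names, most variable first.
#' @export
select_variable_tfs <- function(ppr, expression, n_top = 350,
                                expressed_min_tpm = 1) {
  assert_that(n_top >= 2, "n_top must be >= 2")
  tfs <- ppr$tfs
  in_expr <- tfs[tfs %in% rownames(expression)]
  expressed <- in_expr[apply(expression[in_expr, , drop = FALSE] >=
                               expressed_min_tpm, 1, any)]
  assert_that(length(expressed) >= 2L,
              "fewer than 2 TFs survive the expression filter")
  v <- apply(ppr$raw[expressed, , drop = FALSE], 1, var)
  ord <- expressed[order(-v, expressed)]
  head(ord, n_top)
}

#' Stratify samples by hierarchical clustering of z-scored PageRank
#'
#' Agglomerative clustering with Euclidean distance and complete linkage
#' on the per-TF z-score columns, cut into `k` clusters. Cluster labels
#' are ordered by size, largest first (`CL1`, `CL2`, ...); size ties are
#' broken by the lexicographically smallest member sample.
#'
#' @param ppr_z TFs x samples matrix of z-scored PageRank (typically
#'   `ppr$z[selected_tfs, ]`).
#' @param k number of clusters (default 2).
#' @return a `ClusterAssignment`: list with `labels` (named by sample),
#'   `k`, `tree` (the hclust object), `selected_tfs` and `params`.
#' @export
cluster_samples <- function(ppr_z, k = 2) {
  n <- ncol(ppr_z)
  assert_that(k >= 1 && k <= n, "k must be between 1 and the number of samples")
  assert_that(!anyNA(ppr_z), "missing values in the PageRank matrix")
  tree <- hclust(dist(t(ppr_z), method = "euclidean"), method = "complete")
  raw <- cutree(tree, k = k)
  sizes <- table(raw)
  first_member <- vapply(names(sizes), function(l) {
    min(names(raw)[raw == as.integer(l)])
  }, "")
  ord <- names(sizes)[order(-as.vector(sizes), first_member)]
  labels <- setNames(paste0("CL", match(as.character(raw), ord)), names(raw))
  structure(list(labels = labels, k = k, tree = tree,
                 selected_tfs = rownames(ppr_z),
                 params = list(distance = "euclidean", linkage = "complete")),
            class = "ClusterAssignment")
}

cluster_members <- function(assignment, cluster) {
  names(assignment$labels)[assignment$labels == cluster]
}

#' Per-sample silhouette widths for a cluster assignment
#'
#' Standard silhouettes with Euclidean distance. Members of singleton
#' clusters get silhouette 0 (the usual convention), as do all samples
#' when every pairwise distance is zero.
#'
#' @param assignment a `ClusterAssignment`.
#' @param mat features x samples matrix (samples in columns).
#' @return data.frame sample, cluster, sil_width.
#' @export
silhouette_report <- function(assignment, mat) {
  assert_that(assignment$k >= 2, "silhouettes need k >= 2")
  samples <- names(assignment$labels)
  assert_that(all(samples %in% colnames(mat)), "samples missing from matrix")
  d <- dist(t(mat[, samples, drop = FALSE]), method = "euclidean")
  cl <- as.integer(factor(assignment$labels))
  if (max(d) == 0 || assignment$k == length(samples)) {
    sw <- rep(0, length(samples))
  } else {
    sil <- cluster::silhouette(cl, d)
    sw <- sil[, "sil_width"]
  }
  data.frame(sample = samples, cluster = unname(assignment$labels),
             sil_width = as.vector(sw), stringsAsFactors = FALSE)
}
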