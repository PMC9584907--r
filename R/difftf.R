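# Two-sample Hotelling T2 on PCA-reduced data.
# X: samples x variables; g1/g2: row indices of the two groups.
# k = smallest PC count explaining >= variance_kept of the variance,
# capped at n1+n2-2 (and at the number of positive-variance PCs).
hotelling_core <- function(X, g1, g2, variance_kept = 0.90,
                           ridge = 1e-6) {
  n1 <- length(g1); n2 <- length(g2)
  assert_that(n1 >= 2 && n2 >= 2, "each group needs >= 2 samples")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (sum(ev) <= 0) {
    return(list(k = 0L, T2 = 0, F = 0, p = 1, df2 = n1 + n2 - 2,
                skipped = "zero variance"))
  }
  k90 <- which(cumsum(ev) / sum(ev) >= variance_kept)[1]
  k <- min(k90, n1 + n2 - 2L, sum(ev > 1e-12))
  S <- pc$x[, seq_len(k), drop = FALSE]
  d <- colMeans(S[g1, , drop = FALSE]) - colMeans(S[g2, , drop = FALSE])
  S1 <- cov(S[g1, , drop = FALSE])
  S2 <- cov(S[g2, , drop = FALSE])
  Sp <- ((n1 - 1) * S1 + (n2 - 1) * S2) / (n1 + n2 - 2)
  M <- Sp * (1 / n1 + 1 / n2)
  Minv <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(Minv) || !all(is.finite(Minv))) {
    lambda <- ridge * sum(diag(Sp)) / k
    if (lambda <= 0) lambda <- ridge
    Minv <- solve(M + diag(lambda, k))
  }
  T2 <- drop(t(d) %*% Minv %*% d)
  Fstat <- (n1 + n2 - k - 1) / (k * (n1 + n2 - 2)) * T2
  df2 <- n1 + n2 - k - 1
  p <- pf(Fstat, k, df2, lower.tail = FALSE)
  list(k = k, T2 = T2, F = Fstat, p = p, df2 = df2, skipped = NA_character_)
}

#' Union of a TF's regulatees across sample networks
#'
#' @param tf TF name.
#' @param networks list of `RegulatoryNetwork`s (one per sample).
#' @return character vector of child genes (empty if the TF is absent
#'   from every network).
#' @export
regulatee_union <- function(tf, networks) {
  kids <- lapply(networks, function(n) {
    n$edges$child_gene[n$edges$parent_tf == tf]
  })
  sort(unique(unlist(kids)))
}

#' Regulatee-PCA Hotelling T-squared test for one TF
#'
#' Tests whether the TF's regulatees (union of its child nodes across all
#' sample networks) have different PageRank z-score profiles between the
#' two clusters. The samples x regulatees matrix is reduced by centered
#' PCA to the smallest number of components explaining
#' `variance_kept` of the variance (capped at n1 + n2 - 2); the two-sample
#' Hotelling T2 with pooled covariance is referred to
#' `F(k, n1 + n2 - k - 1)`. A TF with no regulatees is reported with
#' p = 1 and k = 0 (test skipped). A singular pooled covariance is
#' ridge-shrunk (`lambda = 1e-6 tr(Sp)/k`).
#'
#' @param tf TF name.
#' @param ppr a `PPRMatrix` (node-level z-scores are used).
#' @param assignment a `ClusterAssignment` with two clusters.
#' @param networks list of per-sample `RegulatoryNetwork`s.
#' @param variance_kept cumulative explained-variance target (default 0.90).
#' @return one-row data.frame (`HotellingResult`): tf, n_regulatees, n1,
#'   n2, k, T2, F, df1, df2, p.
#' @export
regulatee_hotelling <- function(tf, ppr, assignment, networks,
                                variance_kept = 0.90) {
  samples <- names(assignment$labels)
  g1 <- which(assignment$labels[samples] == "CL1")
  g2 <- which(assignment$labels[samples] == "CL2")
  assert_that(length(g1) + length(g2) >= 4, "need n1 + n2 >= 4")
  regs <- regulatee_union(tf, networks)
  regs <- intersect(regs, rownames(ppr$z))
  if (length(regs) == 0L) {
    return(data.frame(tf = tf, n_regulatees = 0L, n1 = length(g1),
                      n2 = length(g2), k = 0L, T2 = 0, F = 0, df1 = 0L,
                      df2 = length(g1) + length(g2) - 2L, p = 1,
                      stringsAsFactors = FALSE))
  }
  X <- t(ppr$z[regs, samples, drop = FALSE])
  h <- hotelling_core(X, g1, g2, variance_kept)
  data.frame(tf = tf, n_regulatees = length(regs), n1 = length(g1),
             n2 = length(g2), k = h$k, T2 = h$T2, F = h$F, df1 = h$k,
             df2 = h$df2, p = h$p, stringsAsFactors = FALSE)
}

#' Rank and select cluster-specific TFs
#'
#' TFs are ranked by the absolute difference in mean PageRank z-score
#' between the two clusters (`delta_mean_z`). The top `n_candidates` are
#' tested with [regulatee_hotelling()]; the shortlist keeps the top
#' `n_shortlist` by delta among those with Hotelling p < `alpha`;
#' Benjamini-Hochberg q-values are computed over all tested candidates and
#' the final selection is the shortlist members with q < `q_alpha`.
#'
#' @param ppr a `PPRMatrix`.
#' @param assignment a `ClusterAssignment` with clusters CL1 and CL2, each
#'   of size >= 2.
#' @param networks list of per-sample `RegulatoryNetwork`s.
#' @param n_candidates TFs tested (default 200).
#' @param n_shortlist shortlist size (default 100).
#' @param alpha Hotelling p threshold (default 0.05).
#' @param q_alpha BH q threshold (default 0.05).
#' @param variance_kept PCA variance target (default 0.90).
#' @return data.frame ordered by delta_mean_z (descending): tf,
#'   delta_mean_z, mean_z_cl1, mean_z_cl2, plus the Hotelling columns, q,
#'   shortlisted and selected flags. Attribute `selected` carries the
#'   selected TF names.
#' @export
rank_cluster_tfs <- function(ppr, assignment, networks, n_candidates = 200,
                             n_shortlist = 100, alpha = 0.05,
                             q_alpha = 0.05, variance_kept = 0.90) {
  s1 <- cluster_members(assignment, "CL1")
  s2 <- cluster_members(assignment, "CL2")
  assert_that(length(s1) >= 2 && length(s2) >= 2,
              "both clusters need >= 2 samples (got %d and %d)",
              length(s1), length(s2))
  z <- ppr$z[ppr$tfs, , drop = FALSE]
  m1 <- rowMeans(z[, s1, drop = FALSE])
  m2 <- rowMeans(z[, s2, drop = FALSE])
  delta <- abs(m1 - m2)
  ord <- names(delta)[order(-delta, names(delta))]
  cand <- head(ord, n_candidates)
  res <- do.call(rbind, lapply(cand, regulatee_hotelling, ppr = ppr,
                               assignment = assignment, networks = networks,
                               variance_kept = variance_kept))
  res$delta_mean_z <- delta[res$tf]
  res$mean_z_cl1 <- m1[res$tf]
  res$mean_z_cl2 <- m2[res$tf]
  res$q <- p.adjust(res$p, method = "BH")
  passing <- res$tf[res$p < alpha]
  shortlist <- head(intersect(cand, passing), n_shortlist)
  res$shortlisted <- res$tf %in% shortlist
  res$selected <- res$shortlisted & res$q < q_alpha
  res <- res[order(-res$delta_mean_z, res$tf),
             c("tf", "delta_mean_z", "mean_z_cl1", "mean_z_cl2",
               "n_regulatees", "n1", "n2", "k", "T2", "F", "df1", "df2",
               "p", "q", "shortlisted", "selected")]
  rownames(res) <- NULL
  attr(res, "selected") <- res$tf[res$selected]
  res
}

#' Differentially expressed genes between the two clusters
#'
#' Fold change is the ratio of cluster mean TPM (pseudocount 0.01 on both
#' sides); the two-sided Student t-test (pooled variance) is run on
#' log2(TPM + 1). A gene is a DEG iff fold > `fold_min` in either
#' direction AND p < `alpha`, both strict. Genes with zero pooled variance
#' get p = 1 when the group means agree and p = 0 otherwise.
#'
#' @param expression genes x samples TPM matrix.
#' @param assignment a `ClusterAssignment` (clusters CL1 and CL2, each
#'   at least 2 samples).
#' @param fold_min fold-change threshold (default 2).
#' @param alpha p threshold (default 0.05).
#' @param pseudocount added to both cluster means for the ratio (0.01).
#' @return a `DEGTable` data.frame: gene_id, mean_cl1, mean_cl2, fold,
#'   log2_fold, t, p, deg.
#' @export
compute_degs <- function(expression, assignment, fold_min = 2,
                         alpha = 0.05, pseudocount = 0.01) {
  s1 <- cluster_members(assignment, "CL1")
  s2 <- cluster_members(assignment, "CL2")
  assert_that(length(s1) >= 2 && length(s2) >= 2,
              "both clusters need >= 2 samples")
  x1 <- expression[, s1, drop = FALSE]
  x2 <- expression[, s2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  fold <- (m1 + pseudocount) / (m2 + pseudocount)
  l1 <- log2(x1 + 1); l2 <- log2(x2 + 1)
  n1 <- length(s1); n2 <- length(s2)
  mu1 <- rowMeans(l1); mu2 <- rowMeans(l2)
  v1 <- apply(l1, 1, var); v2 <- apply(l2, 1, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, (mu1 - mu2) / se, 0)
  p <- ifelse(se > 0, 2 * pt(-abs(t), df = n1 + n2 - 2),
              ifelse(mu1 == mu2, 1, 0))
  deg <- (fold > fold_min | fold < 1 / fold_min) & p < alpha
  out <- data.frame(gene_id = rownames(expression), mean_cl1 = m1,
                    mean_cl2 = m2, fold = fold, log2_fold = log2(fold),
                    t = t, p = p, deg = deg, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("DEGTable", "data.frame")
  out
}

#' Fraction of DEGs regulated by a TF set
#'
#' The union of the TFs' regulatees (across all sample networks) is
#' intersected with the DEG set; the fraction of DEGs covered is
#' returned.
#'
#' @param tf_set character vector of TF names.
#' @param degs a `DEGTable` (or a character vector of DEG gene ids).
#' @param networks list of per-sample `RegulatoryNetwork`s.
#' @return list with `fraction`, `n_regulated`, `n_deg` and the regulated
#'   DEG ids.
#' @export
regulated_fraction <- function(tf_set, degs, networks) {
  deg_set <- if (is.character(degs)) degs else degs$gene_id[degs$deg]
  assert_that(length(deg_set) > 0L, "no DEGs to cover")
  regs <- unique(unlist(lapply(tf_set, regulatee_union, networks = networks)))
  covered <- intersect(regs, deg_set)
  list(fraction = length(covered) / length(deg_set),
       n_regulated = length(covered), n_deg = length(deg_set),
       regulated = sort(covered))
}

#' Cluster-specific TF-TF subnetwork
#'
#' Keeps TF -> TF edges present in strictly more than `presence_min` of
#' the target cluster's networks whose mean edge weight in that cluster
#' (absent edges counted as weight 0) is strictly more than
#' `weight_ratio_min` times the mean in the other cluster (denominator
#' stabilized with eps = 1e-12).
#'
#' @param networks list of weighted per-sample `RegulatoryNetwork`s (edge
#'   weights set, e.g. via [edge_weights()]).
#' @param assignment a `ClusterAssignment`.
#' @param cluster target cluster label ("CL1" or "CL2").
#' @param tfs TF universe used for both the parent and the child side;
#'   default: every gene that acts as a parent in some network.
#' @param presence_min presence threshold, strict (default 0.75).
#' @param weight_ratio_min weight-ratio threshold, strict (default 1.5).
#' @return data.frame of `SubnetworkEdge`s: parent_tf, child_tf, cluster,
#'   presence, mean_weight_in, mean_weight_out, weight_ratio; attribute
#'   `out_degree` is a named count per parent for display sizing.
#' @export
tf_tf_subnetwork <- function(networks, assignment, cluster,
                             tfs = NULL, presence_min = 0.75,
                             weight_ratio_min = 1.5) {
  eps <- 1e-12
  ids <- vapply(networks, `[[`, "", "sample_id")
  names(networks) <- ids
  in_s <- intersect(ids, cluster_members(assignment, cluster))
  out_s <- intersect(ids, setdiff(names(assignment$labels), in_s))
  assert_that(length(in_s) > 0L, "cluster '%s' has no networks", cluster)
  tfs <- tfs %||%
    unique(unlist(lapply(networks, function(n) n$edges$parent_tf)))
  edge_tab <- function(n) {
    e <- n$edges[n$edges$parent_tf %in% tfs &
                   n$edges$child_gene %in% tfs, , drop = FALSE]
    setNames(e$weight, paste(e$parent_tf, e$child_gene, sep = "\r"))
  }
  tabs <- lapply(networks, edge_tab)
  keys <- unique(unlist(lapply(tabs[in_s], names)))
  if (!length(keys)) {
    return(structure(data.frame(parent_tf = character(), child_tf = character(),
                                cluster = character(), presence = numeric(),
                                mean_weight_in = numeric(),
                                mean_weight_out = numeric(),
                                weight_ratio = numeric(),
                                stringsAsFactors = FALSE),
                     out_degree = integer()))
  }
  wmat <- function(samples) {
    m <- vapply(samples, function(s) {
      w <- tabs[[s]][keys]
      ifelse(is.na(w), 0, w)
    }, numeric(length(keys)))
    matrix(m, nrow = length(keys))
  }
  w_in <- wmat(in_s)
  presence <- rowMeans(w_in > 0)
  mean_in <- rowMeans(w_in)
  mean_out <- if (length(out_s)) rowMeans(wmat(out_s)) else rep(0, length(keys))
  ratio <- mean_in / (mean_out + eps)
  keep <- presence > presence_min & ratio > weight_ratio_min
  pc <- strsplit(keys[keep], "\r", fixed = TRUE)
  out <- data.frame(parent_tf = vapply(pc, `[[`, "", 1),
                    child_tf = vapply(pc, `[[`, "", 2),
                    cluster = rep(cluster, sum(keep)),
                    presence = presence[keep],
                    mean_weight_in = mean_in[keep],
                    mean_weight_out = mean_out[keep],
                    weight_ratio = ratio[keep], stringsAsFactors = FALSE)
  out <- out[order(out$parent_tf, out$child_tf), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "out_degree") <- c(table(out$parent_tf))
  out
}

#' Hypergeometric over-representation test against gene-set collections
#'
#' Upper-tail hypergeometric p-value per set (overlap at least as large as
#' observed), BH-adjusted across sets. Set members outside the universe
#' are ignored.
#'
#' @param query character vector of genes (must lie in `universe`).
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @param universe character vector of background genes.
#' @return data.frame: set, set_size, overlap, p, q, ordered by p.
#' @export
hypergeom_enrichment <- function(query, collection, universe) {
  universe <- unique(universe)
  query <- unique(query)
  assert_that(length(universe) > 0L, "empty universe")
  assert_that(length(query) > 0L, "empty query")
  assert_that(all(query %in% universe), "query genes outside the universe")
  rows <- lapply(names(collection), function(nm) {
    K <- intersect(collection[[nm]], universe)
    ov <- length(intersect(query, K))
    p <- phyper(ov - 1, length(K), length(universe) - length(K),
                length(query), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(K), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
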