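#' Strand-aware promoter windows around TSSs
#'
#' The promoter of a gene is the 5 kb upstream / 1 kb downstream region
#' around its TSS (defaults), oriented by strand, as a 0-based half-open
#' interval clipped at the chromosome origin.
#'
#' @param annotation a `GeneAnnotation` (or any data.frame with gene_id,
#'   chrom, tss, strand).
#' @param upstream,downstream window extents in bp (defaults 5000 and 1000).
#' @return data.frame gene_id, chrom, start, end.
#' @export
promoter_window <- function(annotation, upstream = 5000, downstream = 1000) {
  assert_that(all(annotation$strand %in% c("+", "-")), "invalid strand")
  plus <- annotation$strand == "+"
  start <- ifelse(plus, annotation$tss - upstream, annotation$tss - downstream)
  end <- ifelse(plus, annotation$tss + downstream, annotation$tss + upstream)
  data.frame(gene_id = annotation$gene_id, chrom = annotation$chrom,
             start = pmax(start, 0), end = end, stringsAsFactors = FALSE)
}

#' Classify peaks as promoter or enhancer evidence
#'
#' A peak overlapping at least one promoter window by >= 1 bp is a
#' promoter peak, assigned to every overlapped gene. Remaining (distal)
#' peaks are enhancer peaks, assigned to genes only through the link
#' table; distal peaks with no link are dropped. Links that point at a
#' promoter-classified peak are ignored (the classification is exclusive)
#' and reported.
#'
#' @param peaks a `PeakSet`.
#' @param annotation a `GeneAnnotation`.
#' @param links an `EnhancerLinkTable` (peak_id, gene_id).
#' @param upstream,downstream promoter window extents (see
#'   [promoter_window()]).
#' @return list with data.frames `promoter` and `enhancer` (peak_id,
#'   gene_id), character `dropped` (distal unlinked peak ids) and
#'   `ignored_links` (links into promoter peaks).
#' @export
classify_peaks <- function(peaks, annotation, links,
                           upstream = 5000, downstream = 1000) {
  win <- promoter_window(annotation, upstream, downstream)
  prom <- list()
  for (chr in unique(peaks$chrom)) {
    p <- which(peaks$chrom == chr)
    w <- which(win$chrom == chr)
    if (!length(p) || !length(w)) next
    # peak [s,e) overlaps window [ws,we) iff s < we and e > ws
    ov <- outer(peaks$start[p], win$end[w], `<`) &
      outer(peaks$end[p], win$start[w], `>`)
    hit <- which(ov, arr.ind = TRUE)
    if (nrow(hit)) {
      prom[[chr]] <- data.frame(peak_id = peaks$peak_id[p][hit[, 1]],
                                gene_id = win$gene_id[w][hit[, 2]],
                                stringsAsFactors = FALSE)
    }
  }
  promoter <- if (length(prom)) do.call(rbind, prom) else
    data.frame(peak_id = character(), gene_id = character(),
               stringsAsFactors = FALSE)
  rownames(promoter) <- NULL
  prom_peaks <- unique(promoter$peak_id)
  lk <- links[links$peak_id %in% peaks$peak_id &
                links$gene_id %in% annotation$gene_id, , drop = FALSE]
  ignored <- lk[lk$peak_id %in% prom_peaks, , drop = FALSE]
  enhancer <- lk[!lk$peak_id %in% prom_peaks, , drop = FALSE]
  rownames(ignored) <- rownames(enhancer) <- NULL
  dropped <- setdiff(peaks$peak_id, c(prom_peaks, enhancer$peak_id))
  list(promoter = promoter,
       enhancer = as.data.frame(enhancer),
       dropped = dropped,
       ignored_links = as.data.frame(ignored))
}

# 150 bp scan windows centred on peak summits, clipped to the peak.
# Returns per-peak window substrings of the peak sequences plus their
# genomic start.
summit_windows <- function(peaks, sequences, window = 150L) {
  half <- window %/% 2L
  ws <- pmax(peaks$summit - half, peaks$start)
  we <- pmin(peaks$summit + (window - half), peaks$end)
  miss <- setdiff(peaks$peak_id, names(sequences))
  assert_that(length(miss) == 0L, "missing sequence for peak '%s'",
              if (length(miss)) miss[1] else "")
  seqs <- sequences[peaks$peak_id]
  lens <- nchar(seqs)
  assert_that(all(lens == peaks$end - peaks$start),
              "sequence length disagrees with peak width")
  out <- substring(seqs, ws - peaks$start + 1L, we - peaks$start)
  names(out) <- peaks$peak_id
  attr(out, "window_start") <- setNames(ws, peaks$peak_id)
  out
}

#' Build a per-sample TF-to-gene regulatory network
#'
#' Scans the 150 bp summit-centred window of every peak with every motif,
#' then creates a directed edge TF -> gene whenever the TF has a
#' significant hit in a promoter peak of the gene or in an enhancer peak
#' linked to it. Multiple supporting hits for one (TF, gene) pair are
#' aggregated to a single edge keeping the maximum motif score (with its
#' peak and evidence) and the maximum supporting peak intensity. Every
#' node carries its cross-sample expression z-score; edge weights are
#' initialised to 0 and set later by [edge_weights()].
#'
#' @param sample_id sample whose peaks are used.
#' @param peaks a `PeakSet` for the sample.
#' @param sequences named character vector of full peak sequences (by
#'   peak_id), e.g. from [read_sequences()].
#' @param annotation a `GeneAnnotation`.
#' @param motifs a `MotifLibrary`.
#' @param links an `EnhancerLinkTable`.
#' @param expression genes x samples TPM matrix (all samples; the
#'   z-scores are cross-sample).
#' @param p_threshold motif significance threshold (default 1e-4).
#' @param background 4 base frequencies; NULL (default) estimates a
#'   0-order background from the scanned windows of this sample.
#' @param scan_window width of the summit-centred scan region (150).
#' @param upstream,downstream promoter window extents.
#' @param log2_expression z-score expression on log2(TPM+1) (default TRUE).
#' @return a `RegulatoryNetwork`; `$report` holds peak/hit/edge counts.
#' @export
build_network <- function(sample_id, peaks, sequences, annotation, motifs,
                          links, expression, p_threshold = 1e-4,
                          background = NULL, scan_window = 150L,
                          upstream = 5000, downstream = 1000,
                          log2_expression = TRUE) {
  assert_that(inherits(motifs, "MotifLibrary"), "motifs must be a MotifLibrary")
  cls <- classify_peaks(peaks, annotation, links, upstream, downstream)
  windows <- summit_windows(peaks, sequences, scan_window)
  if (is.null(background)) {
    counts <- table(factor(unlist(strsplit(paste(windows, collapse = ""), "",
                                           fixed = TRUE)), DNA_BASES))
    background <- if (sum(counts) > 0) as.vector(counts / sum(counts)) else
      rep(0.25, 4)
    if (any(background == 0)) background <- rep(0.25, 4)
  }
  tf_names <- vapply(motifs, `[[`, "", "tf_name")
  extra_tfs <- setdiff(tf_names, annotation$gene_id)
  if (length(extra_tfs)) {
    warning(sprintf("%d motif TF(s) absent from annotation (e.g. %s); added as nodes with zero expression",
                    length(extra_tfs), extra_tfs[1]), call. = FALSE)
  }
  # Cross-sample z-scores for node annotation.
  zmat <- expression_zscores(expression, log2 = log2_expression)
  assert_that(sample_id %in% colnames(expression),
              "sample '%s' not in expression matrix", sample_id)
  nodes <- sort(unique(c(annotation$gene_id, tf_names)))
  node_z <- setNames(rep(0, length(nodes)), nodes)
  common <- intersect(nodes, rownames(zmat))
  node_z[common] <- zmat[common, sample_id]

  # peak -> gene evidence maps
  assign_tab <- rbind(
    if (nrow(cls$promoter)) cbind(cls$promoter, evidence = "promoter"),
    if (nrow(cls$enhancer)) cbind(cls$enhancer[c("peak_id", "gene_id")],
                                  evidence = "enhancer"))
  encoded <- lapply(windows, encode_dna)
  sc <- scan_library(encoded, motifs, background, p_threshold)
  edges <- edges_from_hits(sc, assign_tab,
                           setNames(peaks$intensity, peaks$peak_id))
  report <- list(sample_id = sample_id,
                 n_peaks = nrow(peaks),
                 n_promoter_peaks = length(unique(cls$promoter$peak_id)),
                 n_enhancer_peaks = length(unique(cls$enhancer$peak_id)),
                 n_dropped_peaks = length(cls$dropped),
                 n_ignored_links = nrow(cls$ignored_links),
                 n_hits = sc$n_hits,
                 n_edges = nrow(edges),
                 background = as.vector(background))
  new_network(sample_id, edges, nodes, node_z = node_z, report = report)
}

# Scan every motif over the encoded windows; keep the strongest hit per
# (motif, peak) with the score normalized by the PWM's maximum.
scan_library <- function(encoded, motifs, background, p_threshold) {
  n_hits <- 0L
  best <- lapply(motifs, function(m) {
    hits <- scan_motifs(encoded, m, background = background,
                        p_threshold = p_threshold)
    n_hits <<- n_hits + nrow(hits)
    if (!nrow(hits)) return(NULL)
    mx <- pwm_max_score(m$pwm, background)
    b <- hits[order(hits$peak_id, -hits$score), , drop = FALSE]
    b <- b[!duplicated(b$peak_id), , drop = FALSE]
    b$motif_frac <- b$score / mx
    b
  })
  list(best = best, n_hits = n_hits)
}

# Turn per-motif best hits into aggregated edges for one sample:
# one edge per (TF, gene), max-score evidence, max supporting intensity.
edges_from_hits <- function(sc, assign_tab, intensity) {
  edge_rows <- list()
  for (tf in names(sc$best)) {
    b <- sc$best[[tf]]
    if (is.null(b) || is.null(assign_tab) || !nrow(assign_tab)) next
    j <- merge(assign_tab, b, by = "peak_id")
    if (!nrow(j)) next
    j$intensity <- intensity[j$peak_id]
    j <- j[order(j$gene_id, -j$score), , drop = FALSE]
    max_int <- tapply(j$intensity, j$gene_id, max)
    j <- j[!duplicated(j$gene_id), , drop = FALSE]
    edge_rows[[tf]] <- data.frame(
      parent_tf = tf, child_gene = j$gene_id, weight = 0,
      evidence = as.character(j$evidence), peak_id = j$peak_id,
      motif_score = j$score, motif_frac = j$motif_frac,
      intensity = as.vector(max_int[j$gene_id]), stringsAsFactors = FALSE)
  }
  edges <- if (length(edge_rows)) do.call(rbind, edge_rows) else empty_edges_df()
  edges <- edges[order(edges$parent_tf, edges$child_gene), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Build networks for all samples sharing one peak atlas
#'
#' When every sample's peaks have identical coordinates and sequences
#' (e.g. a pooled peak atlas, or [simulate_dataset()] output, where only
#' intensities vary by sample), the motif scan is identical across
#' samples. This builds all networks with a single scan; results equal
#' calling [build_network()] per sample.
#'
#' @param peaks named list of per-sample `PeakSet`s with identical
#'   coordinates.
#' @inheritParams build_network
#' @return named list of `RegulatoryNetwork`s.
#' @export
build_networks <- function(peaks, sequences, annotation, motifs, links,
                           expression, p_threshold = 1e-4,
                           background = NULL, scan_window = 150L,
                           upstream = 5000, downstream = 1000,
                           log2_expression = TRUE) {
  assert_that(length(peaks) >= 1L, "no samples")
  ref <- peaks[[1]]
  for (p in peaks[-1]) {
    assert_that(identical(p[c("chrom", "start", "end", "peak_id", "summit")],
                          ref[c("chrom", "start", "end", "peak_id", "summit")]),
                "build_networks() needs identical peak coordinates across samples; use build_network() per sample")
  }
  cls <- classify_peaks(ref, annotation, links, upstream, downstream)
  windows <- summit_windows(ref, sequences, scan_window)
  if (is.null(background)) {
    counts <- table(factor(unlist(strsplit(paste(windows, collapse = ""), "",
                                           fixed = TRUE)), DNA_BASES))
    background <- if (sum(counts) > 0) as.vector(counts / sum(counts)) else
      rep(0.25, 4)
    if (any(background == 0)) background <- rep(0.25, 4)
  }
  assign_tab <- rbind(
    if (nrow(cls$promoter)) cbind(cls$promoter, evidence = "promoter"),
    if (nrow(cls$enhancer)) cbind(cls$enhancer[c("peak_id", "gene_id")],
                                  evidence = "enhancer"))
  encoded <- lapply(windows, encode_dna)
  sc <- scan_library(encoded, motifs, background, p_threshold)
  tf_names <- vapply(motifs, `[[`, "", "tf_name")
  nodes <- sort(unique(c(annotation$gene_id, tf_names)))
  zmat <- expression_zscores(expression, log2 = log2_expression)
  common <- intersect(nodes, rownames(zmat))
  nets <- lapply(names(peaks), function(s) {
    assert_that(s %in% colnames(expression),
                "sample '%s' not in expression matrix", s)
    node_z <- setNames(rep(0, length(nodes)), nodes)
    node_z[common] <- zmat[common, s]
    edges <- edges_from_hits(sc, assign_tab,
                             setNames(peaks[[s]]$intensity,
                                      peaks[[s]]$peak_id))
    report <- list(sample_id = s, n_peaks = nrow(ref),
                   n_promoter_peaks = length(unique(cls$promoter$peak_id)),
                   n_enhancer_peaks = length(unique(cls$enhancer$peak_id)),
                   n_dropped_peaks = length(cls$dropped),
                   n_ignored_links = nrow(cls$ignored_links),
                   n_hits = sc$n_hits, n_edges = nrow(edges),
                   background = as.vector(background))
    new_network(s, edges, nodes, node_z = node_z, report = report)
  })
  names(nets) <- names(peaks)
  nets
}
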