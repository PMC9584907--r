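#' Configuration for the synthetic two-cluster benchmark generator
#'
#' Defaults state the emulated study design: 11 samples split 7 + 4 into
#' two latent clusters, a few dozen TFs with a handful of planted
#' cluster-specific drivers per cluster, a few hundred genes, log-normal
#' peak intensities and motif instances planted inside 150 bp
#' summit-centred windows.
#'
#' @param n_samples number of samples (default 11).
#' @param n_tfs number of TFs (default 40).
#' @param n_genes number of non-TF genes (default 300).
#' @param n_driver_tfs planted driver TFs per cluster (default 4).
#' @param cluster_sizes sizes of the two clusters (default c(7, 4)).
#' @param effect_size standardized mean shift (in units of `noise_sd`) of
#'   driver-TF log2-expression between clusters (default 3).
#' @param noise_sd additive log2-expression noise SD (default 0.4).
#' @param edge_density probability a TF regulates a given gene (0.08).
#' @param beta slope linking a regulatee's log2-expression to its parent
#'   driver's standardized expression (default 1.2).
#' @param driver_target_fraction probability a gene is additionally wired
#'   to one planted driver (default 0.9).
#' @param motif_length planted motif length in bp (default 10).
#' @param motif_info probability of the consensus base at each PWM
#'   position, in \[0.25, 1\] (default 0.97).
#' @param peak_intensity_lognorm (meanlog, sdlog) of peak intensities
#'   (default c(1, 0.5)).
#' @param enhancer_fraction fraction of true edges mediated by a linked
#'   enhancer peak rather than the promoter peak (default 0.2).
#' @param driver_intensity_boost multiplier on intensities of peaks
#'   carrying a driver edge, applied in the driver's own cluster (2.5).
#' @param peak_width peak width in bp (default 300).
#' @param gene_spacing TSS spacing in bp (default 20000).
#' @param baseline_mean,baseline_sd per-gene baseline log2-expression
#'   distribution (defaults 5 and 1.5).
#' @param seed RNG seed; the dataset is a pure function of this config.
#' @return a validated `SimulationConfig` list.
#' @export
simulation_config <- function(n_samples = 11, n_tfs = 40, n_genes = 300,
                              n_driver_tfs = 4, cluster_sizes = c(7, 4),
                              effect_size = 3, noise_sd = 0.4,
                              edge_density = 0.08, beta = 1.2,
                              driver_target_fraction = 0.9,
                              motif_length = 10, motif_info = 0.97,
                              peak_intensity_lognorm = c(1, 0.5),
                              enhancer_fraction = 0.2,
                              driver_intensity_boost = 2.5,
                              peak_width = 300, gene_spacing = 20000,
                              baseline_mean = 5, baseline_sd = 1.5,
                              seed = 1) {
  cfg <- as.list(environment())
  assert_that(sum(cluster_sizes) == n_samples,
              "cluster sizes (%s) do not sum to n_samples (%d)",
              paste(cluster_sizes, collapse = "+"), n_samples)
  assert_that(length(cluster_sizes) == 2L, "exactly two clusters are planted")
  assert_that(effect_size >= 0, "effect_size must be >= 0")
  assert_that(edge_density > 0 && edge_density <= 1,
              "edge_density must be in (0, 1]")
  assert_that(motif_info >= 0.25 && motif_info <= 1,
              "motif_info must be in [0.25, 1]")
  assert_that(2 * n_driver_tfs <= n_tfs, "too many driver TFs")
  assert_that(motif_length >= 4, "motif_length must be >= 4")
  assert_that(noise_sd >= 0 && beta >= 0, "noise_sd and beta must be >= 0")
  structure(cfg, class = "SimulationConfig")
}

#' Simulate a coupled peak/motif/expression/link dataset with ground truth
#'
#' Generates, in one deterministic pass from `config$seed`:
#' gene annotation (TFs are genes too), one promoter peak per gene and one
#' linked enhancer peak per gene with enhancer-mediated edges, per-sample
#' log-normal peak intensities (boosted in a driver's own cluster for
#' peaks carrying driver edges), uniform-background peak sequences with
#' the TF consensus planted inside the 150 bp summit window of every true
#' edge's peak, motif PWMs with `motif_info` consensus dominance, and a
#' TPM matrix (columns sum to 1e6) in which driver-TF expression is
#' shifted between clusters by `effect_size * noise_sd` and each driver
#' regulatee's log2-expression is `baseline + beta * z(driver) + noise`.
#'
#' @param config a `SimulationConfig` from [simulation_config()].
#' @return list with `sequences`, `peaks` (named list of per-sample
#'   `PeakSet`s), `expression` (TPM matrix), `annotation`, `motifs`,
#'   `links` and `ground_truth` (true edges, clusters, drivers, planted
#'   motif positions, config).
#' @export
simulate_dataset <- function(config) {
  assert_that(inherits(config, "SimulationConfig"),
              "config must come from simulation_config()")
  set.seed(config$seed)
  samples <- sprintf("S%02d", seq_len(config$n_samples))
  cluster <- setNames(rep(1:2, config$cluster_sizes), samples)
  tfs <- sprintf("TF%02d", seq_len(config$n_tfs))
  genes <- sprintf("G%03d", seq_len(config$n_genes))
  all_genes <- c(tfs, genes)
  drivers <- list(`1` = tfs[seq_len(config$n_driver_tfs)],
                  `2` = tfs[config$n_driver_tfs + seq_len(config$n_driver_tfs)])

  # --- annotation: TSSs spaced widely so promoter windows never collide
  anno <- data.frame(gene_id = all_genes, chrom = "chr1",
                     tss = config$gene_spacing * seq_along(all_genes),
                     strand = sample(c("+", "-"), length(all_genes),
                                     replace = TRUE),
                     is_tf = all_genes %in% tfs, stringsAsFactors = FALSE)
  class(anno) <- c("GeneAnnotation", "data.frame")

  # --- motifs: random consensus with motif_info dominance
  motifs <- lapply(tfs, function(tf) {
    consensus <- sample(DNA_BASES, config$motif_length, replace = TRUE)
    pwm <- matrix((1 - config$motif_info) / 3, config$motif_length, 4,
                  dimnames = list(NULL, DNA_BASES))
    pwm[cbind(seq_along(consensus), match(consensus, DNA_BASES))] <-
      config$motif_info
    list(tf_name = tf, pwm = pwm, consensus = paste(consensus, collapse = ""))
  })
  names(motifs) <- tfs
  motif_lib <- structure(motifs,
                         background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                         class = "MotifLibrary")

  # --- true edge wiring
  rand_edges <- which(matrix(runif(config$n_tfs * length(all_genes)),
                             config$n_tfs) < config$edge_density,
                      arr.ind = TRUE)
  edges <- data.frame(tf = tfs[rand_edges[, 1]],
                      gene = all_genes[rand_edges[, 2]],
                      stringsAsFactors = FALSE)
  edges <- edges[edges$tf != edges$gene, , drop = FALSE]
  driver_all <- unlist(drivers, use.names = FALSE)
  # drivers regulate non-driver genes AND non-driver TFs (TF-TF edges are
  # central to the emulated networks); drivers never regulate each other
  targets <- setdiff(all_genes, driver_all)
  is_target <- runif(length(targets)) < config$driver_target_fraction
  driver_of <- setNames(rep(NA_character_, length(targets)), targets)
  driver_of[is_target] <- sample(driver_all, sum(is_target), replace = TRUE)
  for (d in driver_all) { # every driver must regulate something
    if (!any(driver_of == d, na.rm = TRUE)) {
      driver_of[sample(which(is.na(driver_of)), 1)] <- d
    }
  }
  drv_edges <- data.frame(tf = driver_of[!is.na(driver_of)],
                          gene = names(driver_of)[!is.na(driver_of)],
                          stringsAsFactors = FALSE)
  edges <- unique(rbind(edges, drv_edges))
  edges <- edges[order(edges$tf, edges$gene), , drop = FALSE]
  edges$evidence <- ifelse(runif(nrow(edges)) < config$enhancer_fraction,
                           "enhancer", "promoter")
  edges$peak_id <- ifelse(edges$evidence == "promoter",
                          paste0("p_", edges$gene), paste0("e_", edges$gene))

  # --- peaks: one promoter peak per gene; one enhancer peak per gene
  # that has >= 1 enhancer-mediated edge, on a gene-free contig
  half <- config$peak_width %/% 2L
  prom <- data.frame(chrom = "chr1", start = anno$tss - half,
                     end = anno$tss + (config$peak_width - half),
                     peak_id = paste0("p_", anno$gene_id),
                     strand = ".", summit = anno$tss,
                     stringsAsFactors = FALSE)
  enh_genes <- sort(unique(edges$gene[edges$evidence == "enhancer"]))
  enh <- if (length(enh_genes)) {
    pos <- config$gene_spacing * seq_along(enh_genes)
    data.frame(chrom = "chr_enh", start = pos,
               end = pos + config$peak_width,
               peak_id = paste0("e_", enh_genes), strand = ".",
               summit = pos + half, stringsAsFactors = FALSE)
  }
  peak_tab <- rbind(prom, enh)
  links <- data.frame(peak_id = paste0("e_", enh_genes), gene_id = enh_genes,
                      stringsAsFactors = FALSE)
  class(links) <- c("EnhancerLinkTable", "data.frame")

  # --- sequences: uniform background, then plant consensus sequences at
  # non-overlapping offsets inside each peak's 150 bp summit window
  seqs <- vapply(seq_len(nrow(peak_tab)), function(i) {
    paste(sample(DNA_BASES, peak_tab$end[i] - peak_tab$start[i],
                 replace = TRUE), collapse = "")
  }, "")
  names(seqs) <- peak_tab$peak_id
  win_lo <- pmax(peak_tab$summit - 75L, peak_tab$start) - peak_tab$start + 1L
  win_hi <- pmin(peak_tab$summit + 75L, peak_tab$end) - peak_tab$start
  names(win_lo) <- names(win_hi) <- peak_tab$peak_id
  occupied <- lapply(setNames(nm = peak_tab$peak_id), function(p) integer())
  planted <- vector("list", nrow(edges))
  L <- config$motif_length
  keep <- logical(nrow(edges))
  ord <- order(match(edges$tf, driver_all, nomatch = length(tfs) + 1L))
  for (i in ord) { # drivers plant first so they never lose a full window
    p <- edges$peak_id[i]
    cand <- setdiff(seq(win_lo[p], win_hi[p] - L + 1L), occupied[[p]])
    # an offset is free if none of its L positions collide with a plant
    free <- cand[vapply(cand, function(o) {
      !any(seq(o, o + L - 1L) %in% occupied[[p]])
    }, TRUE)]
    if (!length(free)) next # no room: edge not realized, not ground truth
    o <- if (length(free) == 1L) free else sample(free, 1)
    substr(seqs[p], o, o + L - 1L) <- motifs[[edges$tf[i]]]$consensus
    occupied[[p]] <- c(occupied[[p]], seq(o, o + L - 1L))
    keep[i] <- TRUE
    planted[[i]] <- data.frame(peak_id = p, tf = edges$tf[i],
                               offset_in_peak = o - 1L,
                               offset_in_window = o - win_lo[p],
                               stringsAsFactors = FALSE)
  }
  true_edges <- edges[keep, , drop = FALSE]
  rownames(true_edges) <- NULL
  planted <- do.call(rbind, planted[keep])
  rownames(planted) <- NULL

  # --- per-sample intensities (log-normal; driver peaks boosted in the
  # driver's own cluster)
  mlog <- config$peak_intensity_lognorm[1]
  slog <- config$peak_intensity_lognorm[2]
  drv_cluster <- setNames(rep(names(drivers), lengths(drivers)), driver_all)
  boost_cl <- lapply(c("1", "2"), function(cl) {
    unique(true_edges$peak_id[true_edges$tf %in% drivers[[cl]]])
  })
  names(boost_cl) <- c("1", "2")
  peaks <- lapply(samples, function(s) {
    intensity <- rlnorm(nrow(peak_tab), mlog, slog)
    names(intensity) <- peak_tab$peak_id
    bp <- boost_cl[[as.character(cluster[s])]]
    intensity[bp] <- intensity[bp] * config$driver_intensity_boost
    new_peakset(data.frame(chrom = peak_tab$chrom, start = peak_tab$start,
                           end = peak_tab$end, peak_id = peak_tab$peak_id,
                           intensity = as.vector(intensity),
                           strand = peak_tab$strand,
                           summit = peak_tab$summit,
                           stringsAsFactors = FALSE), s)
  })
  names(peaks) <- samples

  # --- expression: drivers first, then their regulatees
  baseline <- setNames(rnorm(length(all_genes), config$baseline_mean,
                             config$baseline_sd), all_genes)
  logx <- matrix(0, length(all_genes), length(samples),
                 dimnames = list(all_genes, samples))
  shift <- config$effect_size * config$noise_sd
  for (g in all_genes) {
    delta <- if (g %in% driver_all) {
      shift * (cluster[samples] == as.integer(drv_cluster[g]))
    } else 0
    logx[g, ] <- baseline[g] + delta +
      rnorm(length(samples), 0, config$noise_sd)
  }
  for (g in names(driver_of)[!is.na(driver_of)]) {
    d <- driver_of[g]
    zd <- as.vector(scale(logx[d, ]))
    logx[g, ] <- baseline[g] + config$beta * zd +
      rnorm(length(samples), 0, config$noise_sd)
  }
  tpm <- 2^logx
  tpm <- sweep(tpm, 2, colSums(tpm), `/`) * 1e6

  ground <- list(true_edges = true_edges,
                 true_clusters = cluster,
                 true_drivers = list(CL1 = drivers[["1"]], CL2 = drivers[["2"]]),
                 planted_positions = planted,
                 config = unclass(config))
  list(sequences = seqs, peaks = peaks, expression = tpm, annotation = anno,
       motifs = motif_lib, links = links, ground_truth = ground)
}

#' Fraction of planted edges recovered by a built network
#'
#' @param ground the `ground_truth` element of [simulate_dataset()] output.
#' @param net a `RegulatoryNetwork` built from the simulated data.
#' @return recall in \[0, 1\] for the network's sample; attribute
#'   `precision` reports the matching precision.
#' @export
realized_edge_recall <- function(ground, net) {
  assert_that(net$sample_id %in% names(ground$true_clusters),
              "sample '%s' absent from ground truth", net$sample_id)
  truth <- paste(ground$true_edges$tf, ground$true_edges$gene)
  assert_that(length(truth) > 0L, "ground truth has no edges")
  found <- paste(net$edges$parent_tf, net$edges$child_gene)
  recall <- mean(truth %in% found)
  attr(recall, "precision") <- if (length(found)) mean(found %in% truth) else NA_real_
  recall
}

#' Write a simulated dataset to disk in the pipeline's exchange formats
#'
#' Emits `annotation.tsv`, `expression.tsv`, `motifs.meme`, `links.tsv`,
#' `sequences.fa`, `peaks_<sample>.bed` and `ground_truth.json`.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  write_expression(sim$expression, file.path(dir, "expression.tsv"))
  write_motifs(sim$motifs, file.path(dir, "motifs.meme"))
  write_links(sim$links, file.path(dir, "links.tsv"))
  write_sequences(sim$sequences, file.path(dir, "sequences.fa"))
  for (s in names(sim$peaks)) {
    write_peaks(sim$peaks[[s]], file.path(dir, sprintf("peaks_%s.bed", s)))
  }
  gt <- sim$ground_truth
  gt$true_clusters <- as.list(gt$true_clusters)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a simulated dataset back from disk
#' @param dir directory written by [write_dataset()].
#' @return list shaped like [simulate_dataset()] output (ground truth
#'   included when present).
#' @export
read_dataset <- function(dir) {
  anno <- read_annotation(file.path(dir, "annotation.tsv"))
  expr <- read_expression(file.path(dir, "expression.tsv"))
  beds <- sort(list.files(dir, pattern = "^peaks_.*\\.bed$", full.names = TRUE))
  samples <- sub("^peaks_(.*)\\.bed$", "\\1", basename(beds))
  peaks <- Map(read_peaks, beds, samples)
  names(peaks) <- samples
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) {
    g <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    g$true_clusters <- unlist(g$true_clusters)
    g
  }
  list(sequences = read_sequences(file.path(dir, "sequences.fa")),
       peaks = peaks, expression = expr, annotation = anno,
       motifs = read_motifs(file.path(dir, "motifs.meme")),
       links = read_links(file.path(dir, "links.tsv")),
       ground_truth = gt)
}
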