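test_that("promoter windows are strand-aware, half-open, clipped at 0", {
  anno <- data.frame(gene_id = c("gp", "gm", "gc"), chrom = "chr1",
                     tss = c(10000, 10000, 2000), strand = c("+", "-", "+"),
                     is_tf = FALSE)
  w <- promoter_window(anno)
  expect_equal(unlist(w[w$gene_id == "gp", c("start", "end")]),
               c(start = 5000, end = 11000))
  expect_equal(unlist(w[w$gene_id == "gm", c("start", "end")]),
               c(start = 9000, end = 15000))
  expect_equal(unlist(w[w$gene_id == "gc", c("start", "end")]),
               c(start = 0, end = 3000))
})

test_that("classify_peaks partitions peaks into promoter/enhancer/dropped", {
  anno <- data.frame(gene_id = "geneX", chrom = "chr1", tss = 10000,
                     strand = "+", is_tf = FALSE)
  peaks <- pprnet:::new_peakset(data.frame(
    chrom = "chr1", start = c(4900, 50000, 80000),
    end = c(5100, 50300, 80300),
    peak_id = c("pProm", "pLinked", "pLost"),
    intensity = 1, strand = ".",
    summit = c(5000, 50150, 80150), stringsAsFactors = FALSE), "s1")
  links <- data.frame(peak_id = c("pLinked", "pProm"), gene_id = "geneX")
  cls <- classify_peaks(peaks, anno, links)
  # 100 bp overlap with [5000, 11000) makes pProm a promoter peak
  expect_equal(cls$promoter$peak_id, "pProm")
  expect_equal(cls$promoter$gene_id, "geneX")
  expect_equal(cls$enhancer$peak_id, "pLinked")
  expect_equal(cls$dropped, "pLost")
  # the link aimed at a promoter-classified peak is ignored, not reused
  expect_equal(cls$ignored_links$peak_id, "pProm")
  # partition: each peak in exactly one bucket
  buckets <- c(unique(cls$promoter$peak_id), unique(cls$enhancer$peak_id),
               cls$dropped)
  expect_setequal(buckets, peaks$peak_id)
  expect_equal(anyDuplicated(buckets), 0L)
})

test_that("a single planted hit produces one promoter edge", {
  set.seed(21)
  anno <- data.frame(gene_id = c("TF_A", "gene_B"), chrom = "chr1",
                     tss = c(10000, 50000), strand = "+",
                     is_tf = c(TRUE, FALSE))
  seqB <- random_dna(300)
  substr(seqB, 140, 149) <- "ACGTACGTAC"
  seqs <- c(pA = random_dna(300), pB = seqB)
  peaks <- pprnet:::new_peakset(data.frame(
    chrom = "chr1", start = c(9850, 49850), end = c(10150, 50150),
    peak_id = c("pA", "pB"), intensity = c(1, 2), strand = ".",
    summit = c(10000, 50000), stringsAsFactors = FALSE), "s1")
  motifs <- structure(list(TF_A = list(tf_name = "TF_A",
                                       pwm = consensus_pwm("ACGTACGTAC"))),
                      background = c(A = .25, C = .25, G = .25, T = .25),
                      class = "MotifLibrary")
  expr <- matrix(c(10, 12, 5, 6), 2, 2,
                 dimnames = list(c("TF_A", "gene_B"), c("s1", "s2")))
  links <- data.frame(peak_id = character(), gene_id = character())
  net <- build_network("s1", peaks, seqs, anno, motifs, links, expr,
                       background = rep(0.25, 4))
  e <- net$edges[net$edges$child_gene == "gene_B", ]
  expect_equal(nrow(e), 1L)
  expect_equal(e$parent_tf, "TF_A")
  expect_equal(e$evidence, "promoter")
  expect_equal(e$peak_id, "pB")
  expect_equal(e$motif_frac, 1, tolerance = 1e-12)
})

test_that("promoter and enhancer support for one pair aggregate to one edge", {
  set.seed(22)
  anno <- data.frame(gene_id = c("TF_A", "gene_B"), chrom = "chr1",
                     tss = c(10000, 50000), strand = "+",
                     is_tf = c(TRUE, FALSE))
  # plant a perfect site in the promoter peak and a weaker (one-mismatch)
  # site in the linked enhancer peak
  seqProm <- random_dna(300); substr(seqProm, 140, 149) <- "ACGTACGTAC"
  seqEnh <- random_dna(300); substr(seqEnh, 140, 149) <- "ACGTACGTAT"
  seqs <- c(pA = random_dna(300), pProm = seqProm, pEnh = seqEnh)
  peaks <- pprnet:::new_peakset(data.frame(
    chrom = "chr1", start = c(9850, 49850, 200000),
    end = c(10150, 50150, 200300),
    peak_id = c("pA", "pProm", "pEnh"), intensity = c(1, 2, 9), strand = ".",
    summit = c(10000, 50000, 200150), stringsAsFactors = FALSE), "s1")
  motifs <- structure(list(TF_A = list(tf_name = "TF_A",
                                       pwm = consensus_pwm("ACGTACGTAC"))),
                      background = c(A = .25, C = .25, G = .25, T = .25),
                      class = "MotifLibrary")
  expr <- matrix(c(10, 12, 5, 6), 2, 2,
                 dimnames = list(c("TF_A", "gene_B"), c("s1", "s2")))
  links <- data.frame(peak_id = "pEnh", gene_id = "gene_B")
  net <- build_network("s1", peaks, seqs, anno, motifs, links, expr,
                       background = rep(0.25, 4))
  e <- net$edges[net$edges$child_gene == "gene_B", ]
  expect_equal(nrow(e), 1L) # aggregated
  expect_equal(e$evidence, "promoter") # max-score evidence wins
  expect_equal(e$peak_id, "pProm")
  expect_equal(e$intensity, 9) # max supporting intensity (enhancer peak)
})

test_that("edge count is monotone in the motif p-value threshold", {
  sim <- small_sim()
  s <- names(sim$peaks)[1]
  counts <- vapply(c(1e-5, 1e-4, 1e-3), function(th) {
    nrow(build_network(s, sim$peaks[[s]], sim$sequences, sim$annotation,
                       sim$motifs, sim$links, sim$expression,
                       p_threshold = th)$edges)
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("build is deterministic and recovers planted edges (recall >= 0.9)", {
  sim <- default_sim()
  s <- names(sim$peaks)[1]
  net <- build_network(s, sim$peaks[[s]], sim$sequences, sim$annotation,
                       sim$motifs, sim$links, sim$expression)
  net2 <- build_network(s, sim$peaks[[s]], sim$sequences, sim$annotation,
                        sim$motifs, sim$links, sim$expression)
  expect_identical(net$edges, net2$edges)
  rec <- realized_edge_recall(sim$ground_truth, net)
  expect_gte(as.numeric(rec), 0.9)
  expect_true(attr(rec, "precision") > 0.5) # reported, sanity-bounded
})

test_that("build_networks equals per-sample builds on a shared atlas", {
  sim <- small_sim()
  nets <- build_networks(sim$peaks, sim$sequences, sim$annotation,
                         sim$motifs, sim$links, sim$expression)
  s <- names(sim$peaks)[2]
  single <- build_network(s, sim$peaks[[s]], sim$sequences, sim$annotation,
                          sim$motifs, sim$links, sim$expression)
  expect_identical(nets[[s]]$edges, single$edges)
  expect_identical(nets[[s]]$node_z, single$node_z)
})
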