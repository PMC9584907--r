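# Shared fixtures. Simulations are memoized per test run; everything is
# generated in code (no stored data files).

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# default-world simulation (the stated 11-sample, 7+4 design)
default_sim <- function(seed = 101) {
  memo(paste0("sim", seed), simulate_dataset(simulation_config(seed = seed)))
}

# a small, fast world for module-level tests
small_config <- function(seed = 7, ...) {
  simulation_config(n_samples = 7, cluster_sizes = c(4, 3), n_tfs = 12,
                    n_genes = 80, n_driver_tfs = 2, seed = seed, ...)
}

small_sim <- function(seed = 7) {
  memo(paste0("small", seed), simulate_dataset(small_config(seed)))
}

# frozen small fixture for end-to-end pipeline runs (seed chosen once;
# the run is deterministic, so reruns are byte-identical by construction)
pipeline_fixture_cfg <- function(outdir, seed = 11) {
  pipeline_config(list(
    outdir = outdir, seed = seed,
    simulate = list(n_samples = 7, cluster_sizes = c(4, 3), n_tfs = 15,
                    n_genes = 120, n_driver_tfs = 2),
    validate = list(n_top = 120, folds = 10, trees = 40)))
}

# networks -> weighted networks -> PPR matrix for a simulation
run_ppr_pipeline <- function(sim) {
  nets <- build_networks(sim$peaks, sim$sequences, sim$annotation,
                         sim$motifs, sim$links, sim$expression)
  wnets <- lapply(names(nets), function(s)
    edge_weights(nets[[s]], sim$expression, sim$peaks[[s]]))
  names(wnets) <- names(nets)
  scores <- lapply(wnets, personalized_pagerank)
  nets_w <- lapply(names(nets), function(s) {
    n <- nets[[s]]
    n$edges <- wnets[[s]]$edges
    n
  })
  names(nets_w) <- names(nets)
  ppr <- ppr_matrix(scores, vapply(sim$motifs, `[[`, "", "tf_name"))
  list(nets = nets, nets_w = nets_w, wnets = wnets, ppr = ppr)
}

default_pipeline <- function(seed = 101) {
  memo(paste0("pipe", seed), run_ppr_pipeline(default_sim(seed)))
}

small_pipeline <- function(seed = 7) {
  memo(paste0("smallpipe", seed), run_ppr_pipeline(small_sim(seed)))
}

# PWM with a given consensus string and dominance
consensus_pwm <- function(consensus, info = 0.97) {
  b <- strsplit(consensus, "")[[1]]
  pwm <- matrix((1 - info) / 3, length(b), 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  pwm[cbind(seq_along(b), match(b, c("A", "C", "G", "T")))] <- info
  pwm
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a hand-built regulatory network from an edge table
toy_network <- function(sample_id, edges, nodes = NULL) {
  df <- data.frame(parent_tf = edges$parent_tf, child_gene = edges$child_gene,
                   weight = edges$weight %||% rep(1, nrow(edges)),
                   evidence = edges$evidence %||% rep("promoter", nrow(edges)),
                   peak_id = edges$peak_id %||% sprintf("p%d", seq_len(nrow(edges))),
                   motif_score = edges$motif_score %||% rep(5, nrow(edges)),
                   motif_frac = edges$motif_frac %||% rep(1, nrow(edges)),
                   intensity = edges$intensity %||% rep(1, nrow(edges)),
                   stringsAsFactors = FALSE)
  pprnet:::new_network(sample_id, df,
                       nodes %||% sort(unique(c(df$parent_tf, df$child_gene))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random weighted network in the walk representation, for PPR oracles
random_weighted_network <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- sprintf("n%03d", seq_len(n_nodes))
  from <- sample(n_nodes, n_edges, replace = TRUE)
  to <- sample(n_nodes, n_edges, replace = TRUE)
  w <- runif(n_edges, 0.1, 2)
  W <- matrix(0, n_nodes, n_nodes, dimnames = list(nodes, nodes))
  for (i in seq_len(n_edges)) W[to[i], from[i]] <- W[to[i], from[i]] + w[i]
  cs <- colSums(W)
  dangling <- cs == 0
  W[, !dangling] <- sweep(W[, !dangling, drop = FALSE], 2, cs[!dangling], `/`)
  s <- runif(n_nodes, 0.05, 1)
  s <- s / sum(s)
  names(s) <- nodes
  structure(list(sample_id = "toy", nodes = nodes, seed = s, W = W,
                 dangling = dangling, edges = NULL),
            class = "WeightedNetwork")
}

# dense linear-solver oracle for Personalized PageRank
ppr_direct_solve <- function(wnet, damping) {
  n <- length(wnet$nodes)
  Weff <- wnet$W
  if (any(wnet$dangling)) {
    Weff[, wnet$dangling] <- Weff[, wnet$dangling, drop = FALSE] + wnet$seed
  }
  v <- solve(diag(n) - damping * Weff, (1 - damping) * wnet$seed)
  setNames(as.vector(v), wnet$nodes)
}
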