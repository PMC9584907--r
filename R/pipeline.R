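default_pipeline_config <- function() {
  list(
    outdir = "pprnet_run",
    data_dir = NULL,          # set after `simulate`, or point at real inputs
    gmt = NULL,               # optional gene-set collection for `enrich`
    seed = 1,
    simulate = list(),        # overrides for simulation_config()
    network = list(p_threshold = 1e-4, scan_window = 150,
                   upstream = 5000, downstream = 1000,
                   log2_expression = TRUE),
    pagerank = list(damping = 0.85, tol = 1e-8, max_iter = 1000),
    stratify = list(n_top = 350, expressed_min_tpm = 1, k = 2),
    difftf = list(n_candidates = 200, n_shortlist = 100, alpha = 0.05,
                  q_alpha = 0.05, variance_kept = 0.90, fold_min = 2,
                  presence_min = 0.75, weight_ratio_min = 1.5),
    validate = list(n_top = 500, floor = 1e-2, folds = 10, trees = 100)
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list) and merges it over the defaults.
#' Parameter ranges are validated up front, before any compute.
#'
#' @param config path to a YAML file, a list of overrides, or NULL for
#'   the defaults.
#' @return a validated `PipelineConfig` list.
#' @export
pipeline_config <- function(config = NULL) {
  cfg <- default_pipeline_config()
  user <- if (is.character(config)) {
    assert_that(file.exists(config), "config file not found: %s", config)
    yaml::read_yaml(config)
  } else config %||% list()
  for (k in names(user)) {
    cfg[[k]] <- if (is.list(user[[k]]) && is.list(cfg[[k]])) {
      utils::modifyList(cfg[[k]], user[[k]])
    } else user[[k]]
  }
  assert_that(cfg$pagerank$damping >= 0 && cfg$pagerank$damping < 1,
              "config error: pagerank damping %.3g outside [0, 1)",
              cfg$pagerank$damping)
  assert_that(cfg$pagerank$tol > 0, "config error: pagerank tol must be > 0")
  assert_that(cfg$network$p_threshold > 0 && cfg$network$p_threshold <= 1,
              "config error: motif p_threshold outside (0, 1]")
  assert_that(cfg$stratify$k >= 1, "config error: k must be >= 1")
  assert_that(cfg$difftf$alpha > 0 && cfg$difftf$alpha <= 1 &&
                cfg$difftf$q_alpha > 0 && cfg$difftf$q_alpha <= 1,
              "config error: alpha/q_alpha outside (0, 1]")
  assert_that(cfg$validate$folds >= 2, "config error: folds must be >= 2")
  structure(cfg, class = "PipelineConfig")
}

stage_manifest <- function(outdir, stage, params, inputs = character()) {
  manifest <- list(stage = stage,
                   package = "pprnet",
                   version = as.character(utils::packageVersion("pprnet")),
                   parameters = params,
                   inputs = as.list(setNames(unname(tools::md5sum(inputs)),
                                             basename(inputs))))
  jsonlite::write_json(manifest,
                       file.path(outdir, sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

artifact <- function(cfg, ...) file.path(cfg$outdir, ...)

need_artifact <- function(path, producer) {
  assert_that(file.exists(path),
              "missing artifact '%s': run the '%s' stage first", path, producer)
  path
}

#' Run pipeline stages
#'
#' Subcommands: `simulate` (write a synthetic dataset), `build-network`
#' (one network TSV per sample), `pagerank` (weighted networks + PageRank
#' matrices), `stratify` (cluster assignment, Newick tree, silhouettes),
#' `difftf` (ranked TF table, DEGs, TF-TF subnetworks), `validate`
#' (topology validation report), `enrich` (gene-set over-representation
#' for the selected TFs' regulated DEGs; needs `gmt` in the config) and
#' `all` (the full chain). Each stage writes its artifacts plus a JSON
#' manifest (package version, parameters, input checksums) into
#' `config$outdir`; reruns with identical config and inputs are
#' byte-identical.
#'
#' @param subcommand one of simulate, build-network, pagerank, stratify,
#'   difftf, validate, enrich, all.
#' @param config a `PipelineConfig`, a YAML path, a list of overrides, or
#'   NULL for defaults.
#' @return invisibly, a list of the stage's main in-memory results.
#' @export
run_pipeline <- function(subcommand, config = NULL) {
  cfg <- if (inherits(config, "PipelineConfig")) config else pipeline_config(config)
  stages <- c("simulate", "build-network", "pagerank", "stratify", "difftf",
              "validate", "enrich", "all")
  assert_that(subcommand %in% stages, "unknown subcommand '%s' (expected one of %s)",
              subcommand, paste(stages, collapse = ", "))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  if (subcommand == "all") {
    out <- list()
    chain <- c("build-network", "pagerank", "stratify", "difftf", "validate")
    # simulate only when the config does not point at existing inputs
    if (is.null(cfg$data_dir) || !dir.exists(cfg$data_dir)) {
      chain <- c("simulate", chain)
    }
    if (!is.null(cfg$gmt)) chain <- c(chain, "enrich")
    for (s in chain) out[[s]] <- run_pipeline(s, cfg)
    return(invisible(out))
  }
  switch(subcommand,
         "simulate" = stage_simulate(cfg),
         "build-network" = stage_build_network(cfg),
         "pagerank" = stage_pagerank(cfg),
         "stratify" = stage_stratify(cfg),
         "difftf" = stage_difftf(cfg),
         "validate" = stage_validate(cfg),
         "enrich" = stage_enrich(cfg))
}

data_dir_of <- function(cfg) cfg$data_dir %||% artifact(cfg, "data")

stage_simulate <- function(cfg) {
  sim_cfg <- do.call(simulation_config,
                     utils::modifyList(list(seed = cfg$seed), cfg$simulate))
  sim <- simulate_dataset(sim_cfg)
  dir <- data_dir_of(cfg)
  write_dataset(sim, dir)
  stage_manifest(cfg$outdir, "simulate", unclass(sim_cfg))
  invisible(sim)
}

load_inputs <- function(cfg) {
  dir <- data_dir_of(cfg)
  assert_that(dir.exists(dir),
              "missing input directory '%s': run the 'simulate' stage or set data_dir",
              dir)
  read_dataset(dir)
}

stage_build_network <- function(cfg) {
  inp <- load_inputs(cfg)
  ndir <- artifact(cfg, "networks")
  dir.create(ndir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg$network
  nets <- lapply(names(inp$peaks), function(s) {
    net <- build_network(s, inp$peaks[[s]], inp$sequences, inp$annotation,
                         inp$motifs, inp$links, inp$expression,
                         p_threshold = p$p_threshold,
                         scan_window = p$scan_window,
                         upstream = p$upstream, downstream = p$downstream,
                         log2_expression = p$log2_expression)
    write_network(net, file.path(ndir, sprintf("%s.tsv", s)))
    net
  })
  names(nets) <- names(inp$peaks)
  reports <- lapply(nets, `[[`, "report")
  jsonlite::write_json(reports, artifact(cfg, "build_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_manifest(cfg$outdir, "build-network", p,
                 list.files(data_dir_of(cfg), full.names = TRUE))
  invisible(nets)
}

load_networks <- function(cfg, weighted = FALSE) {
  ndir <- artifact(cfg, if (weighted) "networks_weighted" else "networks")
  need_artifact(ndir, if (weighted) "pagerank" else "build-network")
  files <- sort(list.files(ndir, pattern = "\\.tsv$", full.names = TRUE))
  assert_that(length(files) > 0L,
              "no network TSVs under '%s': run the '%s' stage first", ndir,
              if (weighted) "pagerank" else "build-network")
  nets <- lapply(files, read_network)
  names(nets) <- vapply(nets, `[[`, "", "sample_id")
  nets
}

write_matrix_tsv <- function(mat, path, id_col) {
  header <- paste(c(id_col, colnames(mat)), collapse = "\t")
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], fmt_num(mat[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
}

stage_pagerank <- function(cfg) {
  inp <- load_inputs(cfg)
  nets <- load_networks(cfg)
  p <- cfg$pagerank
  wdir <- artifact(cfg, "networks_weighted")
  dir.create(wdir, showWarnings = FALSE, recursive = TRUE)
  node_universe <- sort(unique(c(inp$annotation$gene_id,
                                 names(inp$motifs))))
  conv <- list()
  scores <- lapply(names(nets), function(s) {
    net <- nets[[s]]
    net$nodes <- node_universe
    wnet <- edge_weights(net, inp$expression, peaks = inp$peaks[[s]],
                         log2_expression = cfg$network$log2_expression)
    v <- personalized_pagerank(wnet, damping = p$damping, tol = p$tol,
                               max_iter = p$max_iter)
    conv[[s]] <<- attr(v, "iterations")
    wn <- net
    wn$edges <- wnet$edges
    write_network(wn, file.path(wdir, sprintf("%s.tsv", s)))
    v
  })
  names(scores) <- names(nets)
  tf_names <- vapply(inp$motifs, `[[`, "", "tf_name")
  ppr <- ppr_matrix(scores, tf_names)
  write_matrix_tsv(ppr$raw, artifact(cfg, "ppr_raw.tsv"), "node")
  write_matrix_tsv(ppr$z, artifact(cfg, "ppr_z.tsv"), "node")
  jsonlite::write_json(conv, artifact(cfg, "pagerank_convergence.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  stage_manifest(cfg$outdir, "pagerank", p)
  invisible(ppr)
}

load_ppr <- function(cfg) {
  raw_p <- need_artifact(artifact(cfg, "ppr_raw.tsv"), "pagerank")
  z_p <- need_artifact(artifact(cfg, "ppr_z.tsv"), "pagerank")
  read_mat <- function(path) {
    df <- read_tsv_strict(path, "node")
    m <- vapply(df[-1], function(col) as_num_col(col, "score", path),
                numeric(nrow(df)))
    matrix(m, nrow = nrow(df), dimnames = list(df$node, names(df)[-1]))
  }
  inp <- load_inputs(cfg)
  tf_names <- vapply(inp$motifs, `[[`, "", "tf_name")
  raw <- read_mat(raw_p)
  structure(list(raw = raw, z = read_mat(z_p),
                 tfs = intersect(tf_names, rownames(raw))),
            class = "PPRMatrix")
}

stage_stratify <- function(cfg) {
  inp <- load_inputs(cfg)
  ppr <- load_ppr(cfg)
  p <- cfg$stratify
  sel <- select_variable_tfs(ppr, inp$expression, n_top = p$n_top,
                             expressed_min_tpm = p$expressed_min_tpm)
  assignment <- cluster_samples(ppr$z[sel, , drop = FALSE], k = p$k)
  sil <- silhouette_report(assignment, ppr$z[sel, , drop = FALSE])
  out <- data.frame(sample = names(assignment$labels),
                    cluster = unname(assignment$labels),
                    stringsAsFactors = FALSE)
  write.table(out, artifact(cfg, "clusters.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ape::write.tree(ape::as.phylo(assignment$tree), artifact(cfg, "tree.nwk"))
  write.table(sil, artifact(cfg, "silhouette.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(sel, artifact(cfg, "selected_tfs.txt"))
  stage_manifest(cfg$outdir, "stratify", p)
  invisible(assignment)
}

load_assignment <- function(cfg) {
  path <- need_artifact(artifact(cfg, "clusters.tsv"), "stratify")
  df <- read_tsv_strict(path, c("sample", "cluster"))
  labels <- setNames(df$cluster, df$sample)
  structure(list(labels = labels, k = length(unique(labels)), tree = NULL,
                 selected_tfs = NULL, params = NULL),
            class = "ClusterAssignment")
}

stage_difftf <- function(cfg) {
  inp <- load_inputs(cfg)
  ppr <- load_ppr(cfg)
  assignment <- load_assignment(cfg)
  nets <- load_networks(cfg, weighted = TRUE)
  p <- cfg$difftf
  ranking <- rank_cluster_tfs(ppr, assignment, nets,
                              n_candidates = p$n_candidates,
                              n_shortlist = p$n_shortlist, alpha = p$alpha,
                              q_alpha = p$q_alpha,
                              variance_kept = p$variance_kept)
  degs <- compute_degs(inp$expression, assignment, fold_min = p$fold_min,
                       alpha = p$alpha)
  cover <- regulated_fraction(attr(ranking, "selected"), degs, nets)
  tf_names <- vapply(inp$motifs, `[[`, "", "tf_name")
  subnets <- do.call(rbind, lapply(c("CL1", "CL2"), function(cl) {
    tf_tf_subnetwork(nets, assignment, cl, tfs = tf_names,
                     presence_min = p$presence_min,
                     weight_ratio_min = p$weight_ratio_min)
  }))
  num_cols <- function(df) {
    for (k in names(df)) if (is.numeric(df[[k]])) df[[k]] <- fmt_num(df[[k]])
    df
  }
  write.table(num_cols(ranking), artifact(cfg, "tf_ranking.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(num_cols(degs), artifact(cfg, "degs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(num_cols(subnets), artifact(cfg, "tf_subnetwork.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cover[c("fraction", "n_regulated", "n_deg")],
                       artifact(cfg, "deg_coverage.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  stage_manifest(cfg$outdir, "difftf", p)
  invisible(list(ranking = ranking, degs = degs, coverage = cover,
                 subnetwork = subnets))
}

stage_validate <- function(cfg) {
  inp <- load_inputs(cfg)
  nets <- load_networks(cfg)
  p <- cfg$validate
  design <- validation_design(n_top = p$n_top, floor = p$floor,
                              folds = p$folds, trees = p$trees,
                              seed = cfg$seed)
  fm <- build_feature_matrix(nets, inp$expression, design)
  rep_true <- crossval_rf(fm$X, fm$y, design)
  rep_shuf <- shuffled_baseline(fm$X, fm$y, design)
  report <- list(n_rows = rep_true$n_rows, n_features = rep_true$n_features,
                 mean_r = rep_true$mean_r, fold_r = rep_true$fold_r,
                 shuffled_mean_r = rep_shuf$mean_r,
                 shuffled_fold_r = rep_shuf$fold_r)
  jsonlite::write_json(report, artifact(cfg, "validation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_manifest(cfg$outdir, "validate", p)
  invisible(list(true = rep_true, shuffled = rep_shuf))
}

stage_enrich <- function(cfg) {
  assert_that(!is.null(cfg$gmt), "config error: 'gmt' path needed for enrich")
  inp <- load_inputs(cfg)
  nets <- load_networks(cfg, weighted = TRUE)
  ranking_path <- need_artifact(artifact(cfg, "tf_ranking.tsv"), "difftf")
  ranking <- read_tsv_strict(ranking_path, c("tf", "selected"))
  selected <- ranking$tf[ranking$selected == "TRUE"]
  collection <- read_gmt(cfg$gmt)
  universe <- rownames(inp$expression)
  regs <- unique(unlist(lapply(selected, regulatee_union, networks = nets)))
  regs <- intersect(regs, universe)
  assert_that(length(regs) > 0L, "selected TFs regulate no genes in the universe")
  enr <- hypergeom_enrichment(regs, collection, universe)
  enr$p <- fmt_num(enr$p); enr$q <- fmt_num(enr$q)
  write.table(enr, artifact(cfg, "enrichment.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  stage_manifest(cfg$outdir, "enrich", list(gmt = cfg$gmt))
  invisible(enr)
}
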