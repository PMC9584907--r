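NETWORK_COLS <- c("sample", "parent_tf", "child_gene", "weight", "evidence",
                  "peak_id", "motif_score", "motif_frac", "intensity")

new_network <- function(sample_id, edges, nodes, node_z = NULL, report = NULL) {
  structure(list(sample_id = sample_id, edges = edges, nodes = nodes,
                 node_z = node_z, report = report),
            class = "RegulatoryNetwork")
}

empty_edges_df <- function() {
  data.frame(parent_tf = character(), child_gene = character(),
             weight = numeric(), evidence = character(),
             peak_id = character(), motif_score = numeric(),
             motif_frac = numeric(), intensity = numeric(),
             stringsAsFactors = FALSE)
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  cat(sprintf("RegulatoryNetwork '%s': %d nodes, %d edges (%d promoter, %d enhancer)\n",
              x$sample_id, length(x$nodes), nrow(x$edges),
              sum(x$edges$evidence == "promoter"),
              sum(x$edges$evidence == "enhancer")))
  invisible(x)
}

#' Write a regulatory network as a TSV edge list
#'
#' Columns: sample, parent_tf, child_gene, weight, evidence
#' (promoter|enhancer), peak_id, motif_score (bits), motif_frac (score over
#' the PWM's maximum achievable score) and intensity (supporting peak).
#' Doubles are written so the round-trip is bit-exact.
#'
#' @param net a `RegulatoryNetwork`.
#' @param path output TSV.
#' @export
write_network <- function(net, path) {
  e <- net$edges
  header <- paste(NETWORK_COLS, collapse = "\t")
  if (nrow(e) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  body <- paste(net$sample_id, e$parent_tf, e$child_gene, fmt_num(e$weight),
                e$evidence, e$peak_id, fmt_num(e$motif_score),
                fmt_num(e$motif_frac), fmt_num(e$intensity), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a regulatory network from a TSV edge list
#'
#' @param path TSV written by [write_network()].
#' @param nodes optional node universe (defaults to the edge endpoints).
#' @return a `RegulatoryNetwork`.
#' @export
read_network <- function(path, nodes = NULL) {
  df <- read_tsv_strict(path, NETWORK_COLS)
  if (nrow(df) == 0L) {
    return(new_network(NA_character_, empty_edges_df(), nodes %||% character()))
  }
  sample_id <- unique(df$sample)
  assert_that(length(sample_id) == 1L,
              "%s: edge list mixes samples: %s", path,
              paste(sample_id, collapse = ", "))
  bad <- which(!df$evidence %in% c("promoter", "enhancer"))
  assert_that(length(bad) == 0L, "%s: row %d: unknown evidence tag '%s'", path,
              if (length(bad)) bad[1] else 0L,
              if (length(bad)) df$evidence[bad[1]] else "")
  num <- function(col) {
    v <- as_num_col(df[[col]], col, path)
    assert_that(all(is.finite(v)), "%s: non-finite %s", path, col)
    v
  }
  edges <- data.frame(parent_tf = df$parent_tf, child_gene = df$child_gene,
                      weight = num("weight"), evidence = df$evidence,
                      peak_id = df$peak_id, motif_score = num("motif_score"),
                      motif_frac = num("motif_frac"),
                      intensity = num("intensity"), stringsAsFactors = FALSE)
  key <- paste(edges$parent_tf, edges$child_gene)
  assert_that(!anyDuplicated(key), "%s: duplicated edge %s", path,
              key[duplicated(key)][1])
  new_network(sample_id, edges,
              nodes %||% sort(unique(c(edges$parent_tf, edges$child_gene))))
}
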