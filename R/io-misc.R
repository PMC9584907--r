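#' Read gene annotation (TSS table)
#'
#' TSV with columns `gene_id chrom tss strand is_tf`. `tss` is a 0-based
#' coordinate; `strand` must be `+` or `-`; `is_tf` marks transcription
#' factors (TRUE/FALSE or 1/0).
#'
#' @param path TSV file.
#' @return a `GeneAnnotation` data.frame.
#' @export
read_annotation <- function(path) {
  df <- read_tsv_strict(path, c("gene_id", "chrom", "tss", "strand", "is_tf"))
  assert_that(!anyDuplicated(df$gene_id), "%s: duplicated gene_id '%s'", path,
              df$gene_id[duplicated(df$gene_id)][1])
  df$tss <- as_num_col(df$tss, "tss", path)
  assert_that(all(df$tss >= 0), "%s: negative TSS coordinate", path)
  bad <- which(!df$strand %in% c("+", "-"))
  assert_that(length(bad) == 0L, "%s: invalid strand '%s' for gene %s", path,
              if (length(bad)) df$strand[bad[1]] else "",
              if (length(bad)) df$gene_id[bad[1]] else "")
  df$is_tf <- df$is_tf %in% c("TRUE", "1", "T", "true")
  class(df) <- c("GeneAnnotation", "data.frame")
  df
}

#' Write gene annotation
#' @param anno a `GeneAnnotation` data.frame.
#' @param path output TSV.
#' @export
write_annotation <- function(anno, path) {
  out <- data.frame(gene_id = anno$gene_id, chrom = anno$chrom,
                    tss = as.integer(anno$tss), strand = anno$strand,
                    is_tf = anno$is_tf)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an enhancer-promoter link table
#'
#' TSV with columns `peak_id gene_id`: precomputed enhancer-to-gene
#' assignments (stand-in for chromatin-interaction predictions). Ids are
#' resolved against the PeakSet / GeneAnnotation at use time, not here.
#'
#' @param path TSV file.
#' @return an `EnhancerLinkTable` data.frame of unique (peak_id, gene_id) pairs.
#' @export
read_links <- function(path) {
  df <- read_tsv_strict(path, c("peak_id", "gene_id"))
  df <- unique(df[c("peak_id", "gene_id")])
  rownames(df) <- NULL
  class(df) <- c("EnhancerLinkTable", "data.frame")
  df
}

#' Write an enhancer-promoter link table
#' @param links data.frame with `peak_id`, `gene_id`.
#' @param path output TSV.
#' @export
write_links <- function(links, path) {
  write.table(links[c("peak_id", "gene_id")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#' @param path GMT file (set name, description, then member genes, tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  assert_that(length(bad) == 0L, "%s: line %d has fewer than 3 fields", path,
              if (length(bad)) bad[1] else 0L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  assert_that(!anyDuplicated(names(sets)), "%s: duplicated set name", path)
  sets
}

#' Read peak sequences from FASTA
#' @param path FASTA file with one record per peak, named by peak_id.
#' @return named character vector of uppercase DNA sequences.
#' @export
read_sequences <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  x <- Biostrings::readDNAStringSet(path)
  id <- sub("\\s.*$", "", names(x))
  assert_that(!anyDuplicated(id), "%s: duplicated sequence id", path)
  setNames(toupper(as.character(x)), id)
}

#' Write peak sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output FASTA.
#' @param width line-wrap width (default 70).
#' @export
write_sequences <- function(seqs, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = width)
  invisible(path)
}
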