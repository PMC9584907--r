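#' Read a TPM expression matrix
#'
#' TSV with a `gene_id` column followed by one numeric column per sample.
#' Duplicate gene ids, negative or non-numeric values are rejected.
#'
#' @param path TSV file.
#' @return numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_expression <- function(path) {
  df <- read_tsv_strict(path, "gene_id")
  assert_that(ncol(df) >= 2L, "%s: expression matrix needs >=1 sample column", path)
  assert_that(!anyDuplicated(df$gene_id), "%s: duplicated gene_id '%s'", path,
              df$gene_id[duplicated(df$gene_id)][1])
  mat <- vapply(df[-1], as_num_col, numeric(nrow(df)),
                what = "expression value", path = path)
  mat <- matrix(mat, nrow = nrow(df),
                dimnames = list(df$gene_id, names(df)[-1]))
  assert_that(all(is.finite(mat)), "%s: non-finite expression values", path)
  assert_that(all(mat >= 0), "%s: negative TPM values", path)
  mat
}

#' Write a TPM expression matrix
#' @param mat genes x samples numeric matrix with dimnames.
#' @param path output TSV.
#' @export
write_expression <- function(mat, path) {
  header <- paste(c("gene_id", colnames(mat)), collapse = "\t")
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], fmt_num(mat[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Per-gene cross-sample expression z-scores
#'
#' z-scores each gene across samples, by default on the `log2(TPM + 1)`
#' scale (set `log2 = FALSE` for raw-TPM z-scores). The sample standard
#' deviation (n - 1 denominator) is used; genes with zero variance get
#' z = 0 in every sample, so that their Personalized PageRank node weight
#' `exp(z)` is 1.
#'
#' @param tpm genes x samples matrix of TPM.
#' @param log2 transform to log2(TPM + 1) first (default TRUE).
#' @return matrix of the same shape: per-gene z-scores.
#' @export
expression_zscores <- function(tpm, log2 = TRUE) {
  assert_that(ncol(tpm) >= 2L, "z-scores need >=2 samples")
  x <- if (log2) base::log2(tpm + 1) else tpm
  mu <- rowMeans(x)
  sdv <- apply(x, 1, sd)
  z <- (x - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z
}
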