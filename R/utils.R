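`%||%` <- function(a, b) if (is.null(a)) b else a

# Format doubles so that as.numeric() recovers the identical bit pattern.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

stop_pprnet <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_pprnet(fmt, ...)
  invisible(TRUE)
}

read_tsv_strict <- function(path, required_cols = NULL) {
  assert_that(file.exists(path), "file not found: %s", path)
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   comment.char = "", check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  if (!is.null(required_cols)) {
    miss <- setdiff(required_cols, names(df))
    assert_that(length(miss) == 0L, "%s: missing column(s): %s",
                path, paste(miss, collapse = ", "))
  }
  df
}

as_num_col <- function(x, what, path = "<input>") {
  suppressWarnings(v <- as.numeric(x))
  # "NaN"/"Inf" parse fine; downstream finiteness checks reject them with
  # a more precise message than a parse error would give
  bad <- which(is.na(v) & !(x %in% c("NA", "NaN")))
  assert_that(length(bad) == 0L, "%s: non-numeric %s at row %d: '%s'",
              path, what, if (length(bad)) bad[1] else 0L,
              if (length(bad)) x[bad[1]] else "")
  v
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#' Used to compare a computed sample partition with planted ground truth.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return ARI in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  assert_that(length(a) == length(b) && length(a) > 0L,
              "partitions must be non-empty and of equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- si * sj / n2
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
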