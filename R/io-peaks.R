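#' Read ATAC-seq peaks (BED6+ or narrowPeak)
#'
#' Accepts the package's own 7-column BED6+ dialect
#' (`chrom start end name intensity strand summit_offset`) or standard
#' 10-column narrowPeak, where the summit is `start + column 10` and the
#' intensity is taken from the signalValue column (column 7). Coordinates
#' are 0-based half-open throughout.
#'
#' @param path BED file, no header.
#' @param sample_id sample identifier attached to the returned set.
#' @return a `PeakSet`: data.frame with columns `chrom, start, end, peak_id,
#'   intensity, strand, summit` (summit is an absolute coordinate) and
#'   attribute `sample_id`.
#' @export
read_peaks <- function(path, sample_id) {
  assert_that(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(new_peakset(empty_peaks_df(), sample_id))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  ok <- nf == 7L | nf >= 10L
  assert_that(all(ok), "%s: malformed line %d: expected 7 (BED6+) or >=10 (narrowPeak) fields, got %d",
              path, which(!ok)[1], nf[!ok][1])
  get <- function(i) vapply(parts, `[[`, "", i)
  chrom <- get(1)
  start <- as_num_col(get(2), "start", path)
  end <- as_num_col(get(3), "end", path)
  peak_id <- get(4)
  strand <- get(6)
  narrow <- nf >= 10L
  intensity <- numeric(length(parts))
  offset <- numeric(length(parts))
  if (any(narrow)) {
    intensity[narrow] <- as_num_col(vapply(parts[narrow], `[[`, "", 7),
                                    "signalValue", path)
    offset[narrow] <- as_num_col(vapply(parts[narrow], `[[`, "", 10),
                                 "summit offset", path)
  }
  if (any(!narrow)) {
    intensity[!narrow] <- as_num_col(vapply(parts[!narrow], `[[`, "", 5),
                                     "intensity", path)
    offset[!narrow] <- as_num_col(vapply(parts[!narrow], `[[`, "", 7),
                                  "summit offset", path)
  }
  bad <- which(!(start < end))
  assert_that(length(bad) == 0L, "%s: line %d: start >= end", path,
              if (length(bad)) bad[1] else 0L)
  bad <- which(offset < 0 | offset >= end - start)
  assert_that(length(bad) == 0L,
              "%s: line %d: summit offset %g outside [0, width) of a %g bp peak",
              path, if (length(bad)) bad[1] else 0L,
              if (length(bad)) offset[bad[1]] else 0,
              if (length(bad)) (end - start)[bad[1]] else 0)
  bad <- which(intensity < 0)
  assert_that(length(bad) == 0L, "%s: line %d: negative intensity", path,
              if (length(bad)) bad[1] else 0L)
  assert_that(!anyDuplicated(peak_id), "%s: duplicated peak_id '%s'", path,
              peak_id[duplicated(peak_id)][1])
  df <- data.frame(chrom = chrom, start = start, end = end,
                   peak_id = peak_id, intensity = intensity,
                   strand = strand, summit = start + offset,
                   stringsAsFactors = FALSE)
  new_peakset(df, sample_id)
}

empty_peaks_df <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             peak_id = character(), intensity = numeric(),
             strand = character(), summit = numeric(),
             stringsAsFactors = FALSE)
}

new_peakset <- function(df, sample_id) {
  structure(df, sample_id = sample_id, class = c("PeakSet", "data.frame"))
}

#' Write a PeakSet as 7-column BED6+
#'
#' @param peaks a `PeakSet` (see [read_peaks()]).
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%d",
                   peaks$chrom, as.integer(peaks$start),
                   as.integer(peaks$end), peaks$peak_id,
                   fmt_num(peaks$intensity), peaks$strand,
                   as.integer(peaks$summit - peaks$start))
  writeLines(lines, path)
  invisible(path)
}
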