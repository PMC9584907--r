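#' Read TF motifs in MEME minimal format
#'
#' Parses `MOTIF <name>` blocks with their `letter-probability matrix:`
#' sections. Each PWM row must sum to 1 within 1e-6, probabilities must lie
#' in \[0, 1\], and motifs must be at least 4 bp long. A `Background letter
#' frequencies` line, if present, is stored as the library's background.
#'
#' @param path MEME minimal-format file.
#' @return a `MotifLibrary`: named list of motifs, each a list with
#'   `tf_name` and `pwm` (L x 4 matrix, columns A, C, G, T); attribute
#'   `background` holds the 4 background frequencies.
#' @export
read_motifs <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    assert_that(length(toks) == 8L, "%s: malformed background line", path)
    vals <- as_num_col(toks[c(2, 4, 6, 8)], "background frequency", path)
    bg <- setNames(vals, toks[c(1, 3, 5, 7)])[c("A", "C", "G", "T")]
    assert_that(abs(sum(bg) - 1) < 1e-6, "%s: background does not sum to 1", path)
  }
  starts <- grep("^MOTIF\\b", lines)
  motifs <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    assert_that(!is.na(name) && nzchar(name), "%s: MOTIF line without a name", path)
    assert_that(is.null(motifs[[name]]), "%s: duplicated motif '%s'", path, name)
    hdr_rel <- grep("^letter-probability matrix:", lines[seq(s, length(lines))])
    assert_that(length(hdr_rel) > 0L,
                "%s: motif '%s' has no letter-probability matrix", path, name)
    hdr <- s + hdr_rel[1] - 1L
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    assert_that(!is.na(w), "%s: motif '%s': cannot parse w=", path, name)
    assert_that(w >= 4L, "%s: motif '%s': length %d < 4", path, name, w)
    rows <- lines[(hdr + 1L):(hdr + w)]
    pwm <- t(vapply(seq_along(rows), function(i) {
      toks <- strsplit(trimws(rows[i]), "\\s+")[[1]]
      assert_that(length(toks) == 4L, "%s: motif '%s' row %d: expected 4 fields",
                  path, name, i)
      as_num_col(toks, "PWM probability", path)
    }, numeric(4)))
    colnames(pwm) <- c("A", "C", "G", "T")
    validate_pwm(pwm, name, path)
    motifs[[name]] <- list(tf_name = name, pwm = pwm)
  }
  assert_that(length(motifs) > 0L, "%s: no motifs found", path)
  structure(motifs, background = bg, class = "MotifLibrary")
}

validate_pwm <- function(pwm, name = "<pwm>", path = "<input>") {
  assert_that(all(pwm >= 0 & pwm <= 1),
              "%s: motif '%s': probabilities outside [0,1]", path, name)
  bad <- which(abs(rowSums(pwm) - 1) > 1e-6)
  assert_that(length(bad) == 0L,
              "%s: motif '%s': PWM row %d sums to %.8f, not 1", path, name,
              if (length(bad)) bad[1] else 0L,
              if (length(bad)) rowSums(pwm)[bad[1]] else 0)
  assert_that(nrow(pwm) >= 4L, "%s: motif '%s': length < 4", path, name)
  invisible(TRUE)
}

#' Write a MotifLibrary in MEME minimal format
#' @param motifs a `MotifLibrary` (see [read_motifs()]).
#' @param path output path.
#' @export
write_motifs <- function(motifs, path) {
  bg <- attr(motifs, "background") %||% c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %s C %s G %s T %s", fmt_num(bg[1]), fmt_num(bg[2]),
                       fmt_num(bg[3]), fmt_num(bg[4])), ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$tf_name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       nrow(m$pwm)), con)
    writeLines(apply(m$pwm, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}
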