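DNA_BASES <- c("A", "C", "G", "T")

encode_dna <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], DNA_BASES) - 1L
}

#' Log-odds matrix of a PWM against a 0-order background
#'
#' Scores are in bits: `log2(p / bg)` per position and base. Zero
#' probabilities are floored at 1e-10 before the ratio.
#'
#' @param pwm L x 4 probability matrix (columns A, C, G, T).
#' @param background 4 background frequencies summing to 1.
#' @return L x 4 matrix of log-odds scores.
#' @export
pwm_log_odds <- function(pwm, background = rep(0.25, 4)) {
  assert_that(abs(sum(background) - 1) < 1e-6, "background must sum to 1")
  assert_that(all(background > 0), "background frequencies must be positive")
  sweep(log2(pmax(pwm, 1e-10)), 2, log2(background), `-`)
}

#' Maximum achievable log-odds score of a PWM
#' @inheritParams pwm_log_odds
#' @return scalar, bits.
#' @export
pwm_max_score <- function(pwm, background = rep(0.25, 4)) {
  sum(apply(pwm_log_odds(pwm, background), 1, max))
}

revcomp_pwm <- function(pwm) {
  out <- pwm[rev(seq_len(nrow(pwm))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(out) <- DNA_BASES
  out
}

# Exact distribution of the total log-odds score of a random background
# sequence, by dynamic programming over PWM positions. Partial sums that
# are bit-identical doubles are merged at every step (exact: no rounding),
# so informative PWMs with few distinct column values stay tiny. If the
# support still exceeds `max_support`, scores are coarsened to `grain`
# bits (only reachable for long, near-random PWMs).
pwm_score_distribution <- function(lo, background = rep(0.25, 4),
                                   max_support = 2^18, grain = 1e-9) {
  scores <- 0
  probs <- 1
  for (j in seq_len(nrow(lo))) {
    scores <- as.vector(outer(scores, lo[j, ], `+`))
    probs <- as.vector(outer(probs, background, `*`))
    o <- order(scores)
    scores <- scores[o]
    probs <- probs[o]
    grp <- cumsum(!duplicated(scores))
    if (grp[length(grp)] < length(grp)) {
      probs <- as.vector(rowsum(probs, grp))
      scores <- scores[!duplicated(scores)]
    }
    if (length(scores) > max_support) {
      scores <- round(scores / grain) * grain
      grp <- cumsum(!duplicated(scores))
      probs <- as.vector(rowsum(probs, grp))
      scores <- scores[!duplicated(scores)]
    }
  }
  # tail[i] = P(score >= scores[i]); scores strictly increasing
  list(scores = scores, tail = rev(cumsum(rev(probs))))
}

# P(background score >= s), vectorized lookup in the exact distribution.
# Scores below the support minimum get p = 1; above the maximum, 0.
score_pvalue <- function(s, dist) {
  n <- length(dist$scores)
  idx <- findInterval(s, dist$scores) # last support point <= s
  exact <- idx >= 1L & dist$scores[pmax(idx, 1L)] == s
  p <- ifelse(exact, dist$tail[pmax(idx, 1L)],
              ifelse(idx >= n, 0, dist$tail[pmin(idx + 1L, n)]))
  pmin(p, 1)
}

#' Scan sequences for PWM matches with exact p-values
#'
#' Slides the PWM over both strands of each sequence, scoring in bits
#' against a 0-order background, and keeps positions whose score p-value
#' under the exact background score distribution (computed by dynamic
#' programming) is below `p_threshold` (FIMO-style criterion, default
#' 1e-4). Offsets are 0-based positions of the match start on the forward
#' strand for both strands.
#'
#' @param sequences named character vector of DNA windows (typically the
#'   150 bp regions centred on peak summits).
#' @param pwm L x 4 probability matrix, or a motif list with `$pwm`.
#' @param background 4 background frequencies (default uniform).
#' @param p_threshold significance threshold on the exact score p-value.
#' @param tf_name motif name recorded in the hits (defaults to the motif's).
#' @return data.frame of `MotifHit`s: tf_name, peak_id, offset, strand,
#'   score, p_value. Sequences shorter than the PWM yield no hits.
#' @export
scan_motifs <- function(sequences, pwm, background = rep(0.25, 4),
                        p_threshold = 1e-4, tf_name = NULL) {
  if (is.list(pwm) && !is.null(pwm$pwm)) {
    tf_name <- tf_name %||% pwm$tf_name
    pwm <- pwm$pwm
  }
  tf_name <- tf_name %||% "<motif>"
  validate_pwm(pwm)
  assert_that(p_threshold > 0 && p_threshold <= 1, "invalid p_threshold")
  lo_f <- pwm_log_odds(pwm, background)
  lo_r <- pwm_log_odds(revcomp_pwm(pwm), background)
  dist_f <- pwm_score_distribution(lo_f, background)
  # The reverse-complement PWM has its own background score distribution
  # unless the background is strand-symmetric.
  dist_r <- pwm_score_distribution(lo_r, background)
  # accept pre-encoded sequences (named list of integer code vectors) to
  # avoid re-encoding when scanning a whole motif library
  enc <- if (is.list(sequences)) sequences else lapply(sequences, encode_dna)
  hits <- list()
  for (strand in c("+", "-")) {
    lo <- if (strand == "+") lo_f else lo_r
    dist <- if (strand == "+") dist_f else dist_r
    # smallest score whose tail p-value clears the threshold; p is a
    # non-increasing step function of the score, so the comparison on
    # scores is equivalent and avoids p-value lookups for non-hits
    sig <- which(dist$tail < p_threshold)
    if (!length(sig)) next # threshold unreachable for this PWM
    cutoff <- dist$scores[sig[1]]
    sc <- cpp_scan(enc, lo)
    ns <- lengths(sc)
    if (!sum(ns)) next
    all_sc <- unlist(sc, use.names = FALSE)
    sel <- which(!is.na(all_sc) & all_sc >= cutoff)
    if (!length(sel)) next
    win <- rep.int(seq_along(sc), ns)[sel]
    off <- (sequence(ns) - 1L)[sel]
    hits[[length(hits) + 1L]] <- data.frame(
      tf_name = tf_name, peak_id = names(enc)[win],
      offset = off, strand = strand, score = all_sc[sel],
      p_value = score_pvalue(all_sc[sel], dist), stringsAsFactors = FALSE)
  }
  if (!length(hits)) {
    return(data.frame(tf_name = character(), peak_id = character(),
                      offset = integer(), strand = character(),
                      score = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}
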