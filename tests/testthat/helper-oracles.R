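# Independent oracles, kept free of the implementation paths they check.

# Exact background score distribution of a log-odds matrix by full
# enumeration of all 4^L sequences. Scores accumulate left-to-right,
# matching the scanner's summation order bit for bit.
enum_score_distribution <- function(lo, background = rep(0.25, 4)) {
  L <- nrow(lo)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- numeric(nrow(grid))
  probs <- rep(1, nrow(grid))
  for (j in seq_len(L)) {
    scores <- scores + lo[j, ][grid[, j]]
    probs <- probs * background[grid[, j]]
  }
  list(scores = scores, probs = probs)
}

# Score one window substring against a log-odds matrix, left-to-right.
oracle_score <- function(s, lo) {
  codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  acc <- 0
  for (j in seq_len(nrow(lo))) acc <- acc + lo[j, codes[j]]
  acc
}

# Brute-force hit list for one window: every offset on both strands,
# exact p-values from full enumeration.
brute_force_scan <- function(seq, pwm, background = rep(0.25, 4),
                             p_threshold = 1e-4) {
  lo_f <- pwm_log_odds(pwm, background)
  lo_r <- pwm_log_odds(pprnet:::revcomp_pwm(pwm), background)
  dist_f <- enum_score_distribution(lo_f, background)
  dist_r <- enum_score_distribution(lo_r, background)
  L <- nrow(pwm)
  out <- list()
  for (strand in c("+", "-")) {
    lo <- if (strand == "+") lo_f else lo_r
    dist <- if (strand == "+") dist_f else dist_r
    for (o in seq_len(max(0, nchar(seq) - L + 1))) {
      sc <- oracle_score(substr(seq, o, o + L - 1), lo)
      p <- sum(dist$probs[dist$scores >= sc])
      if (p < p_threshold) {
        out[[length(out) + 1L]] <- data.frame(
          offset = o - 1L, strand = strand, score = sc, p_value = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# random PWM, optionally sharp (consensus-dominated)
random_pwm <- function(L, sharp = FALSE, info = 0.95) {
  if (sharp) return(consensus_pwm(random_dna(L), info = info))
  p <- matrix(runif(4 * L, 0.05, 1), L, 4)
  p <- p / rowSums(p)
  colnames(p) <- c("A", "C", "G", "T")
  p
}
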