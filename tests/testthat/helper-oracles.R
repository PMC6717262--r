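# Independent oracles and small fixture builders shared across tests.
# Each oracle re-derives a quantity along a different code path from the
# implementation it checks.

default_pwm <- function() pfm_to_pwm(build_default_pfm())

BASES4 <- c("A", "C", "G", "T")

# log-odds column, written out directly from the definition
oracle_log_odds <- function(counts_col, pseudocount, background) {
  log2((counts_col + pseudocount * background) /
         (sum(counts_col) + pseudocount) / background)
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# character-by-character PWM score; N scores 0
oracle_score <- function(site, pwm) {
  chars <- strsplit(site, "", fixed = TRUE)[[1L]]
  total <- 0
  for (j in seq_along(chars)) {
    if (chars[j] != "N") total <- total + pwm$weights[chars[j], j]
  }
  total
}

# exhaustive enumeration of every (start, strand, spacer) candidate
oracle_scan_all <- function(sequence, pwm, spacers = 0:13) {
  L <- nchar(sequence)
  rows <- list()
  for (s in spacers) {
    for (i in seq_len(max(0L, L - 20L - s + 1L))) {
      plus <- paste0(substr(sequence, i, i + 9L),
                     substr(sequence, i + 10L + s, i + 19L + s))
      minus <- oracle_revcomp(plus)
      rows[[length(rows) + 1L]] <- data.frame(
        start = i - 1L, strand = c("+", "-"), spacer_len = s,
        score = c(oracle_score(plus, pwm), oracle_score(minus, pwm)),
        site20 = c(plus, minus), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# two-tailed Fisher p by direct hypergeometric enumeration
oracle_fisher <- function(a, b, c, d, rel_tol = 1e-7) {
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  x <- max(0, k - m2):min(k, m1)
  probs <- stats::dhyper(x, m1, m2, k)
  sum(probs[probs <= probs[x == a] * (1 + rel_tol)])
}

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(BASES4, n, replace = TRUE, prob = prob), collapse = "")
}

# a 20-mer equal to the consensus except for given (position, base) edits
edited_consensus <- function(...) {
  edits <- list(...)
  s <- strsplit(consensus_sequence(), "", fixed = TRUE)[[1L]]
  for (e in edits) s[e[[1L]]] <- e[[2L]]
  paste(s, collapse = "")
}
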