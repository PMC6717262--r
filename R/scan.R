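# Scanning peak sequences for two-half-site response elements.

# Encode a DNA string as integer codes 1..5 (A, C, G, T, N); errors on
# anything else, naming the 1-based offset of the first bad character.
encode_dna <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  code <- match(chars, c(DNA_BASES, "N"))
  if (anyNA(code)) {
    off <- which(is.na(code))[1L]
    stop(sprintf("invalid character '%s' at offset %d: sequences must be over A, C, G, T, N",
                 chars[off], off))
  }
  code
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# 5 x 20 lookup table: PWM weights with an all-zero row for N, so unknown
# bases are background-neutral.
pwm_lookup <- function(pwm) {
  rbind(pwm$weights, 0)
}

empty_hits <- function() {
  data.frame(
    peak_id = character(), start = integer(), strand = character(),
    spacer_len = integer(), score = numeric(), site20 = character(),
    stringsAsFactors = FALSE
  )
}

#' Score spacer-removed 20-mers with a PWM
#'
#' @param sites character vector of 20-character sequences over A/C/G/T/N.
#' @param pwm a [pfm_to_pwm()] object.
#' @return Numeric vector of scores in bits; `N` contributes 0 at its
#'   position.
#' @export
score_site20 <- function(sites, pwm) {
  stopifnot(inherits(pwm, "p53_pwm"))
  lk <- pwm_lookup(pwm)
  vapply(sites, function(s) {
    code <- encode_dna(s)
    if (length(code) != 20L) stop("site must be exactly 20 bp, got ", length(code))
    sum(lk[cbind(code, seq_len(20L))])
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Scan a sequence for two-half-site response elements
#'
#' Enumerates every start offset, strand, and spacer length in
#' `spacer_range`. A candidate is a 10-bp half site, an unscored spacer, and
#' a second 10-bp half site; its score is the PWM score of the
#' spacer-removed 20-mer read 5' to 3' on the candidate's strand. All
#' candidates scoring at least `min_score` are returned. `N` bases are
#' background-neutral (weight 0).
#'
#' For a minus-strand candidate, `start` still gives the 0-based offset of
#' the first half-site base within the supplied (plus-strand) sequence,
#' while `site20` is the reverse complement, i.e. the element as read on the
#' minus strand. Under the dyad-symmetric default matrix the two strands of
#' any candidate score identically, and downstream tie-breaking reports such
#' elements on the plus strand.
#'
#' @param sequence a single DNA string (length >= 20) over A/C/G/T/N.
#' @param pwm a [pfm_to_pwm()] object.
#' @param spacer_range integer vector `c(min, max)` of spacer lengths to
#'   enumerate, within 0..20.
#' @param min_score score threshold in bits; default 80% of the PWM's
#'   maximal attainable score.
#' @param peak_id identifier copied into the result.
#' @return A data frame with columns `peak_id`, `start` (0-based offset of
#'   the first half site), `strand`, `spacer_len`, `score`, `site20`.
#' @examples
#' pwm <- pfm_to_pwm(build_default_pfm())
#' peak <- paste0("ACGTACGTAC", consensus_sequence(), "GGCATACGTT")
#' scan_re(peak, pwm, peak_id = "pk1")
#' @export
scan_re <- function(sequence, pwm, spacer_range = c(0L, 13L), min_score = NULL,
                    peak_id = NA_character_) {
  stopifnot(inherits(pwm, "p53_pwm"), is.character(sequence), length(sequence) == 1L)
  spacer_range <- as.integer(spacer_range)
  if (length(spacer_range) != 2L || spacer_range[1L] > spacer_range[2L] ||
      spacer_range[1L] < 0L || spacer_range[2L] > 20L) {
    stop("'spacer_range' must be an ascending integer pair within [0, 20]")
  }
  if (is.null(min_score)) min_score <- 0.8 * pwm$max_score

  code <- encode_dna(sequence)
  L <- length(code)
  if (L < 20L) stop("sequence must be at least 20 bp, got ", L)

  lk_plus <- pwm_lookup(pwm)
  # Minus-strand weights: complement the base, reverse the positions.
  lk_minus <- lk_plus[c(4L, 3L, 2L, 1L, 5L), 20L:1L]

  rows <- list()
  for (s in seq.int(spacer_range[1L], spacer_range[2L])) {
    n <- L - 20L - s + 1L
    if (n < 1L) next
    off <- c(0L:9L, 10L:19L + s)
    starts <- seq_len(n)
    sc_plus <- numeric(n)
    sc_minus <- numeric(n)
    for (j in seq_len(20L)) {
      cj <- code[starts + off[j]]
      sc_plus <- sc_plus + lk_plus[, j][cj]
      sc_minus <- sc_minus + lk_minus[, j][cj]
    }
    for (strand in c("+", "-")) {
      sc <- if (strand == "+") sc_plus else sc_minus
      keep <- which(sc >= min_score)
      if (!length(keep)) next
      site_plus <- paste0(
        substring(sequence, keep, keep + 9L),
        substring(sequence, keep + 10L + s, keep + 19L + s)
      )
      rows[[length(rows) + 1L]] <- data.frame(
        peak_id = peak_id,
        start = keep - 1L,
        strand = strand,
        spacer_len = s,
        score = sc[keep],
        site20 = if (strand == "+") toupper(site_plus) else revcomp(toupper(site_plus)),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) return(empty_hits())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Highest-scored response element of one peak
#'
#' Ties are broken deterministically: smaller start, then plus strand, then
#' smaller spacer length.
#'
#' @param hits data frame of hits from [scan_re()], all sharing one
#'   `peak_id`.
#' @return A one-row data frame, or `NULL` for empty input (a peak with no
#'   candidate above threshold contributes no RE).
#' @export
best_hit_per_peak <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  ids <- unique(hits$peak_id)
  if (length(ids) > 1L) {
    stop("hits must share one peak_id, found: ", paste(ids, collapse = ", "))
  }
  ord <- order(-hits$score, hits$start, match(hits$strand, c("+", "-")), hits$spacer_len)
  out <- hits[ord[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best response element for each peak in a sequence set
#'
#' Runs [scan_re()] on every named sequence and keeps the best hit per peak;
#' peaks with no candidate at or above `min_score` are dropped.
#'
#' @param sequences named character vector of peak sequences.
#' @inheritParams scan_re
#' @return Data frame of best hits (one row per retained peak).
#' @export
scan_peaks <- function(sequences, pwm, spacer_range = c(0L, 13L), min_score = NULL) {
  if (is.null(names(sequences)) || anyNA(names(sequences)) || any(names(sequences) == "")) {
    stop("'sequences' must be a named character vector (names are peak ids)")
  }
  best <- lapply(names(sequences), function(id) {
    best_hit_per_peak(scan_re(sequences[[id]], pwm, spacer_range = spacer_range,
                              min_score = min_score, peak_id = id))
  })
  best <- best[!vapply(best, is.null, logical(1L))]
  if (!length(best)) return(empty_hits())
  out <- do.call(rbind, best)
  rownames(out) <- NULL
  out
}
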