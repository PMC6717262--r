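# Half-site frequency model of the p53 response element and its log-odds
# scoring form. The full RE is two 10-bp half sites, each matching the
# palindromic consensus RRRCWWGYYY (R = A/G, Y = C/T, W = A/T), optionally
# separated by a short spacer that is not scored.

DNA_BASES <- c("A", "C", "G", "T")

# Allowed bases per half-site position under the consensus RRRCWWGYYY.
HALF_SITE_ALLOWED <- list(
  c("A", "G"), c("A", "G"), c("A", "G"),
  "C",
  c("A", "T"), c("A", "T"),
  "G",
  c("C", "T"), c("C", "T"), c("C", "T")
)

#' Consensus p53 response element
#'
#' A canonical 20-bp written form of the p53 consensus, two copies of the
#' 10-bp half site `GGGCATGCCC` (G for purine positions, C for pyrimidine
#' positions, A/T at the central weak positions). The half site is its own
#' reverse complement, so the 20-mer is dyad symmetric.
#'
#' @param half logical; return the 10-bp half site instead of the 20-mer.
#' @return A character scalar.
#' @examples
#' consensus_sequence()
#' @export
consensus_sequence <- function(half = FALSE) {
  h <- "GGGCATGCCC"
  if (half) h else paste0(h, h)
}

#' Build the default half-site position frequency matrix
#'
#' Converts the consensus half site RRRCWWGYYY into a 4 x 10 base-probability
#' matrix. At each position the probability mass `1 - degeneracy_epsilon` is
#' split equally among the bases the consensus symbol allows, and
#' `degeneracy_epsilon` equally among the remaining bases, so the matrix
#' tolerates occasional off-consensus bases without ever preferring them.
#'
#' @param degeneracy_epsilon probability mass given to off-consensus bases
#'   per position; must satisfy `0 <= degeneracy_epsilon < 0.5`.
#' @param name label stored with the matrix.
#' @return An object of class `half_site_pfm`: a list with elements `counts`
#'   (4 x 10 numeric matrix, rows A/C/G/T, columns summing to 1) and `name`.
#' @examples
#' pfm <- build_default_pfm(0.04)
#' pfm$counts[, 4] # fixed C position
#' @export
build_default_pfm <- function(degeneracy_epsilon = 0.04, name = "p53_half_site_consensus") {
  if (!is.numeric(degeneracy_epsilon) || length(degeneracy_epsilon) != 1L ||
      degeneracy_epsilon < 0 || degeneracy_epsilon >= 0.5) {
    stop("'degeneracy_epsilon' must be a single probability in [0, 0.5)")
  }
  counts <- vapply(HALF_SITE_ALLOWED, function(allowed) {
    col <- rep(degeneracy_epsilon / (4L - length(allowed)), 4L)
    names(col) <- DNA_BASES
    col[allowed] <- (1 - degeneracy_epsilon) / length(allowed)
    col
  }, numeric(4L))
  half_site_pfm(counts, name = name)
}

#' Construct a half-site PFM from a count matrix
#'
#' @param counts 4 x 10 nonnegative numeric matrix; rows must be (or be
#'   named) A, C, G, T and every column must have a positive total.
#' @param name label for the matrix.
#' @return An object of class `half_site_pfm`.
#' @export
half_site_pfm <- function(counts, name = "half_site_pfm") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("a half-site PFM needs 4 base rows (A, C, G, T)")
  if (ncol(counts) != 10L) {
    stop("a half-site PFM needs exactly 10 columns, found ", ncol(counts))
  }
  if (is.null(rownames(counts))) rownames(counts) <- DNA_BASES
  counts <- counts[DNA_BASES, , drop = FALSE]
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("PFM counts must be finite and nonnegative")
  }
  if (any(colSums(counts) <= 0)) {
    stop("every PFM column must have a positive total")
  }
  colnames(counts) <- as.character(seq_len(10L))
  structure(list(counts = counts, name = name), class = "half_site_pfm")
}

#' @export
print.half_site_pfm <- function(x, ...) {
  cat("p53 half-site PFM:", x$name, "\n")
  print(round(x$counts, 3))
  invisible(x)
}

#' Convert a half-site PFM into a 20-position log-odds PWM
#'
#' Column probabilities are regularised with a background-weighted
#' pseudocount and converted to base-2 log-odds against the background:
#' `weight[b, i] = log2((count[b, i] + pseudocount * background[b]) /
#' (total_i + pseudocount) / background[b])`. The 20-position weight matrix
#' is the half-site matrix concatenated with itself, so both half sites are
#' scored by the same model; the spacer between them is never scored.
#'
#' @param pfm a [half_site_pfm()] object.
#' @param pseudocount nonnegative regulariser added to each column (in count
#'   units; the default PFM columns sum to 1, so the default of 1 weights
#'   observed frequencies and background equally).
#' @param background length-4 base probabilities (A, C, G, T) summing to 1.
#' @return An object of class `p53_pwm`: list with `weights` (4 x 20),
#'   `background`, `pseudocount`, and `max_score`, the best attainable score
#'   in bits (sum of the per-column maxima).
#' @examples
#' pwm <- pfm_to_pwm(build_default_pfm(0.04))
#' pwm$max_score
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 1, background = c(0.25, 0.25, 0.25, 0.25)) {
  stopifnot(inherits(pfm, "half_site_pfm"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0) {
    stop("'pseudocount' must be a single nonnegative number")
  }
  if (length(background) != 4L || any(background <= 0)) {
    stop("'background' must be 4 positive probabilities")
  }
  if (abs(sum(background) - 1) > 1e-9) stop("'background' must sum to 1")
  background <- stats::setNames(as.numeric(background), DNA_BASES)

  totals <- colSums(pfm$counts)
  if (pseudocount == 0 && any(totals == 0)) {
    stop("degenerate PFM: zero column total with zero pseudocount")
  }
  probs <- sweep(pfm$counts + pseudocount * background, 2L, totals + pseudocount, "/")
  half <- log2(sweep(probs, 1L, background, "/"))
  weights <- cbind(half, half)
  colnames(weights) <- as.character(seq_len(20L))
  structure(
    list(
      weights = weights,
      background = background,
      pseudocount = pseudocount,
      max_score = sum(apply(weights, 2L, max)),
      pfm_name = pfm$name
    ),
    class = "p53_pwm"
  )
}

#' @export
print.p53_pwm <- function(x, ...) {
  cat("p53 response-element PWM (two half sites, log2 odds)\n")
  cat("  source PFM :", x$pfm_name, "\n")
  cat("  pseudocount:", x$pseudocount, "\n")
  cat("  max score  :", round(x$max_score, 3), "bits\n")
  invisible(x)
}
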