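# Nucleotide count matrices over RE sets, sequence-logo tables, and
# per-position / concurrent enrichment between two RE sets.

#' Count nucleotides per position over a set of 20-mers
#'
#' @param sites character vector of 20-character sequences over A/C/G/T/N;
#'   `N` counts toward no base.
#' @param label condition name stored with the matrix.
#' @return An object of class `nucleotide_counts`: list with `counts`
#'   (20 positions x 4 bases integer matrix), `n` (number of sites), and
#'   `label`.
#' @examples
#' m <- count_nucleotides(c(consensus_sequence(), consensus_sequence()))
#' m$counts[9, ]
#' @export
count_nucleotides <- function(sites, label = "") {
  counts <- matrix(0L, nrow = 20L, ncol = 4L,
                   dimnames = list(position = as.character(1:20), base = DNA_BASES))
  if (length(sites)) {
    lens <- nchar(sites)
    if (any(lens != 20L)) {
      bad <- which(lens != 20L)[1L]
      stop(sprintf("site %d has length %d, expected 20", bad, lens[bad]))
    }
    chars <- matrix(unlist(strsplit(toupper(sites), "", fixed = TRUE), use.names = FALSE),
                    ncol = 20L, byrow = TRUE)
    ok <- chars %in% c(DNA_BASES, "N")
    if (!all(ok)) {
      stop("sites must be over A, C, G, T, N; offending character: ",
           chars[which(!ok)[1L]])
    }
    for (b in DNA_BASES) counts[, b] <- colSums(chars == b)
  }
  structure(list(counts = counts, n = length(sites), label = label),
            class = "nucleotide_counts")
}

#' @export
print.nucleotide_counts <- function(x, ...) {
  cat(sprintf("Nucleotide counts over %d response elements%s\n", x$n,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  print(t(x$counts))
  invisible(x)
}

#' Per-position frequencies and information content (logo table)
#'
#' Converts a count matrix into the per-position base frequencies and
#' Shannon information content (`2 - H(p)` bits) that sequence-logo
#' renderers consume; write it out with [write_tsv()].
#'
#' @param m a [count_nucleotides()] object with `n > 0`.
#' @return Data frame with columns `position`, `A`, `C`, `G`, `T`
#'   (frequencies) and `ic` (bits).
#' @export
to_logo_matrix <- function(m) {
  stopifnot(inherits(m, "nucleotide_counts"))
  if (m$n == 0L) stop("cannot build a logo table from an empty RE set")
  totals <- rowSums(m$counts)
  if (any(totals == 0)) stop("a position has no counted base (all N)")
  freq <- m$counts / totals
  ent <- apply(freq, 1L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  data.frame(position = 1:20, freq, ic = 2 - ent, row.names = NULL)
}

#' Per-position nucleotide enrichment between two RE sets
#'
#' For every (position, base) pair, builds the 2x2 table of sites carrying
#' the base versus not in each set, and tests it with the two-tailed
#' Fisher's exact test. Sites with `N` at a position count as "without" any
#' base there. P-values are Bonferroni-corrected for the `m_tests` = 80
#' comparisons (20 positions x 4 bases).
#'
#' Degenerate cases carry `degenerate = TRUE`: the fold is reported as
#' `Inf` when the base is absent from set B only, and as 1 when absent from
#' both sets (p fixed at 1, no test possible).
#'
#' @param m_a,m_b [count_nucleotides()] objects for the two RE sets.
#' @param m_tests Bonferroni family size (default 80).
#' @return Data frame with one row per (position, base): the 2x2 cells
#'   `a`, `b`, `c`, `d`, proportions `prop_a`, `prop_b`, `fold`
#'   (`prop_a / prop_b`), `degenerate`, `p`, and `p_bonf`.
#' @examples
#' set.seed(1)
#' x <- simulate_re_sets(50, 50, seed = 1)
#' enr <- position_enrichment(count_nucleotides(x$sites_a, "A"),
#'                            count_nucleotides(x$sites_b, "B"))
#' head(enr[order(enr$p), ])
#' @export
position_enrichment <- function(m_a, m_b, m_tests = 80L) {
  stopifnot(inherits(m_a, "nucleotide_counts"), inherits(m_b, "nucleotide_counts"))
  if (m_a$n == 0L || m_b$n == 0L) stop("both RE sets must be nonempty")
  if (!identical(dim(m_a$counts), dim(m_b$counts))) {
    stop("count matrices must cover the same positions")
  }
  if (m_tests < 1L) stop("'m_tests' must be at least 1")
  n_a <- m_a$n
  n_b <- m_b$n
  grid <- expand.grid(base = DNA_BASES, position = 1:20,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("position", "base")]
  a <- m_a$counts[cbind(grid$position, match(grid$base, DNA_BASES))]
  c_ <- m_b$counts[cbind(grid$position, match(grid$base, DNA_BASES))]
  b <- n_a - a
  d <- n_b - c_
  degenerate <- (a + c_ == 0L) | (b + d == 0L) | (c_ == 0L)
  fold <- ifelse(c_ == 0L, ifelse(a == 0L, 1, Inf), (a / n_a) / (c_ / n_b))
  p <- vapply(seq_len(nrow(grid)), function(i) {
    if ((a[i] + c_[i]) == 0L || (b[i] + d[i]) == 0L) return(1)
    fisher_exact_two_tailed(a[i], b[i], c_[i], d[i])
  }, numeric(1L))
  data.frame(
    position = grid$position, base = grid$base,
    a = a, b = b, c = c_, d = d,
    prop_a = a / n_a, prop_b = c_ / n_b,
    fold = fold, degenerate = degenerate,
    p = p, p_bonf = pmin(1, m_tests * p),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Define a sequence signature as (position, base) pairs
#'
#' @param positions integer positions in 1..20, distinct.
#' @param bases bases (A/C/G/T), one per position.
#' @return Data frame with columns `position` and `base`.
#' @export
signature_spec <- function(positions, bases) {
  positions <- as.integer(positions)
  bases <- toupper(as.character(bases))
  if (!length(positions) || length(positions) != length(bases)) {
    stop("'positions' and 'bases' must be nonempty and the same length")
  }
  if (anyDuplicated(positions) || any(positions < 1L) || any(positions > 20L)) {
    stop("positions must be distinct and within 1..20")
  }
  if (!all(bases %in% DNA_BASES)) stop("bases must be A, C, G or T")
  data.frame(position = positions, base = bases, stringsAsFactors = FALSE)
}

#' The C9 + G12 signature of iASPP-regulated response elements
#' @return A [signature_spec()] with C at position 9 and G at position 12.
#' @export
signature_c9_g12 <- function() signature_spec(c(9L, 12L), c("C", "G"))

#' Which sites carry a signature
#'
#' A site carries the signature iff it matches every (position, base) pair;
#' `N` never matches.
#'
#' @param sites character vector of 20-mers.
#' @param spec a [signature_spec()].
#' @return Logical vector along `sites`.
#' @export
matches_signature <- function(sites, spec = signature_c9_g12()) {
  stopifnot(is.data.frame(spec), nrow(spec) >= 1L)
  hit <- rep(TRUE, length(sites))
  for (i in seq_len(nrow(spec))) {
    hit <- hit & substr(toupper(sites), spec$position[i], spec$position[i]) == spec$base[i]
  }
  hit
}

#' Concurrent enrichment of a multi-position signature
#'
#' Compares, between two RE sets, the proportions of sites carrying every
#' base of `spec` simultaneously, with the two-tailed Fisher's exact test.
#'
#' @param sites_a,sites_b character vectors of 20-mers.
#' @param spec a [signature_spec()].
#' @return One-row data frame shaped like a [position_enrichment()] record,
#'   with a `signature` label instead of (position, base).
#' @examples
#' # the published 2x2 table for concurrent C9+G12 gives fold 1.39
#' @export
concurrent_enrichment <- function(sites_a, sites_b, spec = signature_c9_g12()) {
  if (!length(sites_a) || !length(sites_b)) stop("both RE sets must be nonempty")
  n_a <- length(sites_a)
  n_b <- length(sites_b)
  a <- sum(matches_signature(sites_a, spec))
  c_ <- sum(matches_signature(sites_b, spec))
  b <- n_a - a
  d <- n_b - c_
  degenerate <- (a + c_ == 0L) || (b + d == 0L) || (c_ == 0L)
  fold <- if (c_ == 0L) (if (a == 0L) 1 else Inf) else (a / n_a) / (c_ / n_b)
  p <- if ((a + c_) == 0L || (b + d) == 0L) 1 else fisher_exact_two_tailed(a, b, c_, d)
  data.frame(
    signature = paste0(spec$base, spec$position, collapse = "+"),
    a = a, b = b, c = c_, d = d,
    prop_a = a / n_a, prop_b = c_ / n_b,
    fold = fold, degenerate = degenerate, p = p,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
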