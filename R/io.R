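# Readers and writers for the plain-text formats the pipeline exchanges:
# FASTA (via Biostrings), BED6+2 peak intervals, JASPAR-style PFM text,
# and tab-separated tables ('.' marks missing values).

#' Read and write FASTA sequence sets
#'
#' Thin wrappers around Biostrings that exchange named character vectors.
#'
#' @param path file path.
#' @return `read_fasta()` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences named character vector of DNA sequences.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  names(x) <- names(sequences)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read and write peak intervals as BED6+2
#'
#' Columns: chrom, start, end, name, score, strand, plus two signal columns
#' (test then control condition). Coordinates are 0-based half-open, as in
#' BED.
#'
#' @param path file path.
#' @return `read_peaks_bed()` returns a data frame with columns `chrom`,
#'   `start`, `end`, `peak_id`, `score`, `strand`, `signal_test`,
#'   `signal_ctrl`.
#' @export
read_peaks_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty BED file: ", path)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      peak_id = character(), score = numeric(), strand = character(),
                      signal_test = numeric(), signal_ctrl = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 8L)) {
    stop("malformed BED6+2 line ", which(nf != 8L)[1L], ": expected 8 fields")
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad)) {
    stop("malformed BED interval at line ", bad[1L],
         ": start must be a number smaller than end")
  }
  data.frame(
    chrom = m[, 1L], start = start, end = end, peak_id = m[, 4L],
    score = as.numeric(m[, 5L]), strand = m[, 6L],
    signal_test = as.numeric(m[, 7L]), signal_ctrl = as.numeric(m[, 8L]),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_peaks_bed
#' @param peaks data frame as returned by [read_peaks_bed()] or
#'   [simulate_peaks()].
#' @export
write_peaks_bed <- function(peaks, path) {
  cols <- c("chrom", "start", "end", "peak_id", "score", "strand",
            "signal_test", "signal_ctrl")
  miss <- setdiff(cols, names(peaks))
  if (length(miss)) stop("peaks are missing columns: ", paste(miss, collapse = ", "))
  utils::write.table(peaks[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write JASPAR-style half-site PFMs
#'
#' The accepted text form is an optional `>name` header followed by four
#' rows `A [ n1 ... n10 ]` (brackets optional) for A, C, G, T; exactly 10
#' columns are required for the 10-bp half site.
#'
#' @param path file path.
#' @return `read_pfm_jaspar()` returns a [half_site_pfm()] object.
#' @export
read_pfm_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  name <- "half_site_pfm"
  if (length(lines) && startsWith(lines[1L], ">")) {
    name <- trimws(sub("^>", "", lines[1L]))
    lines <- lines[-1L]
  }
  if (length(lines) != 4L) stop("a JASPAR PFM needs 4 base rows, found ", length(lines))
  rows <- lapply(lines, function(l) {
    base <- toupper(substr(trimws(l), 1L, 1L))
    nums <- scan(text = gsub("[^0-9.eE+-]", " ", sub("^[ \t]*[ACGTacgt]", "", l)),
                 what = numeric(), quiet = TRUE)
    list(base = base, nums = nums)
  })
  bases <- vapply(rows, `[[`, "", "base")
  if (!setequal(bases, DNA_BASES)) stop("PFM rows must be labelled A, C, G, T")
  ncols <- lengths(lapply(rows, `[[`, "nums"))
  if (any(ncols != 10L)) {
    stop("half-site PFM must have exactly 10 columns, found ", ncols[ncols != 10L][1L])
  }
  counts <- do.call(rbind, lapply(rows, `[[`, "nums"))
  rownames(counts) <- bases
  half_site_pfm(counts[DNA_BASES, , drop = FALSE], name = name)
}

#' @rdname read_pfm_jaspar
#' @param pfm a [half_site_pfm()] object.
#' @export
write_pfm_jaspar <- function(pfm, path) {
  stopifnot(inherits(pfm, "half_site_pfm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", pfm$name), con)
  for (b in DNA_BASES) {
    writeLines(sprintf("%s [ %s ]", b,
                       paste(format(pfm$counts[b, ], trim = TRUE, digits = 15),
                             collapse = " ")), con)
  }
  invisible(path)
}

#' Read and write tab-separated tables
#'
#' The canonical table dialect of the pipeline: tab delimiter, header row,
#' `.` for missing values.
#'
#' @param path file path.
#' @return `read_tsv()` returns a data frame.
#' @export
read_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) {
    warning("empty table file: ", path)
    return(data.frame())
  }
  utils::read.delim(path, na.strings = ".", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' @rdname read_tsv
#' @param x data frame to write.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read a differential-expression table
#'
#' Expects tab-separated columns `gene_id`, `fpkm_ctrl`, `fpkm_test`,
#' `fdr` (a `log2fc` column is accepted and recomputed downstream on the
#' FPKM + 1 scale).
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_de_table <- function(path) {
  x <- read_tsv(path)
  miss <- setdiff(c("gene_id", "fpkm_ctrl", "fpkm_test", "fdr"), names(x))
  if (length(miss)) stop("DE table is missing columns: ", paste(miss, collapse = ", "))
  x
}

#' Read gene models
#'
#' Tab-separated columns `gene_id`, `chrom`, `start`, `end`, `strand`
#' (0-based half-open span; strand + or -).
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_gene_models <- function(path) {
  gene_models_granges(read_tsv(path))
}

#' Read and write response-element hit tables
#'
#' The on-disk representation is 1-based inclusive for the start column;
#' in-memory hits are 0-based (see [scan_re()]).
#'
#' @param path file path.
#' @return `read_hits_tsv()` returns a hits data frame with 0-based
#'   `start`.
#' @export
read_hits_tsv <- function(path) {
  x <- read_tsv(path)
  miss <- setdiff(c("peak_id", "start", "strand", "spacer_len", "score", "site20"),
                  names(x))
  if (length(miss)) stop("hits table is missing columns: ", paste(miss, collapse = ", "))
  x$start <- as.integer(x$start) - 1L
  x
}

#' @rdname read_hits_tsv
#' @param hits hits data frame from [scan_re()] or [scan_peaks()].
#' @export
write_hits_tsv <- function(hits, path) {
  hits$start <- as.integer(hits$start) + 1L
  write_tsv(hits, path)
}
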