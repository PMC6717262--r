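# Differential-binding and differential-expression filters, peak-to-gene
# assignment, and the intersection that calls regulated p53 target genes.

#' Call peaks with condition-elevated binding signal
#'
#' Keeps peaks whose pseudocounted test/control signal ratio strictly
#' exceeds `fold_threshold` (the published filter is fold change > 2).
#'
#' @param peaks data frame with columns `chrom`, `start`, `end`, `peak_id`,
#'   `signal_test`, `signal_ctrl` (nonnegative normalised binding signals).
#' @param fold_threshold positive fold-change cutoff (strict).
#' @param pseudo pseudocount added to both signals to guard zero controls.
#' @return The retained rows, with a `chip_fold` column appended.
#' @export
call_differential_peaks <- function(peaks, fold_threshold = 2, pseudo = 1) {
  req <- c("chrom", "start", "end", "peak_id", "signal_test", "signal_ctrl")
  miss <- setdiff(req, names(peaks))
  if (length(miss)) stop("peaks are missing columns: ", paste(miss, collapse = ", "))
  if (fold_threshold <= 0) stop("'fold_threshold' must be positive")
  if (pseudo < 0) stop("'pseudo' must be nonnegative")
  if (any(peaks$signal_test < 0) || any(peaks$signal_ctrl < 0)) {
    stop("binding signals must be nonnegative")
  }
  peaks$chip_fold <- (peaks$signal_test + pseudo) / (peaks$signal_ctrl + pseudo)
  out <- peaks[peaks$chip_fold > fold_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter differentially expressed genes
#'
#' Keeps genes with `fdr < fdr_max` and an absolute FPKM fold change
#' strictly above `fold_min`, where the fold change is computed on
#' FPKM + 1: `log2fc = log2((fpkm_test + 1) / (fpkm_ctrl + 1))`. Both
#' inequalities are strict, so a gene at exactly 2-fold or FDR exactly 0.05
#' is excluded.
#'
#' @param genes data frame with columns `gene_id`, `fpkm_ctrl`, `fpkm_test`,
#'   `fdr`.
#' @param fdr_max FDR cutoff (strict).
#' @param fold_min fold-change cutoff on the FPKM + 1 scale (strict).
#' @return Retained rows with `log2fc` (recomputed on FPKM + 1) and a
#'   `direction` column (`"up"` / `"down"`).
#' @export
filter_de_genes <- function(genes, fdr_max = 0.05, fold_min = 2) {
  req <- c("gene_id", "fpkm_ctrl", "fpkm_test", "fdr")
  miss <- setdiff(req, names(genes))
  if (length(miss)) {
    stop("DE table is missing columns (one per condition is required): ",
         paste(miss, collapse = ", "))
  }
  if (any(genes$fpkm_ctrl < 0, na.rm = TRUE) || any(genes$fpkm_test < 0, na.rm = TRUE)) {
    stop("FPKM values must be nonnegative")
  }
  genes$log2fc <- log2((genes$fpkm_test + 1) / (genes$fpkm_ctrl + 1))
  keep <- genes$fdr < fdr_max & abs(genes$log2fc) > log2(fold_min)
  out <- genes[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

gene_models_granges <- function(models) {
  req <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(req, names(models))
  if (length(miss)) stop("gene models are missing columns: ", paste(miss, collapse = ", "))
  if (any(models$start >= models$end)) stop("gene model with start >= end")
  if (!all(models$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  models
}

#' Assign peaks to genes by body overlap or TSS proximity
#'
#' A peak maps to every gene whose body (span) it overlaps, plus every gene
#' whose transcription start site lies within `tss_window` bp of the peak.
#' One peak may map to several genes (overlapping gene bodies each receive
#' the peak). Coordinates are 0-based half-open; the TSS is the span start
#' on the plus strand and `end - 1` on the minus strand.
#'
#' @param peaks data frame with `chrom`, `start`, `end`, `peak_id`.
#' @param models data frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param tss_window nonnegative window around the TSS, in bp.
#' @return Named list: for every `peak_id`, the sorted character vector of
#'   assigned gene ids (possibly empty).
#' @export
assign_peaks_to_genes <- function(peaks, models, tss_window = 5000) {
  if (tss_window < 0) stop("'tss_window' must be nonnegative")
  models <- gene_models_granges(models)
  out <- stats::setNames(vector("list", nrow(peaks)), peaks$peak_id)
  for (i in seq_along(out)) out[[i]] <- character()
  if (!nrow(peaks) || !nrow(models)) return(out)

  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  bodies <- GenomicRanges::GRanges(models$chrom,
                                   IRanges::IRanges(models$start + 1L, models$end))
  tss1 <- ifelse(models$strand == "+", models$start + 1L, models$end)
  prom <- GenomicRanges::GRanges(models$chrom,
                                 IRanges::IRanges(pmax(1, tss1 - tss_window),
                                                  tss1 + tss_window))
  # peaks and models may legitimately cover different chromosome sets;
  # non-shared chromosomes simply never overlap
  ov <- suppressWarnings(rbind(
    as.data.frame(GenomicRanges::findOverlaps(pk, bodies)),
    as.data.frame(GenomicRanges::findOverlaps(pk, prom))
  ))
  for (k in seq_len(nrow(ov))) {
    i <- ov$queryHits[k]
    out[[i]] <- union(out[[i]], models$gene_id[ov$subjectHits[k]])
  }
  lapply(out, function(g) sort(g))
}

#' Annotate a response element with signature and conserved-position flags
#'
#' Checks the condition-signature positions C9 and G12 together with the
#' four conserved CWWG-core positions of the 20-bp motif (C4 and G7 in the
#' first half site; their dyad partners C14 and G17 in the second). The
#' `conserved_deviation` flag marks any mismatch among the four conserved
#' positions; `concurrent_c9_g12` marks sites carrying both signature
#' bases.
#'
#' @param site20 character vector of 20-character sites over A/C/G/T/N.
#' @return Data frame with logical columns `C4`, `G7`, `C9`, `G12`, `C14`,
#'   `G17`, `concurrent_c9_g12`, `conserved_deviation`.
#' @examples
#' annotate_signature(consensus_sequence())
#' @export
annotate_signature <- function(site20) {
  lens <- nchar(site20)
  if (any(lens != 20L)) {
    bad <- which(lens != 20L)[1L]
    stop(sprintf("site %d has length %d, expected 20", bad, lens[bad]))
  }
  site20 <- toupper(site20)
  expected <- c(`4` = "C", `7` = "G", `9` = "C", `12` = "G", `14` = "C", `17` = "G")
  flags <- vapply(names(expected), function(p) {
    substr(site20, as.integer(p), as.integer(p)) == expected[[p]]
  }, logical(length(site20)))
  flags <- matrix(flags, ncol = length(expected),
                  dimnames = list(NULL, paste0(expected, names(expected))))
  out <- as.data.frame(flags)
  out$concurrent_c9_g12 <- out$C9 & out$G12
  out$conserved_deviation <- !(out$C4 & out$G7 & out$C14 & out$G17)
  out
}

#' Call regulated p53 target genes
#'
#' Intersects differential expression with differential binding: one record
#' is emitted for every (gene, peak) pair where the gene passed the DE
#' filter, the peak passed the differential-binding filter, and the
#' assignment links them. Each record carries the peak's best response
#' element (if any) with its signature flags; a differential peak without a
#' called RE yields a record with `re_present = FALSE`.
#'
#' @param de_genes output of [filter_de_genes()].
#' @param diff_peaks output of [call_differential_peaks()].
#' @param assignment output of [assign_peaks_to_genes()]; must cover every
#'   differential peak.
#' @param re_per_peak best-RE-per-peak data frame from [scan_peaks()].
#' @return Data frame of target-gene records: `gene_id`, `peak_id`,
#'   `direction`, `rna_log2fc`, `chip_fold`, `re_present`, RE fields, and
#'   the flags of [annotate_signature()].
#' @export
call_iptgs <- function(de_genes, diff_peaks, assignment, re_per_peak = empty_hits()) {
  rows <- list()
  for (i in seq_len(nrow(diff_peaks))) {
    pid <- diff_peaks$peak_id[i]
    if (!pid %in% names(assignment)) {
      stop("assignment does not cover differential peak ", pid)
    }
    linked <- intersect(assignment[[pid]], de_genes$gene_id)
    if (!length(linked)) next
    j <- match(pid, re_per_peak$peak_id)
    has_re <- !is.na(j)
    fl <- if (has_re) annotate_signature(re_per_peak$site20[j]) else
      data.frame(C4 = NA, G7 = NA, C9 = NA, G12 = NA, C14 = NA, G17 = NA,
                 concurrent_c9_g12 = NA, conserved_deviation = NA)
    for (g in linked) {
      k <- match(g, de_genes$gene_id)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(
          gene_id = g, peak_id = pid,
          direction = de_genes$direction[k],
          rna_log2fc = de_genes$log2fc[k],
          chip_fold = diff_peaks$chip_fold[i],
          re_present = has_re,
          re_site20 = if (has_re) re_per_peak$site20[j] else NA_character_,
          re_score = if (has_re) re_per_peak$score[j] else NA_real_,
          re_strand = if (has_re) re_per_peak$strand[j] else NA_character_,
          re_spacer_len = if (has_re) re_per_peak$spacer_len[j] else NA_integer_,
          stringsAsFactors = FALSE
        ),
        fl
      )
    }
  }
  if (!length(rows)) {
    out <- cbind(
      data.frame(gene_id = character(), peak_id = character(),
                 direction = character(), rna_log2fc = numeric(),
                 chip_fold = numeric(), re_present = logical(),
                 re_site20 = character(), re_score = numeric(),
                 re_strand = character(), re_spacer_len = integer(),
                 stringsAsFactors = FALSE),
      annotate_signature(character())
    )
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
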