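# Seeded generators emulating the study's inputs: RE sets with controlled
# per-position base probabilities, peak sequences with embedded REs and
# condition-dependent binding signals, expression tables with planted
# differential genes, and a complete integration scenario.
#
# All randomness goes through R's Mersenne-Twister generator with the
# standard inversion/rejection settings, pinned explicitly so fixed seeds
# give byte-identical output across platforms and R versions.

with_sim_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(expr)
}

validate_probs <- function(probs) {
  probs <- as.matrix(probs)
  if (!identical(dim(probs), c(20L, 4L))) {
    stop("base probabilities must be a 20 x 4 matrix (positions x A/C/G/T)")
  }
  if (is.null(colnames(probs))) colnames(probs) <- DNA_BASES
  probs <- probs[, DNA_BASES, drop = FALSE]
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-9)) {
    stop("every probability row must be nonnegative and sum to 1")
  }
  probs
}

#' Per-position base probabilities for simulated response elements
#'
#' Builds the 20 x 4 probability table the RE generator samples from. All
#' positions follow the consensus with a small off-consensus 'slip'
#' probability; the signature positions 9 (pyrimidine) and 12 (purine) are
#' overridden so that P(C at 9) = `p_c9` and P(G at 12) = `p_g12`, with the
#' remaining allowed mass on the alternative consensus base. The defaults
#' reproduce the iASPP-regulated RE set (73.1% C9, 73.1% G12); use
#' `re_base_probs(0.572, 0.560)` for the Nutlin-induced comparison set.
#'
#' @param p_c9 probability of C at position 9.
#' @param p_g12 probability of G at position 12.
#' @param slip total probability of off-consensus bases per position.
#' @return A 20 x 4 matrix of row-stochastic base probabilities.
#' @export
re_base_probs <- function(p_c9 = 0.731, p_g12 = 0.731, slip = 0.005) {
  if (slip < 0 || slip >= 0.5) stop("'slip' must be in [0, 0.5)")
  if (p_c9 < 0 || p_c9 > 1 - slip || p_g12 < 0 || p_g12 > 1 - slip) {
    stop("signature probabilities must lie in [0, 1 - slip]")
  }
  allowed20 <- c(HALF_SITE_ALLOWED, HALF_SITE_ALLOWED)
  probs <- t(vapply(allowed20, function(allowed) {
    row <- rep(slip / (4L - length(allowed)), 4L)
    names(row) <- DNA_BASES
    row[allowed] <- (1 - slip) / length(allowed)
    row
  }, numeric(4L)))
  probs[9L, ] <- c(A = slip / 2, C = p_c9, G = slip / 2, T = 1 - p_c9 - slip)
  probs[12L, ] <- c(A = 1 - p_g12 - slip, C = slip / 2, G = p_g12, T = slip / 2)
  rownames(probs) <- as.character(1:20)
  validate_probs(probs)
}

draw_sites <- function(n, probs) {
  probs <- validate_probs(probs)
  if (n == 0L) return(character())
  cols <- lapply(1:20, function(p) sample(DNA_BASES, n, replace = TRUE, prob = probs[p, ]))
  do.call(paste0, cols)
}

#' Simulate two response-element sets
#'
#' Draws each 20-mer column-independently from its condition's per-position
#' base probabilities. At the study's set sizes (208 and 1,290) and C9/G12
#' probabilities (0.731/0.731 versus 0.572/0.560) the downstream enrichment
#' stage recovers the planted signature.
#'
#' @param n_a,n_b set sizes.
#' @param base_probs_a,base_probs_b 20 x 4 probability tables (see
#'   [re_base_probs()]).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return List with `sites_a`, `sites_b`, and a `truth` list recording the
#'   generating parameters.
#' @export
simulate_re_sets <- function(n_a, n_b,
                             base_probs_a = re_base_probs(0.731, 0.731),
                             base_probs_b = re_base_probs(0.572, 0.560),
                             seed = NULL) {
  base_probs_a <- validate_probs(base_probs_a)
  base_probs_b <- validate_probs(base_probs_b)
  with_sim_seed(seed, {
    list(
      sites_a = draw_sites(n_a, base_probs_a),
      sites_b = draw_sites(n_b, base_probs_b),
      truth = list(n_a = n_a, n_b = n_b, base_probs_a = base_probs_a,
                   base_probs_b = base_probs_b, seed = seed)
    )
  })
}

#' Simulate peak sequences with embedded response elements and signals
#'
#' Backgrounds are i.i.d. bases at the configured GC content. Each peak,
#' except a configurable number left empty, receives one RE drawn from
#' `base_probs`, with a spacer drawn from `spacer_probs` filled with
#' background bases, inserted at a uniform offset on a random strand.
#' Binding signals are log-normal around a planted test/control fold:
#' `signal_fold` for the first `n_differential` peaks and 1 for the rest.
#'
#' @param n_peaks number of peaks.
#' @param n_no_re how many peaks (chosen at random) carry no embedded RE;
#'   with the default scanner threshold these peaks are dropped by
#'   [scan_peaks()], emulating RE-less peaks in real data (208 REs from 214
#'   peaks).
#' @param n_differential how many peaks receive the planted signal fold.
#' @param peak_length peak width in bp; must fit the RE plus the longest
#'   spacer.
#' @param gc background GC content.
#' @param base_probs 20 x 4 RE base probabilities.
#' @param spacer_probs named numeric vector: spacer lengths (names) and
#'   their probabilities.
#' @param signal_fold planted test/control binding fold for differential
#'   peaks.
#' @param noise_sd standard deviation of log-normal multiplicative signal
#'   noise.
#' @param chrom,prefix cosmetic naming of the emitted intervals.
#' @param seed integer seed, or `NULL`.
#' @return List with `sequences` (named character), `peaks` (BED6+2-style
#'   data frame: `chrom`, `start`, `end`, `peak_id`, `score`, `strand`,
#'   `signal_test`, `signal_ctrl`), and `truth` (per-peak data frame with
#'   the planted RE offset, strand, spacer, site and differential status).
#' @export
simulate_peaks <- function(n_peaks = 214L, n_no_re = 6L, n_differential = n_peaks,
                           peak_length = 200L, gc = 0.41,
                           base_probs = re_base_probs(),
                           spacer_probs = c("0" = 0.7, "1" = 0.1, "2" = 0.1, "3" = 0.1),
                           signal_fold = 3, noise_sd = 0.1,
                           chrom = "chrS", prefix = "peak", seed = NULL) {
  base_probs <- validate_probs(base_probs)
  if (n_no_re > n_peaks) stop("'n_no_re' cannot exceed 'n_peaks'")
  if (n_differential > n_peaks) stop("'n_differential' cannot exceed 'n_peaks'")
  spacers <- as.integer(names(spacer_probs))
  if (anyNA(spacers) || any(spacers < 0)) stop("'spacer_probs' names must be spacer lengths")
  if (abs(sum(spacer_probs) - 1) > 1e-9) stop("'spacer_probs' must sum to 1")
  if (peak_length < 20L + max(spacers)) {
    stop("RE longer than peak: 'peak_length' must be at least 20 + the longest spacer")
  }
  bg_prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

  with_sim_seed(seed, {
    peak_ids <- sprintf("%s_%04d", prefix, seq_len(n_peaks))
    no_re <- rep(FALSE, n_peaks)
    if (n_no_re > 0L) no_re[sample.int(n_peaks, n_no_re)] <- TRUE
    differential <- seq_len(n_peaks) <= n_differential

    sequences <- character(n_peaks)
    truth <- data.frame(
      peak_id = peak_ids, has_re = !no_re, offset = NA_integer_,
      strand = NA_character_, spacer_len = NA_integer_,
      site20 = NA_character_, differential = differential,
      stringsAsFactors = FALSE
    )
    for (i in seq_len(n_peaks)) {
      bases <- sample(DNA_BASES, peak_length, replace = TRUE, prob = bg_prob)
      if (!no_re[i]) {
        s <- spacers[sample.int(length(spacers), 1L, prob = spacer_probs)]
        site <- draw_sites(1L, base_probs)
        strand <- sample(c("+", "-"), 1L)
        elem <- paste0(
          substr(site, 1L, 10L),
          paste(sample(DNA_BASES, s, replace = TRUE, prob = bg_prob), collapse = ""),
          substr(site, 11L, 20L)
        )
        if (strand == "-") elem <- revcomp(elem)
        off <- sample.int(peak_length - (20L + s) + 1L, 1L) - 1L
        bases[(off + 1L):(off + 20L + s)] <- strsplit(elem, "", fixed = TRUE)[[1L]]
        truth$offset[i] <- off
        truth$strand[i] <- strand
        truth$spacer_len[i] <- s
        truth$site20[i] <- site
      }
      sequences[i] <- paste(bases, collapse = "")
    }
    names(sequences) <- peak_ids

    base_signal <- stats::rlnorm(n_peaks, meanlog = log(20), sdlog = 0.3)
    fold <- ifelse(differential, signal_fold, 1)
    signal_ctrl <- base_signal * exp(stats::rnorm(n_peaks, 0, noise_sd))
    signal_test <- base_signal * fold * exp(stats::rnorm(n_peaks, 0, noise_sd))

    peaks <- data.frame(
      chrom = chrom,
      start = (seq_len(n_peaks) - 1L) * (peak_length + 100L),
      end = (seq_len(n_peaks) - 1L) * (peak_length + 100L) + peak_length,
      peak_id = peak_ids, score = 0L, strand = ".",
      signal_test = signal_test, signal_ctrl = signal_ctrl,
      stringsAsFactors = FALSE
    )
    list(sequences = sequences, peaks = peaks, truth = truth)
  })
}

#' Simulate a differential-expression table with planted effects
#'
#' Planted up/down genes receive FPKM + 1 fold changes of at least
#' `effect_fold` (strictly above the published cutoff of 2) with FDR drawn
#' below 0.05; null genes get fold changes within (0.64, 1.57) and FDR
#' uniform on (0.05, 1], so [filter_de_genes()] at the published thresholds
#' recovers exactly the planted set.
#'
#' @param n_up,n_down,n_null planted up-regulated, down-regulated, and null
#'   gene counts (defaults mirror the study: 194 up, 281 down).
#' @param effect_fold minimum planted FPKM + 1 fold change.
#' @param prefix gene-id prefix.
#' @param seed integer seed, or `NULL`.
#' @return List with `table` (data frame: `gene_id`, `fpkm_ctrl`,
#'   `fpkm_test`, `log2fc`, `fdr`) and `truth` (per-gene planted status).
#' @export
simulate_de_table <- function(n_up = 194L, n_down = 281L, n_null = 4525L,
                              effect_fold = 4, prefix = "gene", seed = NULL) {
  if (n_up < 0 || n_down < 0 || n_null < 0) stop("gene counts must be nonnegative")
  if (effect_fold <= 1) stop("'effect_fold' must exceed 1")
  n <- n_up + n_down + n_null
  status <- c(rep("up", n_up), rep("down", n_down), rep("null", n_null))

  with_sim_seed(seed, {
    fpkm_ctrl <- numeric(n)
    fpkm_test <- numeric(n)
    is_up <- status == "up"
    is_down <- status == "down"
    is_null <- status == "null"

    fpkm_ctrl[is_up] <- stats::rlnorm(n_up, log(5), 1)
    fold_up <- effect_fold * stats::runif(n_up, 1, 1.5)
    fpkm_test[is_up] <- fold_up * (fpkm_ctrl[is_up] + 1) - 1

    # strongly down-regulated genes need expression to lose
    fpkm_ctrl[is_down] <- stats::rlnorm(n_down, log(30), 0.6) + 5
    fold_down <- effect_fold * stats::runif(n_down, 1, 1.5)
    fpkm_test[is_down] <- (fpkm_ctrl[is_down] + 1) / fold_down - 1

    fpkm_ctrl[is_null] <- stats::rlnorm(n_null, log(5), 1.2)
    r <- exp(stats::runif(n_null, -0.45, 0.45))
    fpkm_test[is_null] <- pmax(0, r * (fpkm_ctrl[is_null] + 1) - 1)

    fdr <- numeric(n)
    fdr[!is_null] <- stats::runif(n_up + n_down, 0, 0.0499)
    fdr[is_null] <- stats::runif(n_null, 0.05, 1)

    ord <- sample.int(n)
    tab <- data.frame(
      gene_id = sprintf("%s_%05d", prefix, seq_len(n)),
      fpkm_ctrl = fpkm_ctrl[ord], fpkm_test = fpkm_test[ord],
      fdr = fdr[ord], stringsAsFactors = FALSE
    )
    tab$log2fc <- log2((tab$fpkm_test + 1) / (tab$fpkm_ctrl + 1))
    tab <- tab[, c("gene_id", "fpkm_ctrl", "fpkm_test", "log2fc", "fdr")]
    truth <- data.frame(gene_id = tab$gene_id, status = status[ord],
                        stringsAsFactors = FALSE)
    list(table = tab, truth = truth)
  })
}

#' Simulate a full binding/expression integration scenario
#'
#' Builds the fixture on which the target-gene intersection is exercised:
#' 13 regulated genes on one chromosome, two of which (the 12th and 13th)
#' have overlapping bodies sharing a single peak, covered by 12 peaks with
#' planted differential binding; decoy peaks with unchanged signal sit in
#' decoy genes elsewhere. Nine of the 12 differential peaks carry an RE
#' with both C9 and G12; the remaining three (including the shared peak)
#' carry T9/A12 elements. The expression table plants the 13 genes among
#' `n_up` up-regulated genes, alongside `n_down` down-regulated and
#' `n_null` null genes.
#'
#' @param n_up,n_down,n_null planted DE composition (defaults 194/281, as
#'   in the study).
#' @param n_decoy_peaks non-differential peaks placed in decoy genes.
#' @param peak_length peak width in bp.
#' @param signal_fold,noise_sd planted binding fold and log-normal noise.
#' @param tss_window kept with the scenario for bookkeeping; assignment is
#'   by gene-body overlap here.
#' @param seed integer seed, or `NULL`.
#' @return List with `models` (gene models), `peaks` (with signals),
#'   `sequences` (named peak sequences), `de` (expression table), and
#'   `truth` (planted structure, including the ids of the 13 target genes
#'   and the number of concurrent-signature REs).
#' @export
simulate_iptg_scenario <- function(n_up = 194L, n_down = 281L, n_null = 4525L,
                                   n_decoy_peaks = 8L, peak_length = 200L,
                                   signal_fold = 3, noise_sd = 0.1,
                                   tss_window = 5000, seed = NULL) {
  if (n_up < 13L) stop("'n_up' must be at least 13 to host the target genes")
  with_sim_seed(seed, {
    target_genes <- sprintf("TG%02d", 1:13)
    # genes 1..11 disjoint; genes 12 and 13 overlap and share peak 12
    g_start <- c((0:10) * 100000L, 1100000L, 1115000L)
    g_end <- c((0:10) * 100000L + 20000L, 1130000L, 1145000L)
    models <- data.frame(
      gene_id = target_genes, chrom = "chrS",
      start = g_start, end = g_end,
      strand = rep(c("+", "-"), length.out = 13L),
      stringsAsFactors = FALSE
    )
    pk_start <- c(g_start[1:11] + 10000L, 1120000L)
    peaks <- data.frame(
      chrom = "chrS", start = pk_start, end = pk_start + peak_length,
      peak_id = sprintf("dpk_%02d", 1:12), score = 0L, strand = ".",
      stringsAsFactors = FALSE
    )
    if (n_decoy_peaks > 0L) {
      d_start <- (seq_len(n_decoy_peaks) - 1L) * 100000L
      decoy_models <- data.frame(
        gene_id = sprintf("DG%02d", seq_len(n_decoy_peaks)), chrom = "chrD",
        start = d_start, end = d_start + 20000L, strand = "+",
        stringsAsFactors = FALSE
      )
      decoy_peaks <- data.frame(
        chrom = "chrD", start = d_start + 10000L,
        end = d_start + 10000L + peak_length,
        peak_id = sprintf("npk_%02d", seq_len(n_decoy_peaks)),
        score = 0L, strand = ".", stringsAsFactors = FALSE
      )
      models <- rbind(models, decoy_models)
      peaks <- rbind(peaks, decoy_peaks)
    }

    # embedded REs: peaks 1..9 carry C9+G12, peaks 10..12 carry T9+A12
    concurrent <- c(rep(TRUE, 9L), rep(FALSE, 3L), rep(FALSE, n_decoy_peaks))
    sites <- character(nrow(peaks))
    sites[concurrent] <- draw_sites(sum(concurrent), re_base_probs(1, 1, slip = 0))
    sites[!concurrent] <- draw_sites(sum(!concurrent), re_base_probs(0, 0, slip = 0))
    bg_prob <- c(0.295, 0.205, 0.205, 0.295)
    sequences <- vapply(seq_len(nrow(peaks)), function(i) {
      bases <- sample(DNA_BASES, peak_length, replace = TRUE, prob = bg_prob)
      off <- sample.int(peak_length - 20L + 1L, 1L) - 1L
      bases[(off + 1L):(off + 20L)] <- strsplit(sites[i], "", fixed = TRUE)[[1L]]
      paste(bases, collapse = "")
    }, character(1L))
    names(sequences) <- peaks$peak_id

    n_pk <- nrow(peaks)
    differential <- c(rep(TRUE, 12L), rep(FALSE, n_decoy_peaks))
    base_signal <- stats::rlnorm(n_pk, log(20), 0.3)
    peaks$signal_ctrl <- base_signal * exp(stats::rnorm(n_pk, 0, noise_sd))
    peaks$signal_test <- base_signal * ifelse(differential, signal_fold, 1) *
      exp(stats::rnorm(n_pk, 0, noise_sd))

    de <- simulate_de_table(n_up = n_up, n_down = n_down, n_null = n_null,
                            seed = NULL)
    up_ids <- de$truth$gene_id[de$truth$status == "up"]
    relabel <- stats::setNames(target_genes, up_ids[1:13])
    hit <- de$table$gene_id %in% names(relabel)
    de$table$gene_id[hit] <- relabel[de$table$gene_id[hit]]
    de$truth$gene_id[hit] <- de$table$gene_id[hit]

    list(
      models = models, peaks = peaks, sequences = sequences,
      de = de$table,
      truth = list(
        target_genes = target_genes, de_truth = de$truth,
        peak_sites = stats::setNames(sites, peaks$peak_id),
        differential_peaks = peaks$peak_id[differential],
        n_concurrent = 9L, shared_peak = "dpk_12",
        shared_genes = c("TG12", "TG13"), tss_window = tss_window
      )
    )
  })
}
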