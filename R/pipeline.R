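# End-to-end driver: simulate (or ingest) -> scan -> enrich -> integrate,
# writing every stage as TSV plus a JSON run log.

#' Run the full analysis pipeline on simulated inputs
#'
#' Executes the published analysis order on seeded synthetic data: two peak
#' sets are simulated (a small condition-elevated set and a larger
#' comparison set), response elements are predicted with the half-site PWM
#' keeping the best RE per peak, per-position and concurrent C9/G12
#' enrichment is tested between the two RE sets, and differential binding
#' is intersected with differential expression on the integration fixture
#' to call regulated target genes. All tables are written to `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving every stage.
#' @param n_peaks_a,n_no_re_a peak count and RE-less peak count for the
#'   test condition (defaults 214 and 6).
#' @param n_peaks_b,n_no_re_b same for the comparison condition (defaults
#'   1328 and 38).
#' @param pfm half-site PFM used for scanning.
#' @param pseudocount,background PWM construction parameters.
#' @param spacer_range,min_score scanner parameters ([scan_re()]).
#' @param fold_threshold,pseudo differential-binding filter parameters.
#' @param fdr_max,fold_min expression filter parameters.
#' @param tss_window peak-to-gene TSS window in bp.
#' @param m_tests Bonferroni family size for position enrichment.
#' @param base_probs_a,base_probs_b per-position RE base probabilities per
#'   condition.
#' @return Invisibly, a list with every intermediate result (`hits_a`,
#'   `hits_b`, `enrichment`, `concurrent`, `de_genes`, `diff_peaks`,
#'   `iptgs`, ...).
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         n_peaks_a = 214L, n_no_re_a = 6L,
                         n_peaks_b = 1328L, n_no_re_b = 38L,
                         pfm = build_default_pfm(),
                         pseudocount = 1, background = rep(0.25, 4),
                         spacer_range = c(0L, 13L), min_score = NULL,
                         fold_threshold = 2, pseudo = 1,
                         fdr_max = 0.05, fold_min = 2,
                         tss_window = 5000, m_tests = 80L,
                         base_probs_a = re_base_probs(0.731, 0.731),
                         base_probs_b = re_base_probs(0.572, 0.560)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pwm <- pfm_to_pwm(pfm, pseudocount = pseudocount, background = background)

  sim_a <- simulate_peaks(n_peaks = n_peaks_a, n_no_re = n_no_re_a,
                          base_probs = base_probs_a, prefix = "peakA",
                          seed = seed)
  sim_b <- simulate_peaks(n_peaks = n_peaks_b, n_no_re = n_no_re_b,
                          base_probs = base_probs_b, prefix = "peakB",
                          seed = seed + 1L)

  hits_a <- scan_peaks(sim_a$sequences, pwm, spacer_range = spacer_range,
                       min_score = min_score)
  hits_b <- scan_peaks(sim_b$sequences, pwm, spacer_range = spacer_range,
                       min_score = min_score)

  counts_a <- count_nucleotides(hits_a$site20, label = "condition_a")
  counts_b <- count_nucleotides(hits_b$site20, label = "condition_b")
  enrichment <- position_enrichment(counts_a, counts_b, m_tests = m_tests)
  concurrent <- concurrent_enrichment(hits_a$site20, hits_b$site20)

  scen <- simulate_iptg_scenario(seed = seed + 2L, tss_window = tss_window)
  de_genes <- filter_de_genes(scen$de, fdr_max = fdr_max, fold_min = fold_min)
  diff_peaks <- call_differential_peaks(scen$peaks, fold_threshold = fold_threshold,
                                        pseudo = pseudo)
  assignment <- assign_peaks_to_genes(scen$peaks, scen$models, tss_window = tss_window)
  re_per_peak <- scan_peaks(scen$sequences, pwm, spacer_range = spacer_range,
                            min_score = min_score)
  iptgs <- call_iptgs(de_genes, diff_peaks, assignment, re_per_peak)

  write_fasta(sim_a$sequences, file.path(out_dir, "peaks_a.fasta"))
  write_fasta(sim_b$sequences, file.path(out_dir, "peaks_b.fasta"))
  write_peaks_bed(sim_a$peaks, file.path(out_dir, "peaks_a.bed"))
  write_peaks_bed(sim_b$peaks, file.path(out_dir, "peaks_b.bed"))
  write_hits_tsv(hits_a, file.path(out_dir, "hits_a.tsv"))
  write_hits_tsv(hits_b, file.path(out_dir, "hits_b.tsv"))
  write_tsv(to_logo_matrix(counts_a), file.path(out_dir, "logo_a.tsv"))
  write_tsv(to_logo_matrix(counts_b), file.path(out_dir, "logo_b.tsv"))
  write_tsv(enrichment, file.path(out_dir, "position_enrichment.tsv"))
  write_tsv(concurrent, file.path(out_dir, "concurrent_c9_g12.tsv"))
  write_tsv(de_genes, file.path(out_dir, "de_genes.tsv"))
  write_tsv(diff_peaks, file.path(out_dir, "differential_peaks.tsv"))
  write_tsv(iptgs, file.path(out_dir, "iptgs.tsv"))

  log <- list(
    package = "p53resig",
    version = as.character(utils::packageVersion("p53resig")),
    r_version = R.version.string,
    seed = seed,
    config = list(
      n_peaks_a = n_peaks_a, n_no_re_a = n_no_re_a,
      n_peaks_b = n_peaks_b, n_no_re_b = n_no_re_b,
      pseudocount = pseudocount,
      min_score = if (is.null(min_score)) 0.8 * pwm$max_score else min_score,
      spacer_range = spacer_range, fold_threshold = fold_threshold,
      pseudo = pseudo, fdr_max = fdr_max, fold_min = fold_min,
      tss_window = tss_window, m_tests = m_tests
    )
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    pwm = pwm, sim_a = sim_a, sim_b = sim_b,
    hits_a = hits_a, hits_b = hits_b,
    counts_a = counts_a, counts_b = counts_b,
    enrichment = enrichment, concurrent = concurrent,
    scenario = scen, de_genes = de_genes, diff_peaks = diff_peaks,
    assignment = assignment, iptgs = iptgs
  ))
}
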