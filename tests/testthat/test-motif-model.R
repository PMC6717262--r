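# Half-site PFM construction, log-odds conversion, and RE scanning.

test_that("default PFM splits probability mass by consensus degeneracy", {
  pfm0 <- build_default_pfm(0)
  expect_equal(unname(pfm0$counts[, 4]), c(0, 1, 0, 0)) # fixed C position
  expect_equal(unname(pfm0$counts[, 7]), c(0, 0, 1, 0)) # fixed G position

  pfm <- build_default_pfm(0.04)
  expect_equal(unname(pfm$counts[, 1]), c(0.48, 0.02, 0.48, 0.02)) # purine
  expect_equal(unname(pfm$counts[, 5]), c(0.48, 0.02, 0.02, 0.48)) # A/T
  expect_equal(unname(colSums(pfm$counts)), rep(1, 10))

  expect_error(build_default_pfm(0.5), "probability")
  expect_error(build_default_pfm(-0.01), "probability")
})

test_that("log-odds weights match an independently coded formula", {
  uniform <- half_site_pfm(matrix(1, 4, 10))
  pwm <- pfm_to_pwm(uniform, pseudocount = 0)
  expect_equal(unname(pwm$weights), matrix(0, 4, 20))

  pure <- matrix(1, 4, 10)
  pure[, 1] <- c(1, 0, 0, 0)
  pwm <- pfm_to_pwm(half_site_pfm(pure), pseudocount = 0)
  expect_equal(unname(pwm$weights["A", 1]), 2) # log2(1 / 0.25)

  pfm <- build_default_pfm(0.04)
  pwm <- pfm_to_pwm(pfm, pseudocount = 1)
  set.seed(31)
  for (j in sample(1:10, 3)) {
    expect_equal(unname(pwm$weights[, j]),
                 unname(oracle_log_odds(pfm$counts[, j], 1, rep(0.25, 4))),
                 tolerance = 1e-12)
    # both half sites share the model
    expect_equal(pwm$weights[, j], pwm$weights[, j + 10], ignore_attr = TRUE)
  }

  degenerate <- structure(list(counts = matrix(c(rep(1, 8), 0, 0, 0, 0, rep(1, 28)),
                                               4, 10,
                                               dimnames = list(BASES4, NULL)),
                               name = "bad"),
                          class = "half_site_pfm")
  expect_error(pfm_to_pwm(degenerate, pseudocount = 0), "degenerate")
  expect_error(pfm_to_pwm(build_default_pfm(), background = c(0.3, 0.3, 0.3, 0.3)),
               "sum to 1")
})

test_that("the consensus 20-mer attains the global maximum PWM score", {
  for (eps in c(0, 0.04, 0.2)) {
    pwm <- pfm_to_pwm(build_default_pfm(eps))
    cons <- strsplit(consensus_sequence(), "", fixed = TRUE)[[1L]]
    for (j in 1:20) {
      expect_equal(pwm$weights[cons[j], j], max(pwm$weights[, j]),
                   ignore_attr = TRUE)
    }
    expect_equal(score_site20(consensus_sequence(), pwm), pwm$max_score)
  }
  # no random 20-mer beats it
  pwm <- default_pwm()
  set.seed(17)
  rand <- replicate(500, random_dna(20))
  expect_true(all(score_site20(rand, pwm) <= pwm$max_score + 1e-12))
})

test_that("scanning recovers a planted consensus element at the maximal score", {
  pwm <- default_pwm()
  set.seed(11)
  peak <- paste0(random_dna(60), consensus_sequence(), random_dna(40))
  best <- best_hit_per_peak(scan_re(peak, pwm, peak_id = "pk"))
  expect_equal(best$start, 60L)
  expect_equal(best$spacer_len, 0L)
  expect_equal(best$score, pwm$max_score)
  expect_equal(best$site20, consensus_sequence())
})

test_that("scan scores are invariant under reverse complement of the peak", {
  pwm <- default_pwm()
  set.seed(12)
  peak <- paste0(random_dna(30), consensus_sequence(), random_dna(25))
  h1 <- scan_re(peak, pwm, spacer_range = c(0, 5), min_score = -1e6)
  h2 <- scan_re(oracle_revcomp(peak), pwm, spacer_range = c(0, 5), min_score = -1e6)
  expect_equal(sort(h1$score), sort(h2$score), tolerance = 1e-9)
  expect_equal(best_hit_per_peak(h1)$score, best_hit_per_peak(h2)$score,
               tolerance = 1e-12)
})

test_that("a planted spacer-3 element is found where brute force says it is", {
  pwm <- default_pwm()
  set.seed(13)
  bg <- random_dna(200)
  element <- paste0(substr(consensus_sequence(), 1, 10), "ACG",
                    substr(consensus_sequence(), 11, 20))
  seqn <- paste0(substr(bg, 1, 100), element, substr(bg, 124, 200))
  hits <- scan_re(seqn, pwm)
  best <- best_hit_per_peak(hits)
  expect_equal(best$start, 100L)
  expect_equal(best$spacer_len, 3L)

  oracle <- oracle_scan_all(seqn, pwm, spacers = 0:13)
  expect_equal(best$score, max(oracle$score), tolerance = 1e-9)
  # scores agree candidate by candidate on a random subset
  full <- scan_re(seqn, pwm, min_score = -1e6)
  set.seed(14)
  idx <- sample(nrow(oracle), 50)
  key <- function(d) paste(d$start, d$strand, d$spacer_len)
  m <- match(key(oracle[idx, ]), key(full))
  expect_false(anyNA(m))
  expect_equal(full$score[m], oracle$score[idx], tolerance = 1e-9)
  expect_equal(full$site20[m], oracle$site20[idx])
})

test_that("N bases are background-neutral and bad characters are rejected", {
  pwm <- default_pwm()
  cons <- consensus_sequence()
  with_n <- paste0("N", substr(cons, 2, 20))
  expect_equal(score_site20(with_n, pwm),
               pwm$max_score - pwm$weights["G", 1], ignore_attr = TRUE)
  expect_equal(score_site20(with_n, pwm), oracle_score(with_n, pwm))
  expect_error(scan_re(paste0(cons, "AXGT"), pwm), "offset 22")
  expect_error(score_site20("ACGTACGTACGTACGTACG", pwm), "20")
})

test_that("rescoring a returned site20 reproduces its stored score", {
  pwm <- default_pwm()
  sim <- simulate_peaks(n_peaks = 15, n_no_re = 0, seed = 21)
  hits <- do.call(rbind, lapply(names(sim$sequences), function(id) {
    scan_re(sim$sequences[[id]], pwm, peak_id = id)
  }))
  expect_gt(nrow(hits), 0)
  expect_equal(hits$score, score_site20(hits$site20, pwm), tolerance = 1e-9)
})

test_that("best-hit tie-breaking is by start, then strand, then spacer", {
  h <- data.frame(
    peak_id = "p", start = c(9L, 5L), strand = "+", spacer_len = 0L,
    score = 3.5, site20 = consensus_sequence(), stringsAsFactors = FALSE
  )
  expect_equal(best_hit_per_peak(h)$start, 5L)
  h$start <- 5L
  h$strand <- c("-", "+")
  expect_equal(best_hit_per_peak(h)$strand, "+")
  h$strand <- "+"
  h$spacer_len <- c(4L, 2L)
  expect_equal(best_hit_per_peak(h)$spacer_len, 2L)

  expect_null(best_hit_per_peak(h[0, ]))
  h$peak_id <- c("p", "q")
  expect_error(best_hit_per_peak(h), "one peak_id")

  single <- h[1, ]
  single$peak_id <- "p"
  expect_equal(best_hit_per_peak(single), single, ignore_attr = TRUE)
})

test_that("raising min_score never increases the number of peaks with an RE", {
  pwm <- default_pwm()
  sim <- simulate_peaks(n_peaks = 30, n_no_re = 5, seed = 22)
  thresholds <- seq(0.5, 1.05, by = 0.05) * pwm$max_score
  n_peaks <- vapply(thresholds, function(th) {
    nrow(scan_peaks(sim$sequences, pwm, min_score = th))
  }, numeric(1))
  expect_true(all(diff(n_peaks) <= 0))
  expect_equal(n_peaks[length(n_peaks)], 0) # above the maximum: nothing
})
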