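# Nucleotide counting, logo tables, Fisher's exact test, and per-position /
# concurrent enrichment between RE sets.

test_that("nucleotide counts are per position, with N counting toward no base", {
  m <- count_nucleotides(consensus_sequence())
  expect_equal(unname(m$counts[9, ]), c(0, 1, 0, 0))
  expect_equal(unname(m$counts[12, ]), c(0, 0, 1, 0))
  expect_equal(m$n, 1L)

  m0 <- count_nucleotides(character())
  expect_equal(sum(m0$counts), 0)
  expect_equal(m0$n, 0L)

  with_n <- paste0("N", substr(consensus_sequence(), 2, 20))
  mn <- count_nucleotides(c(consensus_sequence(), with_n))
  expect_equal(sum(mn$counts[1, ]), 1) # the N site contributes nothing at 1
  expect_equal(sum(mn$counts[2, ]), 2)

  expect_error(count_nucleotides(c(consensus_sequence(), "ACGT")), "site 2")
})

test_that("sampled column frequencies converge to their parameters", {
  x <- simulate_re_sets(1000, 0, base_probs_a = re_base_probs(0.731, 0.731),
                        seed = 41)
  m <- count_nucleotides(x$sites_a)
  sd9 <- sqrt(1000 * 0.731 * 0.269)
  expect_lt(abs(m$counts[9, "C"] - 731), 3 * sd9)
  expect_lt(abs(m$counts[12, "G"] - 731), 3 * sd9)
})

test_that("information content spans 0 to 2 bits as entropy dictates", {
  pure <- count_nucleotides(rep(strrep("A", 20), 3))
  expect_equal(to_logo_matrix(pure)$ic, rep(2, 20))

  uniform <- count_nucleotides(vapply(BASES4, strrep, "", times = 20))
  expect_equal(to_logo_matrix(uniform)$ic, rep(0, 20))

  half <- count_nucleotides(c(strrep("A", 20), strrep("C", 20)))
  lg <- to_logo_matrix(half)
  expect_equal(lg$ic, rep(1, 20))
  expect_equal(lg$A, rep(0.5, 20))

  expect_error(to_logo_matrix(count_nucleotides(character())), "empty")
})

test_that("two-tailed Fisher p-values match enumeration and the printed tables", {
  expect_equal(fisher_exact_two_tailed(1, 1, 1, 1), 1)
  expect_equal(fisher_exact_two_tailed(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)

  # the published C9 / G12 / concurrent comparisons, to 3 significant figures
  expect_equal(signif(fisher_exact_two_tailed(152, 56, 738, 552), 3), 1.30e-5)
  expect_equal(signif(fisher_exact_two_tailed(152, 56, 722, 568), 3), 2.38e-6)
  expect_equal(signif(fisher_exact_two_tailed(121, 87, 541, 749), 3), 1.63e-5)

  expect_error(fisher_exact_two_tailed(0, 0, 3, 4), "margin")
  expect_error(fisher_exact_two_tailed(1, -1, 1, 1), "nonnegative")

  # agreement with stats::fisher.test on random tables, large and small
  set.seed(42)
  for (i in 1:40) {
    t4 <- rpois(4, lambda = sample(c(3, 40, 700), 1)) + 1
    expect_equal(
      fisher_exact_two_tailed(t4[1], t4[2], t4[3], t4[4]),
      stats::fisher.test(matrix(t4, 2, byrow = TRUE))$p.value,
      tolerance = 1e-9
    )
  }
})

test_that("Fisher p is symmetric under row and column swaps", {
  set.seed(43)
  for (i in 1:20) {
    t4 <- rpois(4, 15) + 1
    p <- fisher_exact_two_tailed(t4[1], t4[2], t4[3], t4[4])
    expect_equal(fisher_exact_two_tailed(t4[3], t4[4], t4[1], t4[2]), p,
                 tolerance = 1e-12)
    expect_equal(fisher_exact_two_tailed(t4[2], t4[1], t4[4], t4[3]), p,
                 tolerance = 1e-12)
  }
})

test_that("identical RE sets give flat enrichment and valid Bonferroni bounds", {
  x <- simulate_re_sets(40, 0, seed = 44)
  m <- count_nucleotides(x$sites_a)
  enr <- position_enrichment(m, m)
  expect_equal(nrow(enr), 80L)
  expect_equal(enr$fold, rep(1, 80))
  expect_equal(enr$p, rep(1, 80))
  expect_true(all(enr$p_bonf >= enr$p))
  expect_true(all(enr$p_bonf <= 1))
  expect_true(all(enr$a + enr$b == m$n))
})

test_that("a single perturbed position is the only one flagged at n = 1000", {
  base <- re_base_probs(0.5, 0.5, slip = 0.02)
  shifted <- base
  shifted[5, ] <- c(A = 0.78, C = 0.01, G = 0.01, T = 0.20) # stronger A5
  alpha <- 0.05 / 80
  flagged5 <- 0
  others <- integer(0)
  for (s in 1:20) {
    x <- simulate_re_sets(1000, 1000, base_probs_a = shifted, base_probs_b = base,
                          seed = 500 + s)
    enr <- position_enrichment(count_nucleotides(x$sites_a),
                               count_nucleotides(x$sites_b))
    sig <- unique(enr$position[enr$p < alpha])
    if (5L %in% sig) flagged5 <- flagged5 + 1
    others <- c(others, setdiff(sig, 5L))
  }
  expect_gt(flagged5, 10) # majority of 20 seeds
  expect_true(all(tabulate(others, nbins = 20) < 10))
})

test_that("concurrent enrichment reproduces printed counts and degenerates safely", {
  # site lists realising the published 2x2 table for concurrent C9+G12
  with_sig <- consensus_sequence() # carries C9 and G12
  without <- edited_consensus(list(9, "T"))
  sites_a <- c(rep(with_sig, 121), rep(without, 87))
  sites_b <- c(rep(with_sig, 541), rep(without, 749))
  rec <- concurrent_enrichment(sites_a, sites_b)
  expect_equal(c(rec$a, rec$b, rec$c, rec$d), c(121, 87, 541, 749))
  expect_equal(round(rec$fold, 2), 1.39)
  expect_equal(signif(rec$p, 3), 1.63e-5)

  # a signature matched by no site in either set is degenerate
  none <- concurrent_enrichment(rep(without, 5), rep(without, 5),
                                signature_spec(9, "C"))
  expect_true(none$degenerate)
  expect_equal(none$fold, 1)

  # single-element signature agrees with the positionwise record
  x <- simulate_re_sets(120, 300, seed = 46)
  rec9 <- concurrent_enrichment(x$sites_a, x$sites_b, signature_spec(9, "C"))
  enr <- position_enrichment(count_nucleotides(x$sites_a),
                             count_nucleotides(x$sites_b))
  row9 <- enr[enr$position == 9 & enr$base == "C", ]
  expect_equal(c(rec9$a, rec9$b, rec9$c, rec9$d),
               c(row9$a, row9$b, row9$c, row9$d))
  expect_equal(rec9$p, row9$p)
  expect_equal(rec9$fold, row9$fold)
})

test_that("signature specs are validated", {
  expect_error(signature_spec(c(9, 9), c("C", "G")), "distinct")
  expect_error(signature_spec(21, "C"), "1..20")
  expect_error(signature_spec(9, "Z"), "base")
  expect_equal(signature_c9_g12()$position, c(9L, 12L))
  expect_true(matches_signature(consensus_sequence()))
  expect_false(matches_signature(edited_consensus(list(12, "A"))))
})
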