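# Dichotomization, 2x2 tabulation, agreement statistics, kappa and its
# delta-method confidence interval.

test_that("dichotomize applies the at-or-above convention", {
  expect_true(dichotomize(2, 2))
  expect_false(dichotomize(1, 2))
  expect_false(dichotomize(0, 1))
  expect_equal(dichotomize(0:6, 3), 0:6 >= 3)
  expect_error(dichotomize(2, 0), class = "mast_invalid_cutoff")
  expect_error(dichotomize(2, 7), class = "mast_invalid_cutoff")
})

test_that("tabulate_pairs partitions the pairs at every cutoff", {
  pairs <- data.frame(class_a = c(3, 0, 2), class_b = c(3, 0, 0))
  t2 <- tabulate_pairs(pairs, 2)
  expect_equal(unlist(t2[c("n_pp", "n_pn", "n_np", "n_nn")]),
               c(n_pp = 1, n_pn = 1, n_np = 0, n_nn = 1))
  t3 <- tabulate_pairs(pairs, 3)
  expect_equal(unlist(t3[c("n_pp", "n_nn")]), c(n_pp = 1, n_nn = 2))
  expect_equal(t3$N, 3)
  expect_error(tabulate_pairs(pairs[0, ], 2), class = "mast_empty_comparison")

  set.seed(99)
  rp <- random_pairs(1000)
  for (t in c(1L, 4L, 6L)) {
    expect_equal(tabulate_pairs(rp, t)$N, 1000)
  }
})

test_that("agreement and concordant positive rate reproduce published worked examples", {
  # reconstructed cells from printed N / agreement / CPR
  expect_equal(round_half_up(total_agreement(paired_table(0, 8, 0, 22)), 1), 73.3)
  expect_equal(round_half_up(total_agreement(paired_table(21, 1, 1, 20)), 1), 95.3)
  expect_equal(total_agreement(paired_table(5, 0, 0, 5)), 100)
  expect_equal(round_half_up(concordant_positive_rate(paired_table(22, 0, 0, 21)), 1), 51.2)
  expect_equal(round_half_up(concordant_positive_rate(paired_table(11, 16, 0, 66)), 1), 11.8)
  expect_equal(concordant_positive_rate(paired_table(0, 8, 0, 22)), 0)
  # exact complement identity
  set.seed(7)
  for (tab in all_tables(9)[sample(200, 25)]) {
    if (tab$N == 0) next
    expect_equal(total_agreement(tab) + 100 * (tab$n_pn + tab$n_np) / tab$N, 100)
    expect_gte(total_agreement(tab), concordant_positive_rate(tab))
  }
})

test_that("kappa matches published cells and the brute-force oracle on all tables N <= 12", {
  expect_equal(round_half_up(cohen_kappa(paired_table(21, 1, 1, 20)), 2), 0.91)
  expect_equal(round_half_up(cohen_kappa(paired_table(1, 1, 0, 41)), 2), 0.66)
  expect_identical(cohen_kappa(paired_table(0, 1, 0, 42)), 0)
  expect_equal(round_half_up(cohen_kappa(paired_table(0, 1, 1, 88)), 2), -0.01)
  # undefined exactly when all pairs concordant in one category
  expect_true(is.na(cohen_kappa(paired_table(0, 0, 0, 43))))
  expect_true(is.na(cohen_kappa(paired_table(43, 0, 0, 0))))
  expect_false(is.na(cohen_kappa(paired_table(20, 0, 0, 23))))
  expect_error(total_agreement(paired_table(0, 0, 0, 0)),
               class = "mast_empty_comparison")

  for (n in 1:12) {
    for (tab in all_tables(n)) {
      expect_equal(cohen_kappa(tab), oracle_kappa(tab), tolerance = 1e-12)
    }
  }
})

test_that("delta-method SE and untruncated CI reproduce published intervals", {
  tab <- paired_table(1, 1, 0, 41)
  k <- cohen_kappa(tab)
  se <- kappa_se(tab, k)
  expect_equal(se, 0.3192276, tolerance = 1e-6) # frozen independent-oracle value
  ci <- kappa_ci(k, se)
  expect_equal(round_half_up(ci, 2), c(low = 0.03, high = 1.28))
  expect_gt(ci[["high"]], 1) # untruncated by design
  expect_equal(kappa_ci(k, se, clip = TRUE)[["high"]], 1)

  tab2 <- paired_table(21, 1, 1, 20)
  ci2 <- kappa_ci(cohen_kappa(tab2), kappa_se(tab2))
  expect_equal(round_half_up(ci2, 2), c(low = 0.78, high = 1.03))

  ci3 <- kappa_ci(cohen_kappa(paired_table(0, 1, 1, 88)),
                  kappa_se(paired_table(0, 1, 1, 88)))
  expect_equal(round_half_up(ci3, 2), c(low = -0.03, high = 0.00))

  expect_equal(kappa_ci(0.5, 0), c(low = 0.5, high = 0.5))
  expect_true(all(is.na(kappa_se(paired_table(5, 0, 0, 0)))))
})

test_that("one-sided single-discordance tables with no concordant positives give kappa 0, SE 0", {
  # symbolic property: p_o = p_e = (N-1)/N, and the SE terms cancel exactly
  for (n in 2:100) {
    tab <- paired_table(0, 1, 0, n - 1)
    expect_identical(cohen_kappa(tab), 0)
    expect_equal(kappa_se(tab), 0, tolerance = 1e-12)
  }
})

test_that("kappa and SE are invariant under transposition; kappa = 1 iff no discordance", {
  set.seed(31)
  for (i in 1:50) {
    cells <- as.vector(stats::rmultinom(1, sample(5:60, 1), c(.3, .15, .1, .45)))
    tab <- paired_table(cells[1], cells[2], cells[3], cells[4])
    tt <- transpose_table(tab)
    expect_equal(cohen_kappa(tab), cohen_kappa(tt))
    expect_equal(kappa_se(tab), kappa_se(tt))
    k <- cohen_kappa(tab)
    if (!is.na(k)) {
      expect_equal(k == 1, tab$n_pn == 0 && tab$n_np == 0)
    }
  }
  # relabeling both categories (swap +/- on both sides) preserves kappa
  tab <- paired_table(21, 1, 1, 20)
  relabeled <- paired_table(20, 1, 1, 21)
  expect_equal(cohen_kappa(tab), cohen_kappa(relabeled))
})

test_that("summarize_agreement composes the full row and flags undefined kappa", {
  pairs <- pairs_for_allergen(
    build_pair_set(reference_fixture("dfarinae_food"), "alloscreen", "smart2",
                   "food"), "dermatophagoides farinae")
  s <- summarize_agreement(pairs, 2)
  expect_equal(s$n, 43)
  expect_equal(round_half_up(s$agreement_pct, 1), 95.3)
  expect_equal(round_half_up(s$concordant_positive_pct, 1), 48.8)
  expect_equal(round_half_up(s$kappa, 2), 0.91)
  expect_equal(round_half_up(c(s$ci_low, s$ci_high), 2), c(0.78, 1.03))
  expect_gte(s$agreement_pct, s$concordant_positive_pct)

  allneg <- data.frame(class_a = rep(0, 43), class_b = rep(0, 43))
  s2 <- summarize_agreement(allneg, 2)
  expect_equal(s2$agreement_pct, 100)
  expect_equal(s2$concordant_positive_pct, 0)
  expect_true(is.na(s2$kappa) && is.na(s2$ci_low))
})

test_that("agreement_report rounds only at the formatting layer", {
  ps <- build_pair_set(reference_fixture("dfarinae_food"), "alloscreen",
                       "smart2", "food")
  rep <- agreement_report(ps, 2)
  expect_equal(rep$agreement_pct, 4100 / 43) # full precision retained
  disp <- format_agreement_report(rep)
  expect_equal(disp$agreement_pct, "95.3")
  expect_equal(disp$kappa, "0.91")
  expect_equal(disp$ci_high, "1.03")
})
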