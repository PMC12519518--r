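test_that("confusion matches hand enumeration and isolates unknowns", {
  calls <- c("positive", "positive", "negative", "negative",
             "positive", "negative", "positive", "negative")
  amy <- c("positive", "negative", "negative", "positive",
           "unknown", "negative", "positive", "unknown")
  got <- confusion(calls, amy)
  want <- oracle_confusion(calls, amy)
  expect_equal(got$tp, want[["tp"]])
  expect_equal(got$fp, want[["fp"]])
  expect_equal(got$tn, want[["tn"]])
  expect_equal(got$fn, want[["fn"]])
  expect_equal(got$n_unknown, 2L)
  expect_equal(got$n_total, 8L)
  expect_equal(got$n_negative_calls, 4L)

  all_pos <- confusion(rep("positive", 5), rep("positive", 5))
  expect_equal(c(all_pos$tp, all_pos$fp, all_pos$tn, all_pos$fn),
               c(5L, 0L, 0L, 0L))
  expect_error(confusion("positive", c("positive", "negative")), "equal length")
})

test_that("metrics follow the printed formulas; zero denominators are undefined", {
  # pre-screening subset 1: 49 confirmed BBBM positives, 6 amyloid positive
  s1 <- agreement_metrics(confusion_counts(tp = 6, fp = 43, tn = 0, fn = 0))
  expect_equal(s1$ppv, 6 / 49)
  expect_equal(round(100 * s1$ppv, 1), 12.2)
  expect_equal(s1$npa, 0)                 # 43 amyloid negatives, all called positive
  expect_true(is.na(s1$one_minus_npv))    # no BBBM negatives in this subset
  # subset 2: 6 confirmed BBBM negatives, none amyloid positive
  s2 <- agreement_metrics(confusion_counts(tp = 0, fp = 0, tn = 6, fn = 0))
  expect_equal(s2$one_minus_npv, 0)
  expect_true(is.na(s2$ppv))

  none_pos <- agreement_metrics(confusion_counts(tp = 0, fp = 3, tn = 7, fn = 0))
  expect_equal(none_pos$prevalence, 0)
  expect_true(is.na(none_pos$ppa))

  # screen-out denominators: all BBBM-tested vs reference-confirmed
  g1 <- agreement_metrics(confusion_counts(tp = 6, fp = 43, tn = 6, fn = 0,
                                           n_negative_calls = 1585,
                                           n_total = 3432))
  expect_equal(g1$screen_out_rate, 1585 / 3432)
  expect_equal(g1$screen_out_confirmed, 6 / 55)
})

test_that("integer identities hold exactly for arbitrary counts", {
  set.seed(31)
  for (i in 1:25) {
    k <- rmultinom(1, 200, runif(4))[, 1]
    m <- agreement_metrics(confusion_counts(k[1], k[2], k[3], k[4]))
    n_known <- sum(k)
    expect_equal(m$prevalence * n_known, k[1] + k[4])
    if (!is.na(m$ppa)) expect_equal(m$ppa * (k[1] + k[4]), k[1])
    for (ci in m$ci) {
      if (!anyNA(ci)) expect_true(ci[["lower"]] <= ci[["upper"]])
    }
  }
})

test_that("Wilson intervals match an independent score-test inversion", {
  for (case in list(c(6, 49), c(1, 10), c(25, 50), c(199, 200))) {
    got <- wilson_ci(case[1], case[2])
    want <- oracle_wilson(case[1], case[2])
    expect_equal(got[["lower"]], want[["lower"]], tolerance = 1e-8)
    expect_equal(got[["upper"]], want[["upper"]], tolerance = 1e-8)
    phat <- case[1] / case[2]
    expect_true(got[["lower"]] <= phat && phat <= got[["upper"]])
  }
  expect_equal(wilson_ci(6, 49)[["lower"]], 0.0573, tolerance = 1e-3)
  expect_equal(wilson_ci(6, 49)[["upper"]], 0.2424, tolerance = 1e-3)
  expect_equal(wilson_ci(0, 6)[["lower"]], 0)
  expect_equal(wilson_ci(49, 49)[["upper"]], 1)
  expect_true(all(is.na(wilson_ci(0, 0))))
  expect_error(wilson_ci(5, 4), "successes")
})

test_that("metrics on a calibrated cohort recover the generator targets", {
  coh <- generate_cohort(skyline_group2_spec(n = 50000, seed = 77L))
  coh <- add_composite_amyloid(apply_rule(coh))
  rep <- agreement_metrics(confusion(coh$bbbm_call, coh$composite_amyloid))
  n_pos <- rep$counts$tp + rep$counts$fn
  n_neg <- rep$counts$tn + rep$counts$fp
  expect_lt(abs(rep$ppa - 0.946), 3 * sqrt(0.946 * 0.054 / n_pos))
  expect_lt(abs(rep$npa - 0.445), 3 * sqrt(0.445 * 0.555 / n_neg))
})
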