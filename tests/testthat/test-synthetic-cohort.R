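test_that("generate_cohort is deterministic under a fixed seed", {
  spec <- a4_spec(n = 400, seed = 11L)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_cohort(spec, seed = 12L)
  expect_false(identical(a$ptau181, c$ptau181))
})

test_that("degenerate prevalence yields an all-negative cohort", {
  spec <- cohort_spec(n = 1000, amyloid_prev_carrier = 0,
                      amyloid_prev_noncarrier = 0, assay_cv = 0, seed = 5L)
  coh <- generate_cohort(spec)
  expect_equal(sum(coh$amyloid_true), 0)
  expect_equal(nrow(coh), 1000)
  expect_false(anyDuplicated(coh$id) > 0)
  expect_true(all(coh[c("apoe4p_conc", "ptau181", "gfap",
                        "abeta42", "abeta40")] > 0))
})

test_that("empirical prevalences converge to spec values (3 binomial SEs, n = 50k)", {
  spec <- a4_spec(n = 50000, seed = 303L)
  coh <- generate_cohort(spec)
  n <- nrow(coh)
  se <- function(p, m) sqrt(p * (1 - p) / m)

  p_c <- spec$carrier_prevalence
  expect_lt(abs(mean(coh$apoe4p_carrier_true) - p_c), 3 * se(p_c, n))

  carriers <- coh$apoe4p_carrier_true == 1
  expect_lt(abs(mean(coh$amyloid_true[carriers]) - spec$amyloid_prev_carrier),
            3 * se(spec$amyloid_prev_carrier, sum(carriers)))
  expect_lt(abs(mean(coh$amyloid_true[!carriers]) - spec$amyloid_prev_noncarrier),
            3 * se(spec$amyloid_prev_noncarrier, sum(!carriers)))

  pi <- mixture_prevalence(p_c, spec$amyloid_prev_carrier,
                           spec$amyloid_prev_noncarrier)
  expect_equal(pi, 0.1570423, tolerance = 1e-6)
  expect_lt(abs(mean(coh$amyloid_true) - pi), 3 * se(pi, n))
})

test_that("derive_stratum_operating_points matches closed form and handles boundaries", {
  op <- derive_stratum_operating_points(0.349, 0.289, 0.0863, 0.955, 0.458)
  # frozen from the closed forms Se = (PPA - P(c|A+))/(1 - P(c|A+)),
  # Sp = NPA / P(nc|A-), evaluated independently below
  p_c_pos <- 0.349 * 0.289 / 0.1570423
  p_nc_neg <- 0.651 * (1 - 0.0863) / (1 - 0.1570423)
  expect_equal(op$se_ptau, (0.955 - p_c_pos) / (1 - p_c_pos), tolerance = 1e-10)
  expect_equal(op$sp_ptau, 0.458 / p_nc_neg, tolerance = 1e-10)
  expect_equal(op$se_ptau, 0.8742, tolerance = 1e-4)
  expect_equal(op$sp_ptau, 0.6491, tolerance = 1e-4)

  # PPA target equal to the carrier-step PPA: pTau step needs no sensitivity
  at_boundary <- derive_stratum_operating_points(0.349, 0.289, 0.0863,
                                                 p_c_pos, 0.458)
  expect_equal(at_boundary$se_ptau, 0, tolerance = 1e-12)

  # no carriers: the rule collapses to a single pTau threshold
  collapsed <- derive_stratum_operating_points(0, 0.5, 0.0863, 0.90, 0.45)
  expect_equal(collapsed$se_ptau, 0.90)
  expect_equal(collapsed$sp_ptau, 0.45, tolerance = 1e-12)

  expect_error(derive_stratum_operating_points(0.349, 0.289, 0.0863, 0.5, 0.458),
               "Infeasible PPA")
  expect_error(derive_stratum_operating_points(0.349, 0.289, 0.0863, 0.955, 0.99),
               "Infeasible NPA")
})

test_that("calibrate_marker_location hits the requested exceedance probability", {
  expect_equal(calibrate_marker_location(0.830, 0.5, 0.37), log10(0.830))
  mu_hi <- calibrate_marker_location(0.830, 0.874212, 0.20)
  mu_lo <- calibrate_marker_location(0.830, 1 - 0.649063, 0.20)
  expect_equal(mu_hi, 0.14836, tolerance = 2e-4)
  expect_equal(mu_lo, -0.15748, tolerance = 2e-4)

  # Monte-Carlo oracle: exceedance fraction of 1e6 draws matches the target
  set.seed(99)
  for (case in list(c(mu_hi, 0.874212), c(mu_lo, 1 - 0.649063))) {
    draws <- 10^rnorm(1e6, case[1], 0.20)
    frac <- mean(draws >= 0.830)
    expect_lt(abs(frac - case[2]), 3 * sqrt(case[2] * (1 - case[2]) / 1e6) + 1e-4)
  }
})

test_that("assay perturbation: identity, deterministic bias, truth untouched", {
  coh <- generate_cohort(a4_spec(n = 300, seed = 7L))
  same <- apply_assay_perturbation(coh, bias = 1, cv = 0)
  expect_identical(as.data.frame(same), as.data.frame(coh))

  scaled <- apply_assay_perturbation(coh, bias = c(ptau181 = 0.8), cv = 0)
  expect_equal(scaled$ptau181, 0.8 * coh$ptau181)
  expect_identical(scaled$gfap, coh$gfap)

  noisy <- apply_assay_perturbation(coh, bias = 1, cv = 0.1, seed = 3L)
  expect_false(any(noisy$ptau181 == coh$ptau181))
  expect_identical(noisy$amyloid_true, coh$amyloid_true)
  expect_identical(noisy$pet_result, coh$pet_result)
  # replicate perturbations move the screen-out rate by a little, not wildly
  rates <- vapply(1:20, function(s) {
    p <- apply_assay_perturbation(coh, bias = 1, cv = 0.1, seed = s)
    mean(classify_bbbm(p$apoe4p_conc, p$ptau181)$call == "negative")
  }, numeric(1))
  expect_gt(stats::sd(rates), 0)
  expect_lt(stats::sd(rates), 0.1)
})

test_that("spec validation names the offending field", {
  expect_error(cohort_spec(carrier_prevalence = 1.2), "carrier_prevalence")
  expect_error(cohort_spec(ptau_scale = -1), "ptau_scale")
  expect_error(cohort_spec(assay_cv = -0.1), "assay_cv")
  expect_error(cohort_spec(n = 0), "positive integer")
  expect_error(cohort_spec(bias_gfap = 0), "bias_gfap")
})
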