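make_model_cohort <- function(n = 4000, seed = 17L) {
  add_composite_amyloid(generate_cohort(a4_spec(n = n, seed = seed)))
}

test_that("logistic fit on a saturated 2x2 recovers the closed-form log odds ratio", {
  # counts (10, 5; 5, 10): OR = 4, slope = ln 4, intercept = ln(5/10)
  y <- rep(c(1, 0, 1, 0), c(10, 5, 5, 10))
  x <- rep(c(1, 1, 0, 0), c(10, 5, 5, 10))
  coh <- data.frame(
    apoe4p_conc = ifelse(x == 1, 1.0, 0.1),  # binary via the 0.668 cutoff
    ptau181 = 1, gfap = 1, abeta42 = 1, abeta40 = 1,
    pet_result = ifelse(y == 1, "positive", "negative"),
    csf_ptau181 = NA_real_, csf_abeta42 = NA_real_
  )
  m <- fit_logistic(coh, predictors = "apoe4p")
  expect_equal(unname(m$coefficients["apoe4p"]), log(4), tolerance = 1e-6)
  expect_equal(unname(m$coefficients["(Intercept)"]), log(5 / 10),
               tolerance = 1e-6)
  expect_false(m$separation)
  # determinism of the refit
  m2 <- fit_logistic(coh, predictors = "apoe4p")
  expect_identical(m$coefficients, m2$coefficients)
})

test_that("a permuted-label predictor has a near-zero coefficient", {
  coh <- make_model_cohort()
  set.seed(8)
  coh$composite_amyloid <- sample(coh$composite_amyloid)
  m <- fit_logistic(coh, predictors = "ptau181")
  se <- summary(m$fit)$coefficients["ptau181", "Std. Error"]
  expect_lt(abs(m$coefficients[["ptau181"]]), 4 * se)
})

test_that("perfect separation is flagged; single-class outcomes error", {
  coh <- data.frame(
    apoe4p_conc = 0.1, ptau181 = c(2, 2.5, 3, 0.2, 0.3, 0.4),
    gfap = 1, abeta42 = 1, abeta40 = 1,
    pet_result = rep(c("positive", "negative"), each = 3),
    csf_ptau181 = NA_real_, csf_abeta42 = NA_real_
  )
  m <- fit_logistic(coh, predictors = "ptau181")
  expect_true(m$separation)
  coh$pet_result <- "positive"
  expect_error(fit_logistic(coh, predictors = "ptau181"), "Both amyloid classes")
  expect_error(fit_logistic(coh, predictors = "nope"), "Unknown predictor")
})

test_that("AUC matches brute-force pair enumeration and its boundary cases", {
  expect_equal(auc_rank(c(3, 4, 5, 1, 2), c(1, 1, 1, 0, 0)), 1)
  expect_equal(auc_rank(rep(2, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  scores <- c(0.9, 0.2, 0.7, 0.7, 0.4, 0.1)
  truth <- c(1, 0, 1, 0, 1, 0)
  expect_equal(auc_rank(scores, truth), oracle_auc(scores, truth))
  expect_true(is.na(auc_rank(1:3, c(1, 1, 1))))
  # invariance under strictly monotone transforms of the scores
  set.seed(5)
  s <- runif(40); y <- rbinom(40, 1, 0.4)
  expect_equal(auc_rank(s, y), auc_rank(qlogis(s), y))
  expect_equal(auc_rank(s, y), auc_rank(100 * s + 3, y))
})

test_that("predictiveness curves match exhaustive enumeration on a worked cohort", {
  risk <- c(0.05, 0.10, 0.15, 0.22, 0.31, 0.40, 0.55, 0.63, 0.78, 0.91)
  truth <- c(0, 0, 1, 0, 0, 1, 0, 1, 1, 1)
  rp <- predictiveness_curves(risk, truth, grid_points = 11L)
  for (i in seq_len(nrow(rp))) {
    k <- round(rp$q[i] * 10)
    want <- oracle_predictiveness(risk, truth, k)
    if (is.na(want$ppv)) expect_true(is.na(rp$ppv_raw[i]))
    else expect_equal(rp$ppv_raw[i], want$ppv)
    if (is.na(want$one_minus_npv)) expect_true(is.na(rp$one_minus_npv_raw[i]))
    else expect_equal(rp$one_minus_npv_raw[i], want$one_minus_npv)
  }
  expect_equal(rp$ppv_raw[1], mean(truth))        # q = 0 retains everyone
  expect_true(is.na(rp$one_minus_npv_raw[1]))     # empty screened-out set
  expect_equal(attr(rp, "prevalence"), 0.5)
})

test_that("a perfectly ranked cohort attains the optimal curves", {
  truth <- rep(c(0, 1), c(8, 2))          # prevalence 0.2, positives on top
  risk <- seq(0.05, 0.95, length.out = 10)
  rp <- predictiveness_curves(risk, truth, grid_points = 11L)
  defined <- !is.na(rp$ppv_raw)
  expect_equal(rp$ppv_raw[defined], rp$ppv_opt[defined], tolerance = 1e-12)
  defined <- !is.na(rp$one_minus_npv_raw)
  expect_equal(rp$one_minus_npv_raw[defined], rp$one_minus_npv_opt[defined],
               tolerance = 1e-12)
})

test_that("positives are conserved across every achievable cut", {
  coh <- make_model_cohort(n = 600, seed = 23L)
  m <- fit_logistic(coh)
  n <- length(m$truth)
  rp <- predictiveness_curves(m, grid_points = n + 1L)
  total_pos <- sum(m$truth)
  for (i in seq_len(nrow(rp))) {
    k <- round(rp$q[i] * n)
    screened <- if (is.na(rp$one_minus_npv_raw[i])) 0 else rp$one_minus_npv_raw[i] * k
    retained <- if (is.na(rp$ppv_raw[i])) 0 else rp$ppv_raw[i] * (n - k)
    expect_equal(screened + retained, total_pos, tolerance = 1e-8)
  }
})

test_that("isotonic smoothing is monotone, PAVA-optimal, and dominated by the optimal curves", {
  set.seed(10)
  for (rep in 1:5) {
    y <- runif(7)
    fit <- prescreenr:::isotonic_fit(seq_along(y), y)
    expect_true(all(diff(fit) >= -1e-12))
    expect_equal(fit, oracle_isotonic(y), tolerance = 1e-10)
  }
  coh <- make_model_cohort(n = 800, seed = 29L)
  m <- fit_logistic(coh)
  rp <- predictiveness_curves(m, grid_points = length(m$truth) + 1L)
  ok <- !is.na(rp$ppv_smooth)
  expect_true(all(diff(rp$ppv_smooth[ok]) >= -1e-12))
  expect_true(all(rp$ppv_smooth[ok] <= rp$ppv_opt[ok] + 1e-6))
  ok <- !is.na(rp$one_minus_npv_smooth)
  expect_true(all(diff(rp$one_minus_npv_smooth[ok]) >= -1e-12))
  expect_true(all(rp$one_minus_npv_smooth[ok] >=
                    rp$one_minus_npv_opt[ok] - 1e-6))
})

test_that("combination comparison ranks the generator's strongest pair first", {
  coh <- make_model_cohort(n = 20000, seed = 61L)
  tab <- compare_combinations(coh)
  expect_equal(tab$combination[which.max(tab$auc)], "pTau181 + ApoE4p")
  expect_true(all(tab$auc > 0.5 & tab$auc < 1))
  # permuted labels: every combination collapses towards chance
  set.seed(3)
  coh$composite_amyloid <- sample(coh$composite_amyloid)
  null_tab <- compare_combinations(coh)
  expect_true(all(abs(null_tab$auc - 0.5) < 0.03))
})
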