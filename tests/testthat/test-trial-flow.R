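test_that("prescreen arm: funnel conservation and degenerate blinding", {
  coh <- generate_cohort(skyline_group2_spec(n = 3000, seed = 19L))
  cfg <- flow_config(spec = skyline_group2_spec(n = 3000, seed = 19L),
                     blind_fraction = 0, attrition = 0, seed = 19L)
  arm <- run_prescreen_arm(coh, cfg)
  st <- arm$stages
  expect_equal(st$bbbm_positive + st$bbbm_negative, st$blood_tested)
  expect_equal(st$invited, st$bbbm_positive)        # no blinding pass-through
  expect_equal(st$invited_subset2, 0)
  expect_lte(st$confirmed, st$invited)
  # subset 1 with full confirmation equals the whole BBBM-positive stratum
  whole <- add_composite_amyloid(apply_rule(coh, cfg$cutoffs))
  pos <- whole$bbbm_call == "positive" & whole$composite_amyloid != "unknown"
  expect_equal(arm$subset1$counts$tp, sum(pos & whole$composite_amyloid == "positive"))
  expect_true(is.na(arm$subset1$ppa))  # withheld for the blinded arm
})

test_that("quota blinding gives subset 2 its exact expected size", {
  coh <- generate_cohort(skyline_group2_spec(n = 3000, seed = 29L))
  cfg <- flow_config(spec = skyline_group2_spec(n = 3000, seed = 29L),
                     blind_fraction = 0.10, blind_mode = "quota",
                     attrition = 0, seed = 29L)
  arm <- run_prescreen_arm(coh, cfg)
  expect_equal(arm$stages$invited_subset2,
               round(0.10 * arm$stages$bbbm_negative))
})

test_that("direct arm reports calibrated metrics; a perfect rule is perfect", {
  coh <- generate_cohort(skyline_group2_spec(n = 50000, seed = 37L))
  cfg <- flow_config(spec = skyline_group2_spec(n = 50000, seed = 37L),
                     attrition = 0, seed = 37L)
  arm <- run_direct_arm(coh, cfg)
  rep <- arm$report
  n_pos <- rep$counts$tp + rep$counts$fn
  n_neg <- rep$counts$tn + rep$counts$fp
  expect_lt(abs(rep$ppa - 0.946), 3 * sqrt(0.946 * 0.054 / n_pos))
  expect_lt(abs(rep$npa - 0.445), 3 * sqrt(0.445 * 0.555 / n_neg))
  expect_lt(abs(rep$prevalence - 0.1233), 3 * sqrt(0.1233 * 0.8767 / (n_pos + n_neg)))

  # a rule that reads the composite reference directly is perfect against it
  perfect <- add_composite_amyloid(coh)
  perfect$apoe4p_conc <- ifelse(perfect$composite_amyloid == "positive", 10, 0.01)
  perfect$ptau181 <- 0.1
  parm <- run_direct_arm(perfect, cfg)
  expect_equal(parm$report$ppa, 1)
  expect_equal(parm$report$npa, 1)
  expect_equal(parm$report$one_minus_npv, 0)

  expect_error(run_direct_arm(coh[0, ], cfg), "Empty cohort")
})

test_that("run_experiment: funnel conservation, acceptance flags, determinism", {
  cfg <- skyline_flow_config(n = 8000, seed = 101L)
  rep1 <- run_experiment(cfg)
  g1 <- rep1$groups$group1$stages
  expect_equal(g1$bbbm_positive + g1$bbbm_negative, g1$blood_tested)
  expect_lte(g1$invited, g1$blood_tested)
  expect_lte(g1$confirmed, g1$invited)
  expect_lte(g1$amyloid_positive_confirmed, g1$confirmed)
  # shipped default meets both acceptance criteria
  expect_true(rep1$acceptance$meets_screen_out)
  expect_true(rep1$acceptance$meets_one_minus_npv)
  expect_true(rep1$acceptance$pass)

  rep2 <- run_experiment(cfg)
  expect_identical(
    jsonlite::toJSON(prescreenr:::flow_report_as_list(rep1), auto_unbox = TRUE, digits = NA),
    jsonlite::toJSON(prescreenr:::flow_report_as_list(rep2), auto_unbox = TRUE, digits = NA))
})

test_that("all mass on the direct arm yields a Group-2-only report", {
  cfg <- flow_config(spec = skyline_group2_spec(n = 2000, seed = 43L),
                     group_probs = c(0, 1, 0), attrition = 0, seed = 43L)
  rep <- run_experiment(cfg)
  expect_named(rep$groups, "group2")
  expect_false(is.null(rep$acceptance))
})

test_that("run_experiment writes its artifact set", {
  out <- file.path(tempdir(), "flow_out_test")
  on.exit(unlink(out, recursive = TRUE))
  cfg <- skyline_flow_config(n = 3000, seed = 7L)
  rep <- run_experiment(cfg, out_dir = out)
  expect_true(all(file.exists(file.path(
    out, c("cohort.csv", "report.json", "table1.tsv", "curves.csv")))))
  parsed <- jsonlite::read_json(file.path(out, "report.json"))
  expect_equal(parsed$provenance$seed, 7)
  expect_true(is.numeric(parsed$groups$group2$report$ppa))
})

test_that("flow_config validates group probabilities", {
  expect_error(flow_config(group_probs = c(0.5, 0.5, 0.5)), "summing to 1")
  expect_error(flow_config(blind_fraction = 2), "blind_fraction")
})
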