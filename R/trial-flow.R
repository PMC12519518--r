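#' Configuration of a full screening-flow experiment
#'
#' Bundles everything [run_experiment()] needs: the cohort source, how
#' participants split across the three screening routes (pre-screening arm,
#' direct main-screening entry, historic-PET entry), the blinding
#' pass-through, marker-independent attrition between invitation and
#' confirmatory testing, the rule cutoffs, the acceptance constraints, and a
#' seed.
#'
#' @param spec A [cohort_spec()] to simulate from, or a file path to a
#'   cohort CSV to load instead.
#' @param group_probs Probabilities of assignment to the `prescreen`,
#'   `direct`, and `historic` routes; must sum to 1.
#' @param blind_fraction Fraction of BBBM negatives invited anyway.
#' @param blind_mode `"bernoulli"` or `"quota"` (see [blinding_invite()]).
#' @param attrition Probability an invited participant is lost before
#'   confirmatory amyloid testing (independent of marker values).
#' @param cutoffs A [rule_cutoffs()].
#' @param constraints A [constraint_spec()].
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `flow_config` object.
#' @export
flow_config <- function(spec = skyline_group2_spec(n = 5000L),
                        group_probs = c(prescreen = 0.786, direct = 0.213,
                                        historic = 0.001),
                        blind_fraction = 0.10,
                        blind_mode = c("bernoulli", "quota"),
                        attrition = 0.5,
                        cutoffs = rule_cutoffs(),
                        constraints = constraint_spec(),
                        seed = 20260909L) {
  blind_mode <- match.arg(blind_mode)
  if (length(group_probs) != 3L || abs(sum(group_probs) - 1) > 1e-8 ||
      any(group_probs < 0)) {
    stop("`group_probs` must be three non-negative values summing to 1.",
         call. = FALSE)
  }
  names(group_probs) <- c("prescreen", "direct", "historic")
  check_probability(blind_fraction, "blind_fraction")
  check_probability(attrition, "attrition")
  structure(list(spec = spec, group_probs = group_probs,
                 blind_fraction = blind_fraction, blind_mode = blind_mode,
                 attrition = attrition, cutoffs = cutoffs,
                 constraints = constraints, seed = as.integer(seed)),
            class = "flow_config")
}

#' SKYLINE-like default flow configuration
#'
#' The shipped default: a Group-2-calibrated cohort split 78.6% / 21.3% /
#' 0.1% across the pre-screening, direct, and historic routes (the study's
#' 3432 / 927 / 5 proportions), 10% Bernoulli blinding pass-through, and 56%
#' attrition before confirmatory testing (the direct group's 300 confirmed
#' of 679 blood-tested).
#'
#' @param n Cohort size.
#' @param seed Master seed.
#' @param ... Overrides passed to [flow_config()].
#' @return A `flow_config`.
#' @export
skyline_flow_config <- function(n = 20000L, seed = 20260909L, ...) {
  flow_config(spec = skyline_group2_spec(n = n, seed = seed),
              attrition = 0.56, seed = seed, ...)
}

# Marker-independent thinning of invited participants before confirmation.
attrition_thin <- function(invited, attrition, seed) {
  reached <- invited
  idx <- which(invited)
  if (length(idx) && attrition > 0) {
    with_seed(seed, {
      lost <- stats::runif(length(idx)) < attrition
      reached[idx[lost]] <- FALSE
    })
  }
  reached
}

blanked_report <- function(report) {
  # Group 1 subsets are blinding-biased samples: prevalence/PPA/NPA are not
  # representative and are deliberately withheld from the fragment.
  report$prevalence <- NA_real_
  report$ppa <- NA_real_
  report$npa <- NA_real_
  report$ci$ppa <- c(lower = NA_real_, upper = NA_real_)
  report$ci$npa <- c(lower = NA_real_, upper = NA_real_)
  report
}

#' Run the pre-screening arm of the flow
#'
#' Classifies the arm's cohort with the two-step rule, applies the blinding
#' pass-through, thins invitees by attrition, resolves the composite amyloid
#' reference for those reaching confirmation, and scores Subset 1 (invited
#' BBBM positives; PPV) and Subset 2 (invited BBBM negatives; 1-NPV)
#' separately. Prevalence, PPA and NPA are withheld: the negatives reaching
#' confirmation are a blinding-selected 10%, so those metrics would not be
#' representative.
#'
#' @param cohort Cohort data frame for this arm.
#' @param config A [flow_config()].
#' @param seed Seed for the arm's stochastic stages (blinding, attrition).
#' @return List with `stages` (funnel counts), `subset1` and `subset2`
#'   agreement reports, and the annotated `cohort`.
#' @export
run_prescreen_arm <- function(cohort, config, seed = config$seed) {
  if (!nrow(cohort)) stop("Empty cohort.", call. = FALSE)
  cohort <- apply_rule(cohort, config$cutoffs)
  inv <- blinding_invite(cohort$bbbm_call, config$blind_fraction,
                         seed = derive_seed(seed, 1L),
                         mode = config$blind_mode)
  cohort$invited <- inv$invited
  cohort$subset <- inv$subset
  reached <- attrition_thin(cohort$invited, config$attrition,
                            derive_seed(seed, 2L))
  cohort <- add_composite_amyloid(cohort)
  cohort$confirmed <- reached & cohort$composite_amyloid != "unknown"

  score_subset <- function(label) {
    sel <- cohort$subset == label & cohort$confirmed
    blanked_report(agreement_metrics(
      confusion(cohort$bbbm_call[sel], cohort$composite_amyloid[sel])))
  }
  stages <- list(
    blood_tested = nrow(cohort),
    bbbm_positive = sum(cohort$bbbm_call == "positive"),
    bbbm_negative = sum(cohort$bbbm_call == "negative"),
    invited = sum(cohort$invited),
    invited_subset2 = sum(cohort$subset == "subset2"),
    confirmed = sum(cohort$confirmed),
    amyloid_positive_confirmed = sum(cohort$confirmed &
                                       cohort$composite_amyloid == "positive")
  )
  list(stages = stages,
       subset1 = score_subset("subset1"),
       subset2 = score_subset("subset2"),
       cohort = cohort)
}

#' Run the direct-entry arm of the flow
#'
#' Every participant proceeds to main screening regardless of the BBBM
#' result, which is recorded for retrospective evaluation. Attrition thins
#' who reaches confirmatory testing; the full agreement report (prevalence,
#' PPA, NPA, PPV, 1-NPV, screen-out) is computed among participants with a
#' known composite reference.
#'
#' @inheritParams run_prescreen_arm
#' @return List with `stages`, `report` (full agreement report), and the
#'   annotated `cohort`.
#' @export
run_direct_arm <- function(cohort, config, seed = config$seed) {
  if (!nrow(cohort)) stop("Empty cohort.", call. = FALSE)
  cohort <- apply_rule(cohort, config$cutoffs)
  cohort$invited <- TRUE
  cohort$subset <- "direct"
  reached <- attrition_thin(cohort$invited, config$attrition,
                            derive_seed(seed, 3L))
  cohort <- add_composite_amyloid(cohort)
  cohort$confirmed <- reached & cohort$composite_amyloid != "unknown"
  amy <- ifelse(cohort$confirmed, cohort$composite_amyloid, "unknown")
  report <- agreement_metrics(confusion(cohort$bbbm_call, amy))
  stages <- list(
    blood_tested = nrow(cohort),
    bbbm_positive = sum(cohort$bbbm_call == "positive"),
    bbbm_negative = sum(cohort$bbbm_call == "negative"),
    invited = nrow(cohort),
    confirmed = sum(cohort$confirmed),
    amyloid_positive_confirmed = sum(cohort$confirmed &
                                       cohort$composite_amyloid == "positive")
  )
  list(stages = stages, report = report, cohort = cohort)
}

#' Run the full screening-flow experiment
#'
#' Simulates (or loads) the cohort, assigns participants to the
#' pre-screening / direct / historic routes, runs both analysis arms plus
#' the historic-PET pass-through, evaluates the acceptance constraints on
#' the direct arm's report, and optionally writes all artifacts (cohort CSV,
#' report JSON, per-group summary TSV, predictiveness-curve CSV) to `out_dir`.
#' Identical config and seed give identical reports.
#'
#' @param config A [flow_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return A `flow_report` list: `groups` (per-route stage counts and
#'   reports), `acceptance` flags, and `provenance` (config hash and seed).
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (!inherits(config, "flow_config")) {
    stop("`config` must be a flow_config.", call. = FALSE)
  }
  cohort <- if (is.character(config$spec)) {
    read_cohort(config$spec)
  } else {
    generate_cohort(config$spec, seed = derive_seed(config$seed, 10L))
  }
  n <- nrow(cohort)
  arm <- with_seed(derive_seed(config$seed, 11L), {
    sample(c("prescreen", "direct", "historic"), n, replace = TRUE,
           prob = config$group_probs)
  })

  groups <- list()
  if (any(arm == "prescreen")) {
    groups$group1 <- run_prescreen_arm(cohort[arm == "prescreen", , drop = FALSE],
                                       config, seed = derive_seed(config$seed, 12L))
  }
  if (any(arm == "direct")) {
    groups$group2 <- run_direct_arm(cohort[arm == "direct", , drop = FALSE],
                                    config, seed = derive_seed(config$seed, 13L))
  }
  if (any(arm == "historic")) {
    g3 <- add_composite_amyloid(cohort[arm == "historic", , drop = FALSE])
    # pass-through: amyloid status taken directly from the historic read
    groups$group3 <- list(stages = list(
      entered = nrow(g3),
      amyloid_known = sum(g3$composite_amyloid != "unknown"),
      amyloid_positive = sum(g3$composite_amyloid == "positive")
    ))
  }

  acceptance <- NULL
  if (!is.null(groups$group2)) {
    rep2 <- groups$group2$report
    crit <- switch(config$constraints$screen_out_basis,
                   amyloid_negative = rep2$npa,
                   all = rep2$screen_out_rate)
    acceptance <- list(
      screen_out_basis = config$constraints$screen_out_basis,
      screen_out_value = crit,
      meets_screen_out = !is.na(crit) && crit > config$constraints$min_screen_out,
      one_minus_npv = rep2$one_minus_npv,
      meets_one_minus_npv = !is.na(rep2$one_minus_npv) &&
        rep2$one_minus_npv <= config$constraints$max_one_minus_npv
    )
    acceptance$pass <- acceptance$meets_screen_out && acceptance$meets_one_minus_npv
  }

  report <- structure(list(
    groups = lapply(groups, function(g) g[setdiff(names(g), "cohort")]),
    acceptance = acceptance,
    provenance = list(config_hash = config_hash(config), seed = config$seed)
  ), class = "flow_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cohs <- Filter(Negate(is.null), lapply(groups, function(g) g$cohort))
    if (length(cohs)) {
      common <- Reduce(intersect, lapply(cohs, names))
      full <- do.call(rbind, c(lapply(cohs, function(d) d[, common, drop = FALSE]),
                               list(make.row.names = FALSE)))
      write_cohort(full, file.path(out_dir, "cohort.csv"))
    }
    write_flow_report(report, file.path(out_dir, "report.json"))
    writeLines(format_table1(report), file.path(out_dir, "table1.tsv"))
    if (!is.null(groups$group2)) {
      rm2 <- fit_logistic(groups$group2$cohort)
      curves <- predictiveness_curves(rm2)
      utils::write.csv(as.data.frame(curves),
                       file.path(out_dir, "curves.csv"), row.names = FALSE)
    }
  }
  report
}

config_hash <- function(config) {
  ser <- utils::capture.output(utils::str(config[setdiff(names(config), "seed")],
                                          digits.d = 15))
  fnv1a_hash(ser)
}

flow_report_as_list <- function(report) {
  conv <- function(x) {
    if (inherits(x, "agreement_report")) return(report_as_list(x))
    if (is.list(x)) return(lapply(x, conv))
    x
  }
  conv(unclass(report))
}

#' Serialize a flow report to JSON
#'
#' @param report A `flow_report` from [run_experiment()].
#' @param path Output path.
#' @param timestamp Add a generation timestamp to the provenance block
#'   (default `FALSE`, keeping the file byte-identical across reruns with
#'   the same seed).
#' @return `path`, invisibly.
#' @export
write_flow_report <- function(report, path, timestamp = FALSE) {
  x <- flow_report_as_list(report)
  if (timestamp) {
    x$provenance$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

# Per-group summary-table text rendering of a flow report.
format_table1 <- function(report) {
  g <- report$groups
  col <- function(rep, stages) {
    c(stages$blood_tested,
      sprintf("%d (%s)", stages$bbbm_negative,
              fmt_pct(stages$bbbm_negative / stages$blood_tested)),
      fmt_pct(rep$prevalence), fmt_pct(rep$ppa), fmt_pct(rep$npa),
      fmt_pct(rep$ppv), fmt_pct(rep$one_minus_npv))
  }
  rows <- c("N with BBBM result", "BBBM screen-out, n (%)", "Prevalence",
            "PPA", "NPA", "PPV", "1-NPV")
  cols <- list(metric = rows)
  if (!is.null(g$group1)) {
    cols[["Group 1 (Subset 1)"]] <- col(g$group1$subset1, g$group1$stages)
    cols[["Group 1 (Subset 2)"]] <-
      c("", "", fmt_pct(g$group1$subset2$prevalence),
        fmt_pct(g$group1$subset2$ppa), fmt_pct(g$group1$subset2$npa),
        fmt_pct(g$group1$subset2$ppv), fmt_pct(g$group1$subset2$one_minus_npv))
  }
  if (!is.null(g$group2)) {
    cols[["Group 2"]] <- col(g$group2$report, g$group2$stages)
  }
  tab <- do.call(cbind, cols)
  apply(tab, 1L, paste, collapse = "\t")
}

#' @export
print.flow_report <- function(x, ...) {
  cat("<flow_report>\n")
  for (nm in names(x$groups)) {
    st <- x$groups[[nm]]$stages
    cat(sprintf("  %s: %s\n", nm,
                paste(sprintf("%s=%d", names(st), unlist(st)), collapse = ", ")))
  }
  if (!is.null(x$acceptance)) {
    cat(sprintf("  acceptance (%s basis): screen-out %s, 1-NPV %s => %s\n",
                x$acceptance$screen_out_basis,
                fmt_pct(x$acceptance$screen_out_value),
                fmt_pct(x$acceptance$one_minus_npv),
                ifelse(x$acceptance$pass, "PASS", "FAIL")))
  }
  invisible(x)
}
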