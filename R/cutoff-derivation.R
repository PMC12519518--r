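#' Acceptance constraints for cutoff derivation
#'
#' The pre-defined clinical acceptance criteria: a screen-out of
#' amyloid-negative individuals strictly above `min_screen_out` (default
#' 40%), and a 1-NPV at most `max_one_minus_npv` (default 2%).
#'
#' `screen_out_basis` selects the denominator of the screen-out criterion:
#' `"amyloid_negative"` (default) tests the screened-out fraction among
#' amyloid-negative participants, which equals the NPA; `"all"` tests the
#' overall screen-out rate among everyone with a BBBM result.
#'
#' @param min_screen_out Strict lower bound on the screen-out criterion.
#' @param max_one_minus_npv Non-strict upper bound on 1-NPV.
#' @param screen_out_basis `"amyloid_negative"` or `"all"`.
#' @return A `constraint_spec` object.
#' @export
constraint_spec <- function(min_screen_out = 0.40, max_one_minus_npv = 0.02,
                            screen_out_basis = c("amyloid_negative", "all")) {
  check_probability(min_screen_out, "min_screen_out")
  check_probability(max_one_minus_npv, "max_one_minus_npv")
  structure(list(min_screen_out = min_screen_out,
                 max_one_minus_npv = max_one_minus_npv,
                 screen_out_basis = match.arg(screen_out_basis)),
            class = "constraint_spec")
}

#' @export
print.constraint_spec <- function(x, ...) {
  cat(sprintf("<constraint_spec> screen-out (%s) > %s; 1-NPV <= %s\n",
              x$screen_out_basis, fmt_pct(x$min_screen_out),
              fmt_pct(x$max_one_minus_npv)))
  invisible(x)
}

#' Derive cutoff pairs by exhaustive grid search
#'
#' Evaluates the two-step rule at every (ApoE4p, pTau181) cutoff pair on the
#' grids, scoring each pair on the cohort rows with known composite amyloid
#' status. A pair is feasible when it meets both acceptance constraints.
#' Among feasible pairs the chosen one maximizes the screen-out criterion
#' (on the constraint's basis), with ties broken by smaller 1-NPV, then by
#' larger pTau181 cutoff, then by larger ApoE4p cutoff — so the result does
#' not depend on grid-point ordering. An empty feasible set is a valid
#' outcome, not an error.
#'
#' Default grids are empirical marker quantiles: on a finite cohort every
#' achievable operating point is attained at an observed value.
#'
#' @param cohort Cohort data frame; a `composite_amyloid` column is computed
#'   via [add_composite_amyloid()] if absent.
#' @param apoe4p_grid,ptau_grid Candidate cutoffs; default deciles of the
#'   observed marker values.
#' @param constraints A [constraint_spec()].
#' @return A `cutoff_search` object: `results` (one row per pair with
#'   `apoe4p_cutoff`, `ptau_cutoff`, `screen_out_all`, `npa`, `ppv`,
#'   `one_minus_npv`, `criterion`, `feasible`), `chosen` (a [rule_cutoffs()]
#'   or `NULL`), `objective` (criterion value of the chosen pair or `NA`),
#'   and the `constraints` used.
#' @export
grid_search <- function(cohort, apoe4p_grid = NULL, ptau_grid = NULL,
                        constraints = constraint_spec()) {
  if (!"composite_amyloid" %in% names(cohort)) {
    cohort <- add_composite_amyloid(cohort)
  }
  known <- cohort$composite_amyloid != "unknown"
  if (!any(known)) {
    stop("Cohort has no rows with known amyloid status.", call. = FALSE)
  }
  if (is.null(apoe4p_grid)) {
    apoe4p_grid <- unique(stats::quantile(cohort$apoe4p_conc,
                                          probs = seq(0.1, 0.9, by = 0.1),
                                          names = FALSE))
  }
  if (is.null(ptau_grid)) {
    ptau_grid <- unique(stats::quantile(cohort$ptau181,
                                        probs = seq(0.1, 0.9, by = 0.1),
                                        names = FALSE))
  }
  if (!length(apoe4p_grid) || !length(ptau_grid)) {
    stop("Cutoff grids must be non-empty.", call. = FALSE)
  }
  grid <- expand.grid(apoe4p_cutoff = sort(apoe4p_grid),
                      ptau_cutoff = sort(ptau_grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    co <- rule_cutoffs(grid$apoe4p_cutoff[i], grid$ptau_cutoff[i])
    calls <- classify_bbbm(cohort$apoe4p_conc, cohort$ptau181, co)$call
    rep <- agreement_metrics(confusion(calls, cohort$composite_amyloid))
    crit <- switch(constraints$screen_out_basis,
                   amyloid_negative = rep$npa,
                   all = rep$screen_out_rate)
    data.frame(
      apoe4p_cutoff = grid$apoe4p_cutoff[i],
      ptau_cutoff = grid$ptau_cutoff[i],
      screen_out_all = rep$screen_out_rate,
      npa = rep$npa,
      ppa = rep$ppa,
      ppv = rep$ppv,
      one_minus_npv = rep$one_minus_npv,
      criterion = crit,
      feasible = !is.na(crit) && crit > constraints$min_screen_out &&
        !is.na(rep$one_minus_npv) &&
        rep$one_minus_npv <= constraints$max_one_minus_npv
    )
  })
  results <- do.call(rbind, rows)

  chosen <- NULL
  objective <- NA_real_
  feas <- results[results$feasible, , drop = FALSE]
  if (nrow(feas)) {
    ord <- order(-feas$criterion, feas$one_minus_npv, -feas$ptau_cutoff,
                 -feas$apoe4p_cutoff)
    best <- feas[ord[1L], ]
    chosen <- rule_cutoffs(best$apoe4p_cutoff, best$ptau_cutoff)
    objective <- best$criterion
  }
  structure(list(results = results, chosen = chosen, objective = objective,
                 constraints = constraints),
            class = "cutoff_search")
}

#' @export
print.cutoff_search <- function(x, ...) {
  cat(sprintf("<cutoff_search> %d pairs evaluated, %d feasible\n",
              nrow(x$results), sum(x$results$feasible)))
  print(x$constraints)
  if (is.null(x$chosen)) {
    cat("  no feasible cutoff pair\n")
  } else {
    cat(sprintf("  chosen: ApoE4p > %.4g, pTau181 >= %.4g (criterion %s)\n",
                x$chosen$apoe4p, x$chosen$ptau, fmt_pct(x$objective)))
  }
  invisible(x)
}
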