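#' Bayes transfer of an operating point to a new prevalence
#'
#' PPA and NPA are properties of the test within the diseased and
#' non-diseased strata, so (under the transportability assumption that they
#' do not change with case mix) the predictive values at any prevalence
#' follow from Bayes' rule. These identities are what lets performance
#' measured in one screening cohort be projected onto another with a
#' different amyloid prevalence.
#'
#' `ppv_at()` returns `ppa*pi / (ppa*pi + (1-npa)*(1-pi))`.
#'
#' @param prevalence Target prevalence `pi` in \[0, 1\].
#' @param ppa,npa Positive/negative percent agreement in \[0, 1\].
#' @return Probability; `NA` when the denominator is zero.
#' @examples
#' ppv_at(0.123, 0.946, 0.445)           # ~0.193
#' one_minus_npv_at(0.158, 0.955, 0.458) # ~0.0181
#' @export
ppv_at <- function(prevalence, ppa, npa) {
  check_probability(prevalence, "prevalence")
  check_probability(ppa, "ppa")
  check_probability(npa, "npa")
  den <- ppa * prevalence + (1 - npa) * (1 - prevalence)
  if (den <= 0) return(NA_real_)
  ppa * prevalence / den
}

#' @rdname ppv_at
#' @details `one_minus_npv_at()` returns
#'   `(1-ppa)*pi / ((1-ppa)*pi + npa*(1-pi))`, the fraction of test-negatives
#'   who are truly amyloid positive.
#' @export
one_minus_npv_at <- function(prevalence, ppa, npa) {
  check_probability(prevalence, "prevalence")
  check_probability(ppa, "ppa")
  check_probability(npa, "npa")
  den <- (1 - ppa) * prevalence + npa * (1 - prevalence)
  if (den <= 0) return(NA_real_)
  (1 - ppa) * prevalence / den
}

#' @rdname ppv_at
#' @details `expected_negative_fraction()` returns
#'   `(1-ppa)*pi + npa*(1-pi)`, the expected overall fraction of test
#'   negatives (the projected screen-out rate on the reference-confirmed
#'   denominator).
#' @export
expected_negative_fraction <- function(prevalence, ppa, npa) {
  check_probability(prevalence, "prevalence")
  check_probability(ppa, "ppa")
  check_probability(npa, "npa")
  (1 - ppa) * prevalence + npa * (1 - prevalence)
}

#' Overall prevalence from carrier-stratified prevalences
#'
#' `p_c * pi_c + (1 - p_c) * pi_nc`.
#'
#' @param carrier_prev Carrier prevalence.
#' @param prev_carrier,prev_noncarrier Amyloid prevalence within carriers /
#'   non-carriers.
#' @return Probability.
#' @examples
#' mixture_prevalence(0.291, 0.213, 0.0865) # ~0.123
#' @export
mixture_prevalence <- function(carrier_prev, prev_carrier, prev_noncarrier) {
  check_probability(carrier_prev, "carrier_prev")
  check_probability(prev_carrier, "prev_carrier")
  check_probability(prev_noncarrier, "prev_noncarrier")
  carrier_prev * prev_carrier + (1 - carrier_prev) * prev_noncarrier
}

#' Bundle a (prevalence, PPA, NPA) operating point
#'
#' @param prevalence,ppa,npa Probabilities.
#' @param counts Optional [confusion_counts()] the point was estimated from.
#' @return An `operating_point` object.
#' @export
operating_point <- function(prevalence, ppa, npa, counts = NULL) {
  check_probability(prevalence, "prevalence")
  check_probability(ppa, "ppa")
  check_probability(npa, "npa")
  structure(list(prevalence = prevalence, ppa = ppa, npa = npa,
                 counts = counts),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("<operating_point> prevalence %s, PPA %s, NPA %s\n",
              fmt_pct(x$prevalence), fmt_pct(x$ppa), fmt_pct(x$npa)))
  invisible(x)
}

#' Predict rule performance at a target prevalence
#'
#' Holds the source operating point's PPA/NPA fixed, substitutes the target
#' prevalence, and returns the projected PPV, 1-NPV, expected screen-out,
#' and enrichment ratio (projected PPV over target prevalence), together
#' with pass/fail flags against the acceptance constraints.
#'
#' The screen-out flag follows the basis declared in `constraints`: with the
#' default `"amyloid_negative"` basis the criterion "screen-out of
#' amyloid-negative individuals > 40%" is tested against the NPA; with basis
#' `"all"` it is tested against the overall expected negative fraction.
#'
#' @param source An [operating_point()] (its prevalence is informational).
#' @param target_prevalence Prevalence to project to.
#' @param constraints A [constraint_spec()].
#' @return A `transfer_report` list: `target_prevalence`, `ppa`, `npa`,
#'   `ppv`, `one_minus_npv`, `screen_out` (expected negative fraction),
#'   `enrichment`, `meets_screen_out`, `meets_one_minus_npv`, `pass`.
#' @examples
#' a4 <- operating_point(0.158, 0.955, 0.458)
#' predict_performance(a4, target_prevalence = 0.15)
#' @export
predict_performance <- function(source, target_prevalence,
                                constraints = constraint_spec()) {
  if (!inherits(source, "operating_point")) {
    stop("`source` must be an operating_point.", call. = FALSE)
  }
  if (is.na(source$ppa) || is.na(source$npa)) {
    stop("Source PPA/NPA must be defined.", call. = FALSE)
  }
  check_probability(target_prevalence, "target_prevalence")
  ppv <- ppv_at(target_prevalence, source$ppa, source$npa)
  onm <- one_minus_npv_at(target_prevalence, source$ppa, source$npa)
  so <- expected_negative_fraction(target_prevalence, source$ppa, source$npa)
  so_basis_value <- switch(constraints$screen_out_basis,
                           amyloid_negative = source$npa,
                           all = so)
  meets_so <- so_basis_value > constraints$min_screen_out
  meets_onm <- !is.na(onm) && onm <= constraints$max_one_minus_npv
  structure(list(
    target_prevalence = target_prevalence,
    ppa = source$ppa, npa = source$npa,
    ppv = ppv, one_minus_npv = onm,
    screen_out = so,
    enrichment = if (target_prevalence > 0 && !is.na(ppv)) ppv / target_prevalence else NA_real_,
    screen_out_basis = constraints$screen_out_basis,
    meets_screen_out = meets_so,
    meets_one_minus_npv = meets_onm,
    pass = meets_so && meets_onm
  ), class = "transfer_report")
}

#' @export
print.transfer_report <- function(x, ...) {
  cat("<transfer_report>\n")
  cat(sprintf("  target prevalence    %s\n", fmt_pct(x$target_prevalence)))
  cat(sprintf("  projected PPV        %s (enrichment x%.2f)\n",
              fmt_pct(x$ppv), x$enrichment))
  cat(sprintf("  projected 1-NPV      %s\n", fmt_pct(x$one_minus_npv)))
  cat(sprintf("  expected screen-out  %s\n", fmt_pct(x$screen_out)))
  cat(sprintf("  acceptance: screen-out %s, 1-NPV %s => %s\n",
              ifelse(x$meets_screen_out, "PASS", "FAIL"),
              ifelse(x$meets_one_minus_npv, "PASS", "FAIL"),
              ifelse(x$pass, "PASS", "FAIL")))
  invisible(x)
}
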