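#' Decision thresholds of the two-step BBBM rule
#'
#' The deployed rule first tests plasma ApoE4p concentration: values
#' *strictly above* `apoe4p` (default 0.668 ug/mL) define carriers, who are
#' BBBM positive outright. Non-carriers are tested on plasma pTau181: values
#' *greater than or equal to* `ptau` (default 0.830 pg/mL) are BBBM positive,
#' lower values BBBM negative. The inequality senses are part of the
#' contract: a value exactly at the ApoE4p cutoff falls through to the
#' pTau181 step.
#'
#' @param apoe4p ApoE4p carrier cutoff in ug/mL (sense: `>`).
#' @param ptau pTau181 positivity cutoff in pg/mL (sense: `>=`).
#' @return An object of class `rule_cutoffs`.
#' @export
rule_cutoffs <- function(apoe4p = 0.668, ptau = 0.830) {
  check_positive(apoe4p, "apoe4p")
  check_positive(ptau, "ptau")
  structure(list(apoe4p = apoe4p, ptau = ptau), class = "rule_cutoffs")
}

#' @export
print.rule_cutoffs <- function(x, ...) {
  cat(sprintf("<rule_cutoffs> ApoE4p > %.3f ug/mL; pTau181 >= %.3f pg/mL\n",
              x$apoe4p, x$ptau))
  invisible(x)
}

#' Classify participants with the two-step BBBM rule
#'
#' Vectorised classifier. pTau181 is never consulted for carriers, so the
#' rule is monotone in both markers: increasing either concentration can
#' only move a participant towards (never away from) positivity.
#'
#' @param apoe4p_conc Plasma ApoE4p concentrations (ug/mL), strictly positive.
#' @param ptau181 Plasma pTau181 concentrations (pg/mL), strictly positive.
#' @param cutoffs A [rule_cutoffs()].
#' @return A data frame with columns `call` (`"positive"`/`"negative"`) and
#'   `branch` (`"carrier"`, `"noncarrier_ptau_high"`, `"noncarrier_ptau_low"`).
#' @examples
#' classify_bbbm(c(0.700, 0.500, 0.668), c(0.100, 0.830, 0.829))
#' @export
classify_bbbm <- function(apoe4p_conc, ptau181, cutoffs = rule_cutoffs()) {
  if (length(apoe4p_conc) != length(ptau181)) {
    stop("Marker vectors must have equal length.", call. = FALSE)
  }
  if (anyNA(apoe4p_conc) || anyNA(ptau181)) {
    stop("The rule requires complete ApoE4p and pTau181 values; got NA.",
         call. = FALSE)
  }
  if (any(apoe4p_conc <= 0) || any(ptau181 <= 0)) {
    stop("Concentrations must be strictly positive.", call. = FALSE)
  }
  carrier <- apoe4p_conc > cutoffs$apoe4p
  ptau_high <- !carrier & ptau181 >= cutoffs$ptau
  branch <- ifelse(carrier, "carrier",
                   ifelse(ptau_high, "noncarrier_ptau_high",
                          "noncarrier_ptau_low"))
  data.frame(call = ifelse(carrier | ptau_high, "positive", "negative"),
             branch = branch, stringsAsFactors = FALSE)
}

#' Apply the BBBM rule to a cohort table
#'
#' Appends `bbbm_call` and `bbbm_branch` columns.
#'
#' @param cohort Cohort data frame with `apoe4p_conc` and `ptau181` columns.
#' @param cutoffs A [rule_cutoffs()].
#' @return The cohort with the two added columns.
#' @export
apply_rule <- function(cohort, cutoffs = rule_cutoffs()) {
  cls <- classify_bbbm(cohort$apoe4p_conc, cohort$ptau181, cutoffs)
  cohort$bbbm_call <- cls$call
  cohort$bbbm_branch <- cls$branch
  cohort
}

#' Invitation flags with blinding pass-through
#'
#' Every BBBM-positive participant is invited to main screening. To blind
#' participants and sites to individual pre-screening results, a fraction of
#' BBBM-negative participants is invited as well: either by independent
#' Bernoulli thinning (default) or by an exact quota
#' (`round(pass_fraction * n_negative)` sampled without replacement).
#'
#' @param calls Character vector of BBBM calls (`"positive"`/`"negative"`).
#' @param pass_fraction Probability (Bernoulli) or fraction (quota) of
#'   negatives invited; default 0.10.
#' @param seed RNG seed.
#' @param mode `"bernoulli"` or `"quota"`.
#' @return A data frame with logical `invited` and a `subset` label:
#'   `"subset1"` (invited positives), `"subset2"` (invited negatives),
#'   `"screened_out"` (excluded negatives).
#' @export
blinding_invite <- function(calls, pass_fraction = 0.10, seed = 1L,
                            mode = c("bernoulli", "quota")) {
  mode <- match.arg(mode)
  check_probability(pass_fraction, "pass_fraction")
  if (!all(calls %in% c("positive", "negative"))) {
    stop("`calls` must be 'positive' or 'negative'.", call. = FALSE)
  }
  n <- length(calls)
  invited <- calls == "positive"
  neg_idx <- which(!invited)
  if (length(neg_idx)) {
    with_seed(seed, {
      if (mode == "bernoulli") {
        pass <- stats::runif(length(neg_idx)) < pass_fraction
        invited[neg_idx[pass]] <- TRUE
      } else {
        k <- round(pass_fraction * length(neg_idx))
        if (k > 0) invited[sample(neg_idx, k)] <- TRUE
      }
    })
  }
  subset <- ifelse(calls == "positive", "subset1",
                   ifelse(invited, "subset2", "screened_out"))
  data.frame(invited = invited, subset = subset, stringsAsFactors = FALSE)
}
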