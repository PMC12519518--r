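#' Confusion counts of BBBM calls against the amyloid reference
#'
#' Tallies the 2x2 table over participants with a *known* composite amyloid
#' status; participants whose reference is `"unknown"` are counted separately
#' and enter only the screen-out denominator.
#'
#' @param bbbm_calls Character vector of `"positive"`/`"negative"` calls.
#' @param composite_amyloid Parallel vector in `"positive"`, `"negative"`,
#'   `"unknown"` (`NA` treated as unknown).
#' @return A `confusion_counts` object.
#' @export
confusion <- function(bbbm_calls, composite_amyloid) {
  if (length(bbbm_calls) != length(composite_amyloid)) {
    stop("Inputs must have equal length.", call. = FALSE)
  }
  if (!all(bbbm_calls %in% c("positive", "negative"))) {
    stop("`bbbm_calls` must be 'positive' or 'negative'.", call. = FALSE)
  }
  amy <- as.character(composite_amyloid)
  amy[is.na(amy)] <- "unknown"
  if (!all(amy %in% c("positive", "negative", "unknown"))) {
    stop("`composite_amyloid` entries must be positive/negative/unknown.",
         call. = FALSE)
  }
  known <- amy != "unknown"
  confusion_counts(
    tp = sum(bbbm_calls == "positive" & amy == "positive"),
    fp = sum(bbbm_calls == "positive" & amy == "negative"),
    tn = sum(bbbm_calls == "negative" & amy == "negative"),
    fn = sum(bbbm_calls == "negative" & amy == "positive"),
    n_negative_calls = sum(bbbm_calls == "negative"),
    n_total = length(bbbm_calls)
  )
}

#' Construct confusion counts directly
#'
#' Useful when only published counts are available. `n_negative_calls` and
#' `n_total` default to the reference-confirmed table but may exceed it when
#' some BBBM-tested participants lack a reference result (their calls still
#' count in the screen-out denominator).
#'
#' @param tp,fp,tn,fn Non-negative integers.
#' @param n_negative_calls Total BBBM-negative calls (>= tn + fn).
#' @param n_total Total participants with a BBBM result (>= tp+fp+tn+fn).
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fp, tn, fn,
                             n_negative_calls = tn + fn,
                             n_total = tp + fp + tn + fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("Counts must be non-negative integers.", call. = FALSE)
  }
  if (n_total < tp + fp + tn + fn) {
    stop("`n_total` must be at least tp + fp + tn + fn.", call. = FALSE)
  }
  if (n_negative_calls < tn + fn) {
    stop("`n_negative_calls` must be at least tn + fn.", call. = FALSE)
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn),
                 n_negative_calls = as.integer(n_negative_calls),
                 n_total = as.integer(n_total),
                 n_unknown = as.integer(n_total - (tp + fp + tn + fn))),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts>\n")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d  (unknown reference: %d of %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$n_unknown, x$n_total))
  invisible(x)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes,trials Integers with `0 <= successes <= trials`,
#'   `trials >= 1`.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`, clipped to \[0, 1\];
#'   `c(NA, NA)` when `trials` is 0.
#' @examples
#' wilson_ci(6, 49)
#' @export
wilson_ci <- function(successes, trials, level = 0.95) {
  check_probability(level, "level")
  if (trials == 0) return(c(lower = NA_real_, upper = NA_real_))
  if (successes < 0 || successes > trials) {
    stop("`successes` must lie in [0, trials].", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  centre <- (p + z^2 / (2 * trials)) / denom
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Agreement metrics with Wilson confidence intervals
#'
#' Computes, from confusion counts, the descriptive agreement metrics of a
#' rule-out pre-screening test versus an (imperfect) amyloid reference:
#' prevalence `(TP+FN)/(TP+FP+TN+FN)`, PPA `TP/(TP+FN)`, NPA `TN/(TN+FP)`,
#' PPV `TP/(TP+FP)`, 1-NPV `FN/(TN+FN)`, and two screen-out rates — among
#' everyone with a BBBM result (`screen_out_rate`) and among the
#' reference-confirmed subset (`screen_out_confirmed`). A metric whose
#' denominator is zero is reported as `NA` (undefined), never as 0.
#'
#' @param counts A [confusion_counts()] object.
#' @param ci_level Confidence level for the Wilson intervals (default 0.95).
#' @return An `agreement_report`: named list of point estimates plus a `ci`
#'   list with Wilson intervals for `ppa`, `npa`, `ppv`, `one_minus_npv`.
#' @export
agreement_metrics <- function(counts, ci_level = 0.95) {
  if (!inherits(counts, "confusion_counts")) {
    stop("`counts` must be a confusion_counts object.", call. = FALSE)
  }
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  ci_of <- function(num, den) {
    if (den > 0) wilson_ci(num, den, ci_level) else c(lower = NA_real_, upper = NA_real_)
  }
  with(counts, {
    n_known <- tp + fp + tn + fn
    structure(list(
      prevalence = ratio(tp + fn, n_known),
      ppa = ratio(tp, tp + fn),
      npa = ratio(tn, tn + fp),
      ppv = ratio(tp, tp + fp),
      one_minus_npv = ratio(fn, tn + fn),
      screen_out_rate = ratio(n_negative_calls, n_total),
      screen_out_confirmed = ratio(tn + fn, n_known),
      ci_level = ci_level,
      ci = list(ppa = ci_of(tp, tp + fn),
                npa = ci_of(tn, tn + fp),
                ppv = ci_of(tp, tp + fp),
                one_minus_npv = ci_of(fn, tn + fn)),
      counts = counts
    ), class = "agreement_report")
  })
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  line <- function(label, v, ci = NULL) {
    s <- sprintf("  %-22s %s", label, fmt_pct(v))
    if (!is.null(ci) && !anyNA(ci)) {
      s <- sprintf("%s  (%s CI %s - %s)", s,
                   fmt_pct(x$ci_level), fmt_pct(ci[["lower"]]),
                   fmt_pct(ci[["upper"]]))
    }
    cat(s, "\n")
  }
  line("prevalence", x$prevalence)
  line("PPA", x$ppa, x$ci$ppa)
  line("NPA", x$npa, x$ci$npa)
  line("PPV", x$ppv, x$ci$ppv)
  line("1-NPV", x$one_minus_npv, x$ci$one_minus_npv)
  line("screen-out (all)", x$screen_out_rate)
  line("screen-out (confirmed)", x$screen_out_confirmed)
  invisible(x)
}

# Plain-list view used for JSON serialization.
report_as_list <- function(x) {
  list(
    prevalence = x$prevalence, ppa = x$ppa, npa = x$npa, ppv = x$ppv,
    one_minus_npv = x$one_minus_npv,
    screen_out_rate = x$screen_out_rate,
    screen_out_confirmed = x$screen_out_confirmed,
    ci_level = x$ci_level,
    ci = lapply(x$ci, function(v) list(lower = v[["lower"]], upper = v[["upper"]])),
    counts = list(tp = x$counts$tp, fp = x$counts$fp, tn = x$counts$tn,
                  fn = x$counts$fn, n_total = x$counts$n_total,
                  n_unknown = x$counts$n_unknown)
  )
}
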