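#' Specify a synthetic pre-screening cohort
#'
#' A `cohort_spec` describes the joint distribution from which
#' [generate_cohort()] draws participant records: carrier-status and
#' amyloid-status prevalences, per-stratum log10-normal plasma biomarker
#' distributions, the ApoE4p concentration mixture that encodes carrier
#' status, a CSF model for the confirmatory reference, and assay-noise /
#' missingness knobs.
#'
#' Plasma markers (pTau181, GFAP, Abeta42, Abeta40) are log10-normal within
#' each amyloid stratum: `10^Normal(loc, scale)`. ApoE4p concentration is a
#' two-component log10-normal mixture indexed by true carrier status, with
#' default components far enough from the 0.668 ug/mL carrier cutoff that
#' threshold carriage and true carriage agree almost surely. CSF pTau181 and
#' Abeta42 are log10-normal per amyloid stratum, calibrated so the
#' pTau181/Abeta42 > 0.04 ratio rule reproduces true amyloid status with
#' negligible error.
#'
#' @param n Number of participants (positive integer).
#' @param carrier_prevalence Probability of ApoE4p carriage.
#' @param amyloid_prev_carrier,amyloid_prev_noncarrier Amyloid-positivity
#'   probability within carriers / non-carriers.
#' @param ptau_loc_neg,ptau_loc_pos,ptau_scale log10 location (amyloid
#'   negative / positive) and common log10 scale of plasma pTau181 (pg/mL).
#' @param gfap_loc_neg,gfap_loc_pos,gfap_scale Same for plasma GFAP (pg/mL).
#' @param abeta42_loc_neg,abeta42_loc_pos,abeta42_scale Same for plasma
#'   Abeta42 (pg/mL).
#' @param abeta40_loc_neg,abeta40_loc_pos,abeta40_scale Same for plasma
#'   Abeta40 (pg/mL).
#' @param apoe4p_noncarrier_loc,apoe4p_noncarrier_scale,apoe4p_carrier_loc,apoe4p_carrier_scale
#'   log10 mixture components of plasma ApoE4p concentration (ug/mL).
#' @param csf_ptau_loc_neg,csf_ptau_loc_pos,csf_ptau_scale log10 parameters of
#'   CSF pTau181 (pg/mL) per amyloid stratum.
#' @param csf_abeta42_loc_neg,csf_abeta42_loc_pos,csf_abeta42_scale log10
#'   parameters of CSF Abeta42 (pg/mL) per amyloid stratum.
#' @param assay_cv Fractional coefficient of variation of multiplicative
#'   assay noise applied to every plasma marker (>= 0; 0 disables noise).
#' @param bias_ptau181,bias_gfap,bias_abeta42,bias_abeta40,bias_apoe4p
#'   Multiplicative pre-analytical bias per plasma marker (> 0; 1 = none).
#' @param confirm_fraction Probability that a participant carries any
#'   confirmatory amyloid reference result at all.
#' @param pet_fraction,csf_fraction Probability that a confirmed participant
#'   has a PET read / a CSF result. A confirmed participant with neither is
#'   assigned a PET read so that `confirm_fraction` is honoured.
#' @param seed Default RNG seed used by [generate_cohort()] when no seed is
#'   passed explicitly.
#' @return An object of class `cohort_spec` (a validated named list).
#' @seealso [a4_spec()], [skyline_group1_spec()], [skyline_group2_spec()] for
#'   calibrated presets; [generate_cohort()].
#' @export
cohort_spec <- function(n = 10000L,
                        carrier_prevalence = 0.349,
                        amyloid_prev_carrier = 0.289,
                        amyloid_prev_noncarrier = 0.0863,
                        ptau_loc_neg = -0.157,
                        ptau_loc_pos = 0.150,
                        ptau_scale = 0.20,
                        gfap_loc_neg = log10(95),
                        gfap_loc_pos = log10(130),
                        gfap_scale = 0.22,
                        abeta42_loc_neg = log10(19.4),
                        abeta42_loc_pos = log10(17.5),
                        abeta42_scale = 0.09,
                        abeta40_loc_neg = log10(202),
                        abeta40_loc_pos = log10(202),
                        abeta40_scale = 0.10,
                        apoe4p_noncarrier_loc = log10(0.05),
                        apoe4p_noncarrier_scale = 0.25,
                        apoe4p_carrier_loc = log10(5),
                        apoe4p_carrier_scale = 0.20,
                        csf_ptau_loc_neg = log10(16),
                        csf_ptau_loc_pos = log10(36),
                        csf_ptau_scale = 0.07,
                        csf_abeta42_loc_neg = log10(880),
                        csf_abeta42_loc_pos = log10(400),
                        csf_abeta42_scale = 0.07,
                        assay_cv = 0,
                        bias_ptau181 = 1, bias_gfap = 1, bias_abeta42 = 1,
                        bias_abeta40 = 1, bias_apoe4p = 1,
                        confirm_fraction = 1,
                        pet_fraction = 1,
                        csf_fraction = 0,
                        seed = 20260909L) {
  spec <- list(
    n = as.integer(n),
    carrier_prevalence = carrier_prevalence,
    amyloid_prev_carrier = amyloid_prev_carrier,
    amyloid_prev_noncarrier = amyloid_prev_noncarrier,
    ptau_loc_neg = ptau_loc_neg, ptau_loc_pos = ptau_loc_pos,
    ptau_scale = ptau_scale,
    gfap_loc_neg = gfap_loc_neg, gfap_loc_pos = gfap_loc_pos,
    gfap_scale = gfap_scale,
    abeta42_loc_neg = abeta42_loc_neg, abeta42_loc_pos = abeta42_loc_pos,
    abeta42_scale = abeta42_scale,
    abeta40_loc_neg = abeta40_loc_neg, abeta40_loc_pos = abeta40_loc_pos,
    abeta40_scale = abeta40_scale,
    apoe4p_noncarrier_loc = apoe4p_noncarrier_loc,
    apoe4p_noncarrier_scale = apoe4p_noncarrier_scale,
    apoe4p_carrier_loc = apoe4p_carrier_loc,
    apoe4p_carrier_scale = apoe4p_carrier_scale,
    csf_ptau_loc_neg = csf_ptau_loc_neg, csf_ptau_loc_pos = csf_ptau_loc_pos,
    csf_ptau_scale = csf_ptau_scale,
    csf_abeta42_loc_neg = csf_abeta42_loc_neg,
    csf_abeta42_loc_pos = csf_abeta42_loc_pos,
    csf_abeta42_scale = csf_abeta42_scale,
    assay_cv = assay_cv,
    bias_ptau181 = bias_ptau181, bias_gfap = bias_gfap,
    bias_abeta42 = bias_abeta42, bias_abeta40 = bias_abeta40,
    bias_apoe4p = bias_apoe4p,
    confirm_fraction = confirm_fraction,
    pet_fraction = pet_fraction,
    csf_fraction = csf_fraction,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' Checks every invariant of a [cohort_spec()]; errors name the offending
#' field.
#' @param spec A `cohort_spec`.
#' @return `spec`, invisibly, if valid.
#' @export
validate_cohort_spec <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec.")
  if (!is.numeric(spec$n) || length(spec$n) != 1L || spec$n < 1 ||
      spec$n != round(spec$n)) {
    stop("`n` must be a positive integer.", call. = FALSE)
  }
  for (f in c("carrier_prevalence", "amyloid_prev_carrier",
              "amyloid_prev_noncarrier", "confirm_fraction",
              "pet_fraction", "csf_fraction")) {
    check_probability(spec[[f]], f)
  }
  for (f in grep("_scale$", names(spec), value = TRUE)) {
    check_positive(spec[[f]], f)
  }
  for (f in grep("^bias_", names(spec), value = TRUE)) {
    check_positive(spec[[f]], f)
  }
  if (!is.numeric(spec$assay_cv) || spec$assay_cv < 0) {
    stop("`assay_cv` must be >= 0.", call. = FALSE)
  }
  mix <- spec$carrier_prevalence * spec$amyloid_prev_carrier +
    (1 - spec$carrier_prevalence) * spec$amyloid_prev_noncarrier
  if (mix < 0 || mix > 1) {
    stop("Implied overall amyloid prevalence outside [0, 1].", call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  pi <- mixture_prevalence(x$carrier_prevalence, x$amyloid_prev_carrier,
                           x$amyloid_prev_noncarrier)
  cat("<cohort_spec>\n")
  cat(sprintf("  n = %d, seed = %d\n", x$n, x$seed))
  cat(sprintf("  carrier prevalence %.3f; amyloid prevalence %.3f (carriers) / %.4f (non-carriers); overall %.4f\n",
              x$carrier_prevalence, x$amyloid_prev_carrier,
              x$amyloid_prev_noncarrier, pi))
  cat(sprintf("  pTau181 log10 loc %.4f / %.4f (A- / A+), scale %.2f\n",
              x$ptau_loc_neg, x$ptau_loc_pos, x$ptau_scale))
  cat(sprintf("  assay_cv %.3f; confirm %.2f (PET %.2f, CSF %.2f)\n",
              x$assay_cv, x$confirm_fraction, x$pet_fraction, x$csf_fraction))
  invisible(x)
}

#' Required pTau181-step operating point among non-carriers
#'
#' The two-step rule calls every ApoE4p carrier positive, so the pTau181
#' threshold acts only inside the non-carrier stratum. Given stratified
#' prevalences and algorithm-level PPA/NPA targets, this decomposes the
#' targets into the sensitivity and specificity the pTau181 step must achieve
#' among non-carriers:
#' \deqn{Se = (PPA - P(c \mid A+)) / (1 - P(c \mid A+)),\quad
#'       Sp = NPA / P(nc \mid A-)}
#' with \eqn{P(c \mid A+) = p_c \pi_c / \pi} and
#' \eqn{P(nc \mid A-) = (1-p_c)(1-\pi_{nc}) / (1-\pi)}.
#'
#' @param p_carrier Carrier prevalence.
#' @param prev_carrier,prev_noncarrier Amyloid prevalence within carriers /
#'   non-carriers.
#' @param target_ppa,target_npa Algorithm-level PPA and NPA targets.
#' @return Named list with `se_ptau`, `sp_ptau`, and the intermediate
#'   conditional probabilities `p_carrier_given_pos`, `p_noncarrier_given_neg`.
#' @examples
#' derive_stratum_operating_points(0.349, 0.289, 0.0863, 0.955, 0.458)
#' @export
derive_stratum_operating_points <- function(p_carrier, prev_carrier,
                                            prev_noncarrier,
                                            target_ppa, target_npa) {
  check_probability(p_carrier, "p_carrier")
  check_probability(prev_carrier, "prev_carrier")
  check_probability(prev_noncarrier, "prev_noncarrier")
  check_probability(target_ppa, "target_ppa")
  check_probability(target_npa, "target_npa")
  pi <- mixture_prevalence(p_carrier, prev_carrier, prev_noncarrier)
  if (pi <= 0 || pi >= 1) {
    stop("Implied overall prevalence must lie strictly in (0, 1).",
         call. = FALSE)
  }
  p_c_pos <- p_carrier * prev_carrier / pi
  p_nc_neg <- (1 - p_carrier) * (1 - prev_noncarrier) / (1 - pi)
  if (target_ppa < p_c_pos) {
    stop(sprintf(
      "Infeasible PPA target: the carrier step alone yields PPA %.4f > target %.4f.",
      p_c_pos, target_ppa), call. = FALSE)
  }
  se <- if (p_c_pos >= 1) 0 else (target_ppa - p_c_pos) / (1 - p_c_pos)
  sp <- target_npa / p_nc_neg
  if (sp > 1 + 1e-12) {
    stop(sprintf(
      "Infeasible NPA target: requires pTau181 specificity %.4f > 1 among non-carriers.",
      sp), call. = FALSE)
  }
  list(se_ptau = se, sp_ptau = min(sp, 1),
       p_carrier_given_pos = p_c_pos, p_noncarrier_given_neg = p_nc_neg)
}

#' Calibrate a log10-normal location to an exceedance probability
#'
#' Returns the log10 location `mu` for which a `10^Normal(mu, scale)` draw
#' exceeds `cutoff` with probability `tail_probability`:
#' `mu = log10(cutoff) - scale * qnorm(1 - tail_probability)`.
#'
#' @param cutoff Positive concentration threshold.
#' @param tail_probability Target `P(X >= cutoff)`, in (0, 1).
#' @param log10_scale Positive log10-scale standard deviation.
#' @return The log10 location (numeric scalar).
#' @examples
#' calibrate_marker_location(0.830, 0.5, 0.2)   # median at the cutoff
#' @export
calibrate_marker_location <- function(cutoff, tail_probability, log10_scale) {
  check_positive(cutoff, "cutoff")
  check_positive(log10_scale, "log10_scale")
  if (!is_probability(tail_probability) || tail_probability <= 0 ||
      tail_probability >= 1) {
    stop("`tail_probability` must lie strictly in (0, 1).", call. = FALSE)
  }
  log10(cutoff) - log10_scale * stats::qnorm(1 - tail_probability)
}

# Calibrated preset shared by the study-like specs: derive the non-carrier
# pTau181 operating point from the stratified prevalences and the target
# algorithm-level PPA/NPA, then place the amyloid strata so the published
# 0.830 pg/mL cutoff attains it.
calibrated_spec <- function(n, p_carrier, prev_carrier, prev_noncarrier,
                            target_ppa, target_npa, seed, ptau_scale = 0.20,
                            ptau_cutoff = 0.830, ...) {
  op <- derive_stratum_operating_points(p_carrier, prev_carrier,
                                        prev_noncarrier, target_ppa, target_npa)
  cohort_spec(
    n = n,
    carrier_prevalence = p_carrier,
    amyloid_prev_carrier = prev_carrier,
    amyloid_prev_noncarrier = prev_noncarrier,
    ptau_loc_pos = calibrate_marker_location(ptau_cutoff, op$se_ptau, ptau_scale),
    ptau_loc_neg = calibrate_marker_location(ptau_cutoff, 1 - op$sp_ptau, ptau_scale),
    ptau_scale = ptau_scale,
    seed = seed,
    ...
  )
}

#' A4-like calibrated cohort specification
#'
#' Preset with the A4 screening cohort's printed structure: carrier
#' prevalence 34.9%, amyloid prevalence 28.9% in carriers and 8.63% in
#' non-carriers (overall 15.7%), pTau181 strata calibrated so the published
#' cutoffs (ApoE4p > 0.668 ug/mL, pTau181 >= 0.830 pg/mL) achieve
#' algorithm-level PPA 95.5% and NPA 45.8%. The confirmatory reference is
#' PET-only, available for everyone.
#'
#' @param n Cohort size.
#' @param seed Default generation seed.
#' @param ... Passed on to [cohort_spec()] to override other fields.
#' @return A `cohort_spec`.
#' @export
a4_spec <- function(n = 50000L, seed = 20260909L, ...) {
  calibrated_spec(n, p_carrier = 0.349, prev_carrier = 0.289,
                  prev_noncarrier = 0.0863,
                  target_ppa = 0.955, target_npa = 0.458, seed = seed,
                  pet_fraction = 1, csf_fraction = 0, ...)
}

#' SKYLINE-Group-2-like calibrated cohort specification
#'
#' Preset with the direct-entry group's printed structure: carrier prevalence
#' 29.1%, amyloid prevalence 21.3% in carriers and 8.65% in non-carriers
#' (overall 12.3%), pTau181 strata calibrated to algorithm-level PPA 94.6%
#' and NPA 44.5% at the published cutoffs. Reference is mixed PET/CSF.
#'
#' @inheritParams a4_spec
#' @return A `cohort_spec`.
#' @export
skyline_group2_spec <- function(n = 50000L, seed = 20260909L, ...) {
  calibrated_spec(n, p_carrier = 0.291, prev_carrier = 0.213,
                  prev_noncarrier = 0.0865,
                  target_ppa = 0.946, target_npa = 0.445, seed = seed,
                  pet_fraction = 0.6, csf_fraction = 0.7, ...)
}

#' SKYLINE-Group-1-like calibrated cohort specification
#'
#' Preset for the pre-screening population: the printed ApoE4p carrier
#' prevalence of 25.6% with the Group-2 stratum amyloid prevalences (the
#' pre-screening group's own stratum prevalences are not identifiable from
#' its blinded subsets). The lower carrier prevalence is what pushes the
#' expected screen-out rate above the 46% seen at pre-screening.
#'
#' @inheritParams a4_spec
#' @return A `cohort_spec`.
#' @export
skyline_group1_spec <- function(n = 50000L, seed = 20260909L, ...) {
  calibrated_spec(n, p_carrier = 0.256, prev_carrier = 0.213,
                  prev_noncarrier = 0.0865,
                  target_ppa = 0.946, target_npa = 0.445, seed = seed,
                  pet_fraction = 0.6, csf_fraction = 0.7, ...)
}
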