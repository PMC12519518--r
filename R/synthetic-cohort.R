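#' Generate a synthetic pre-screening cohort
#'
#' Draws `spec$n` participant records: carrier status is Bernoulli with the
#' spec's carrier prevalence, amyloid status Bernoulli within carrier stratum,
#' plasma markers log10-normal within amyloid stratum (ApoE4p within carrier
#' stratum), each marker then multiplied by its pre-analytical bias factor and
#' by lognormal assay noise of coefficient of variation `assay_cv`.
#' Confirmatory reference results (a PET visual read mirroring true amyloid
#' status, and CSF pTau181/Abeta42 concentrations from the spec's CSF model)
#' are generated and thinned by `confirm_fraction`, `pet_fraction` and
#' `csf_fraction`, independently of marker values. Ground truth
#' (`amyloid_true`, `apoe4p_carrier_true`) is retained for every record.
#'
#' The same `spec` and `seed` always produce a bit-identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return A `bbbm_cohort`: a data frame with columns `id`, `amyloid_true`,
#'   `apoe4p_carrier_true`, `apoe4p_conc`, `ptau181`, `gfap`, `abeta42`,
#'   `abeta40`, `pet_result`, `csf_ptau181`, `csf_abeta42`, plus attributes
#'   `spec_used` and `seed_used`.
#' @examples
#' coh <- generate_cohort(a4_spec(n = 500))
#' mean(coh$amyloid_true)
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  validate_cohort_spec(spec)
  n <- as.integer(spec$n)
  with_seed(seed, {
    carrier <- stats::rbinom(n, 1L, spec$carrier_prevalence)
    amyloid <- stats::rbinom(
      n, 1L,
      ifelse(carrier == 1L, spec$amyloid_prev_carrier,
             spec$amyloid_prev_noncarrier))

    draw_marker <- function(loc_neg, loc_pos, scale, bias) {
      loc <- ifelse(amyloid == 1L, loc_pos, loc_neg)
      x <- 10^stats::rnorm(n, loc, scale)
      if (spec$assay_cv > 0) {
        x <- x * 10^stats::rnorm(n, 0, cv_to_log10_sd(spec$assay_cv))
      }
      x * bias
    }

    ptau <- draw_marker(spec$ptau_loc_neg, spec$ptau_loc_pos,
                        spec$ptau_scale, spec$bias_ptau181)
    gfap <- draw_marker(spec$gfap_loc_neg, spec$gfap_loc_pos,
                        spec$gfap_scale, spec$bias_gfap)
    ab42 <- draw_marker(spec$abeta42_loc_neg, spec$abeta42_loc_pos,
                        spec$abeta42_scale, spec$bias_abeta42)
    ab40 <- draw_marker(spec$abeta40_loc_neg, spec$abeta40_loc_pos,
                        spec$abeta40_scale, spec$bias_abeta40)

    apoe_loc <- ifelse(carrier == 1L, spec$apoe4p_carrier_loc,
                       spec$apoe4p_noncarrier_loc)
    apoe_scale <- ifelse(carrier == 1L, spec$apoe4p_carrier_scale,
                         spec$apoe4p_noncarrier_scale)
    apoe <- 10^stats::rnorm(n, apoe_loc, apoe_scale)
    if (spec$assay_cv > 0) {
      apoe <- apoe * 10^stats::rnorm(n, 0, cv_to_log10_sd(spec$assay_cv))
    }
    apoe <- apoe * spec$bias_apoe4p

    confirmed <- stats::rbinom(n, 1L, spec$confirm_fraction) == 1L
    has_pet <- confirmed & stats::rbinom(n, 1L, spec$pet_fraction) == 1L
    has_csf <- confirmed & stats::rbinom(n, 1L, spec$csf_fraction) == 1L
    # a confirmed participant must carry at least one reference modality
    has_pet[confirmed & !has_pet & !has_csf] <- TRUE

    pet <- rep("missing", n)
    pet[has_pet] <- ifelse(amyloid[has_pet] == 1L, "positive", "negative")

    csf_pt <- 10^stats::rnorm(
      n, ifelse(amyloid == 1L, spec$csf_ptau_loc_pos, spec$csf_ptau_loc_neg),
      spec$csf_ptau_scale)
    csf_ab <- 10^stats::rnorm(
      n, ifelse(amyloid == 1L, spec$csf_abeta42_loc_pos, spec$csf_abeta42_loc_neg),
      spec$csf_abeta42_scale)
    csf_pt[!has_csf] <- NA_real_
    csf_ab[!has_csf] <- NA_real_

    out <- data.frame(
      id = sprintf("P%06d", seq_len(n)),
      amyloid_true = amyloid,
      apoe4p_carrier_true = carrier,
      apoe4p_conc = apoe,
      ptau181 = ptau,
      gfap = gfap,
      abeta42 = ab42,
      abeta40 = ab40,
      pet_result = pet,
      csf_ptau181 = csf_pt,
      csf_abeta42 = csf_ab,
      stringsAsFactors = FALSE
    )
    new_cohort(out, spec, as.integer(seed))
  })
}

new_cohort <- function(df, spec, seed) {
  structure(df,
            spec_used = spec,
            seed_used = seed,
            class = c("bbbm_cohort", "data.frame"))
}

#' @export
print.bbbm_cohort <- function(x, ...) {
  cat(sprintf("<bbbm_cohort> %d participants (seed %s)\n",
              nrow(x), format(attr(x, "seed_used"))))
  cat(sprintf("  amyloid prevalence %.4f; ApoE4p carrier prevalence %.4f\n",
              mean(x$amyloid_true), mean(x$apoe4p_carrier_true)))
  print(utils::head(as.data.frame(x), 4L))
  invisible(x)
}

#' Perturb assay measurements of an existing cohort
#'
#' Applies multiplicative pre-analytical bias and lognormal measurement noise
#' to the plasma marker columns of a cohort, leaving ground truth and
#' reference results untouched. Used to probe robustness of an operating
#' point to sample-handling variation and assay error.
#'
#' @param cohort A `bbbm_cohort` (or compatible data frame).
#' @param bias Either a single multiplicative factor applied to every plasma
#'   marker, or a named vector with any of `apoe4p_conc`, `ptau181`, `gfap`,
#'   `abeta42`, `abeta40`.
#' @param cv Fractional coefficient of variation of the noise (>= 0).
#' @param seed RNG seed for the noise draws.
#' @return A new cohort of the same class; with `bias = 1, cv = 0` the marker
#'   columns are returned unchanged.
#' @export
apply_assay_perturbation <- function(cohort, bias = 1, cv = 0, seed = 1L) {
  markers <- c("apoe4p_conc", "ptau181", "gfap", "abeta42", "abeta40")
  if (!all(markers %in% names(cohort))) {
    stop("`cohort` lacks plasma marker columns.", call. = FALSE)
  }
  if (!is.numeric(cv) || length(cv) != 1L || cv < 0) {
    stop("`cv` must be a single non-negative number.", call. = FALSE)
  }
  if (is.null(names(bias))) {
    if (length(bias) != 1L) stop("Unnamed `bias` must be a scalar.", call. = FALSE)
    bias <- stats::setNames(rep(bias, length(markers)), markers)
  } else {
    unknown <- setdiff(names(bias), markers)
    if (length(unknown)) {
      stop(sprintf("Unknown marker(s) in `bias`: %s.",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    full <- stats::setNames(rep(1, length(markers)), markers)
    full[names(bias)] <- bias
    bias <- full
  }
  if (any(bias <= 0)) stop("All `bias` factors must be > 0.", call. = FALSE)

  out <- cohort
  with_seed(seed, {
    for (m in markers) {
      x <- out[[m]] * bias[[m]]
      if (cv > 0) {
        x <- x * 10^stats::rnorm(length(x), 0, cv_to_log10_sd(cv))
      }
      out[[m]] <- x
    }
  })
  out
}
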