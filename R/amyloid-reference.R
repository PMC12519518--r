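#' CSF pTau181/Abeta42 ratio call
#'
#' An individual is CSF amyloid positive when the pTau181/Abeta42 ratio is
#' strictly greater than 0.04; a ratio of exactly 0.04 is negative.
#'
#' @param csf_ptau181,csf_abeta42 CSF concentrations (pg/mL), vectorised.
#'   `NA` in either yields `"missing"`.
#' @param cutoff Ratio cutoff (default 0.04, strict).
#' @return Character vector in `"positive"`, `"negative"`, `"missing"`.
#' @examples
#' csf_ratio_call(30, 600)  # ratio 0.05 -> positive
#' csf_ratio_call(24, 600)  # ratio exactly 0.04 -> negative
#' @export
csf_ratio_call <- function(csf_ptau181, csf_abeta42, cutoff = 0.04) {
  if (length(csf_ptau181) != length(csf_abeta42)) {
    stop("CSF inputs must have equal length.", call. = FALSE)
  }
  bad <- (!is.na(csf_ptau181) & csf_ptau181 <= 0) |
    (!is.na(csf_abeta42) & csf_abeta42 <= 0)
  if (any(bad)) {
    stop("CSF concentrations must be strictly positive when present.",
         call. = FALSE)
  }
  out <- rep("missing", length(csf_ptau181))
  known <- !is.na(csf_ptau181) & !is.na(csf_abeta42)
  out[known] <- ifelse(csf_ptau181[known] / csf_abeta42[known] > cutoff,
                       "positive", "negative")
  out
}

#' Composite amyloid status from PET and CSF calls
#'
#' OR-rule over the two reference modalities: any available positive result
#' makes the composite positive; the composite is negative when every
#' available result is negative; it is `"unknown"` only when both are
#' missing. Symmetric in its arguments and monotone (upgrading an input to
#' positive never downgrades the composite).
#'
#' @param pet_call,csf_call Character vectors in `"positive"`, `"negative"`,
#'   `"missing"` (`NA` treated as missing).
#' @return Character vector in `"positive"`, `"negative"`, `"unknown"`.
#' @export
composite_amyloid_status <- function(pet_call, csf_call) {
  if (length(pet_call) != length(csf_call)) {
    stop("`pet_call` and `csf_call` must have equal length.", call. = FALSE)
  }
  norm <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == ""] <- "missing"
    bad <- !x %in% c("positive", "negative", "missing")
    if (any(bad)) {
      stop(sprintf("Invalid reference call(s): %s.",
                   paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
    }
    x
  }
  pet <- norm(pet_call)
  csf <- norm(csf_call)
  out <- rep("unknown", length(pet))
  out[pet == "positive" | csf == "positive"] <- "positive"
  neg <- out == "unknown" & (pet == "negative" | csf == "negative")
  out[neg] <- "negative"
  out
}

#' Add the composite amyloid reference column to a cohort
#'
#' Computes the CSF ratio call from `csf_ptau181`/`csf_abeta42`, combines it
#' with `pet_result` by the OR-rule, and appends a `composite_amyloid`
#' column.
#'
#' @param cohort A cohort data frame with `pet_result`, `csf_ptau181`,
#'   `csf_abeta42` columns.
#' @param csf_cutoff CSF ratio cutoff (default 0.04).
#' @return The cohort with a `composite_amyloid` column in
#'   `"positive"`, `"negative"`, `"unknown"`.
#' @export
add_composite_amyloid <- function(cohort, csf_cutoff = 0.04) {
  needed <- c("pet_result", "csf_ptau181", "csf_abeta42")
  if (!all(needed %in% names(cohort))) {
    stop("`cohort` lacks reference columns pet_result/csf_ptau181/csf_abeta42.",
         call. = FALSE)
  }
  csf <- csf_ratio_call(cohort$csf_ptau181, cohort$csf_abeta42, csf_cutoff)
  cohort$composite_amyloid <- composite_amyloid_status(cohort$pet_result, csf)
  cohort
}
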