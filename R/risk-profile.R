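#' Fit a logistic amyloid-risk model over plasma biomarkers
#'
#' Amyloid status (known composite reference) is regressed on the requested
#' predictors by maximum likelihood (IRLS; convergence when the deviance
#' change is below 1e-8 or after 100 iterations). Predictors are transformed
#' to the scales used throughout: continuous markers (`ptau181`, `gfap`,
#' `abeta42`, `abeta40`) enter log10-transformed, `abeta_ratio` enters as
#' `log10(abeta42/abeta40)`, and `apoe4p` enters as the binary carrier
#' indicator (concentration above the ApoE4p cutoff). Perfect separation is
#' detected and flagged, not silently ignored.
#'
#' @param cohort Cohort data frame; a `composite_amyloid` column is computed
#'   if absent. Rows with unknown status are dropped before fitting.
#' @param predictors Character vector drawn from `"apoe4p"`, `"ptau181"`,
#'   `"gfap"`, `"abeta42"`, `"abeta40"`, `"abeta_ratio"`. Default is the
#'   deployed pair, `c("apoe4p", "ptau181")`.
#' @param apoe4p_cutoff Carrier cutoff used for the binary ApoE4p predictor.
#' @return A `risk_model`: the `glm` fit, aligned `fitted` probabilities and
#'   binary `truth`, the predictor set, and a `separation` flag.
#' @export
fit_logistic <- function(cohort, predictors = c("apoe4p", "ptau181"),
                         apoe4p_cutoff = 0.668) {
  allowed <- c("apoe4p", "ptau181", "gfap", "abeta42", "abeta40", "abeta_ratio")
  bad <- setdiff(predictors, allowed)
  if (length(bad)) {
    stop(sprintf("Unknown predictor(s): %s.", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (!"composite_amyloid" %in% names(cohort)) {
    cohort <- add_composite_amyloid(cohort)
  }
  dat <- cohort[cohort$composite_amyloid != "unknown", , drop = FALSE]
  y <- as.integer(dat$composite_amyloid == "positive")
  if (length(unique(y)) < 2L) {
    stop("Both amyloid classes must be present to fit a risk model.",
         call. = FALSE)
  }
  X <- data.frame(row.names = seq_along(y))
  for (p in predictors) {
    X[[p]] <- switch(
      p,
      apoe4p = as.integer(dat$apoe4p_conc > apoe4p_cutoff),
      abeta_ratio = log10(dat$abeta42 / dat$abeta40),
      log10(dat[[p]])
    )
  }
  if (anyNA(X)) stop("Predictors must be complete (no NA).", call. = FALSE)
  df <- cbind(y = y, X)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  structure(list(fit = fit,
                 coefficients = stats::coef(fit),
                 fitted = as.numeric(stats::fitted(fit)),
                 truth = y,
                 predictors = predictors,
                 separation = separation),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> amyloid ~ %s (n = %d%s)\n",
              paste(x$predictors, collapse = " + "), length(x$truth),
              if (x$separation) "; WARNING: separation detected" else ""))
  print(signif(x$coefficients, 4))
  invisible(x)
}

# Largest screened-out count <= k such that no tied fitted risks straddle
# the cut (ties are kept together on the retained side).
tie_adjusted_cut <- function(sorted_risk, k) {
  n <- length(sorted_risk)
  while (k > 0 && k < n && sorted_risk[k] == sorted_risk[k + 1]) k <- k - 1L
  k
}

#' Risk-percentile predictiveness curves
#'
#' Ranks participants by fitted risk and, for each percentile `q` on the
#' grid (interpreted as the hypothetical screen-out rate), computes the
#' non-parametric PPV — the amyloid-positive fraction among the retained top
#' `1 - q` of risk — and 1-NPV — the positive fraction among the screened-out
#' bottom `q`. Percentiles are empirical ranks over `n` (no interpolation);
#' tied fitted risks stay together on the retained side of any cut. Each raw
#' curve is smoothed by isotonic (PAVA) regression on the grid, and the
#' prevalence-determined optimal curves are overlaid: for `q <= 1 - pi`,
#' `ppv_opt = pi/(1-q)` and `1-NPV_opt = 0`; beyond, `ppv_opt = 1` and
#' `1-NPV_opt = (q - (1-pi))/q`. 1-NPV at `q = 0` (empty screened-out set)
#' is undefined and reported `NA`; likewise PPV at `q = 1`.
#'
#' @param model A `risk_model` from [fit_logistic()], or a numeric vector of
#'   fitted risks (then `truth` is required).
#' @param truth Binary amyloid truth aligned with the risks (ignored when
#'   `model` is a `risk_model`).
#' @param grid_points Number of equally spaced percentiles (default 101).
#' @return A `risk_profile` data frame with columns `q`, `risk` (fitted risk
#'   at the percentile), `ppv_raw`, `ppv_smooth`, `one_minus_npv_raw`,
#'   `one_minus_npv_smooth`, `ppv_opt`, `one_minus_npv_opt`; attribute
#'   `prevalence`.
#' @export
predictiveness_curves <- function(model, truth = NULL, grid_points = 101L) {
  if (inherits(model, "risk_model")) {
    fitted <- model$fitted
    truth <- model$truth
  } else {
    fitted <- as.numeric(model)
    if (is.null(truth)) stop("`truth` required with raw fitted risks.",
                             call. = FALSE)
  }
  truth <- as.integer(truth)
  if (length(fitted) != length(truth)) {
    stop("Risks and truth must be aligned.", call. = FALSE)
  }
  if (!any(truth == 1L) || !any(truth == 0L)) {
    stop("Both amyloid classes must be present.", call. = FALSE)
  }
  n <- length(fitted)
  ord <- order(fitted)
  r <- fitted[ord]
  y <- truth[ord]
  cum_pos <- cumsum(y)
  total_pos <- cum_pos[n]
  pi_hat <- total_pos / n

  q <- seq(0, 1, length.out = as.integer(grid_points))
  k_raw <- pmin(n, floor(q * n + 1e-9))
  rows <- vapply(k_raw, function(k) {
    k <- tie_adjusted_cut(r, k)
    pos_below <- if (k > 0) cum_pos[k] else 0L
    onm <- if (k > 0) pos_below / k else NA_real_
    ppv <- if (k < n) (total_pos - pos_below) / (n - k) else NA_real_
    risk_q <- if (k < n) r[k + 1L] else r[n]
    c(k = k, risk = risk_q, ppv = ppv, onm = onm)
  }, numeric(4))

  ppv_raw <- rows["ppv", ]
  onm_raw <- rows["onm", ]
  opt_ppv <- ifelse(q <= 1 - pi_hat, pmin(1, pi_hat / (1 - q)), 1)
  opt_ppv[q >= 1] <- 1
  opt_onm <- ifelse(q <= 1 - pi_hat, 0, (q - (1 - pi_hat)) / q)

  out <- data.frame(
    q = q,
    risk = rows["risk", ],
    ppv_raw = ppv_raw,
    ppv_smooth = isotonic_fit(q, ppv_raw),
    one_minus_npv_raw = onm_raw,
    one_minus_npv_smooth = isotonic_fit(q, onm_raw),
    ppv_opt = opt_ppv,
    one_minus_npv_opt = opt_onm
  )
  structure(out, prevalence = pi_hat,
            class = c("risk_profile", "data.frame"))
}

# Isotonic (non-decreasing) least-squares fit on a grid, tolerating NA
# entries: fitted only at defined points, NA preserved elsewhere.
isotonic_fit <- function(x, y) {
  out <- rep(NA_real_, length(y))
  ok <- !is.na(y)
  if (sum(ok) >= 1L) {
    out[ok] <- stats::isoreg(x[ok], y[ok])$yf
  }
  out
}

#' @export
print.risk_profile <- function(x, ...) {
  cat(sprintf("<risk_profile> %d percentiles; observed prevalence %s\n",
              nrow(x), fmt_pct(attr(x, "prevalence"))))
  print(utils::head(as.data.frame(signif(as.matrix(x), 3)), 5L))
  invisible(x)
}

#' Rank-based AUC (concordance probability)
#'
#' Mann-Whitney estimator of `P(score_pos > score_neg)` with ties counted
#' one half. Invariant under strictly monotone transforms of the scores.
#'
#' @param scores Numeric risk scores (or a `risk_model`, whose fitted
#'   probabilities are used).
#' @param truth Binary outcome aligned with scores.
#' @return AUC in \[0, 1\]; `NA` when only one class is present.
#' @export
auc_rank <- function(scores, truth = NULL) {
  if (inherits(scores, "risk_model")) {
    truth <- scores$truth
    scores <- scores$fitted
  }
  truth <- as.integer(truth)
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compare candidate biomarker combinations by AUC
#'
#' Fits one logistic risk model per combination — pTau181 + ApoE4p,
#' GFAP + ApoE4p, and Abeta42/Abeta40 + ApoE4p (the ratio entering as a
#' single log10 predictor) — and tabulates their rank-based AUCs.
#'
#' @param cohort Cohort data frame with all plasma markers.
#' @param apoe4p_cutoff Carrier cutoff for the binary ApoE4p predictor.
#' @return Data frame with `combination`, `auc`, `n`, `separation`, ordered
#'   as listed above; attribute `models` holds the fitted `risk_model`s.
#' @export
compare_combinations <- function(cohort, apoe4p_cutoff = 0.668) {
  combos <- list(
    "pTau181 + ApoE4p" = c("apoe4p", "ptau181"),
    "GFAP + ApoE4p" = c("apoe4p", "gfap"),
    "Abeta42/Abeta40 + ApoE4p" = c("apoe4p", "abeta_ratio")
  )
  models <- lapply(combos, function(p) {
    fit_logistic(cohort, predictors = p, apoe4p_cutoff = apoe4p_cutoff)
  })
  out <- data.frame(
    combination = names(combos),
    auc = vapply(models, auc_rank, numeric(1)),
    n = vapply(models, function(m) length(m$truth), numeric(1)),
    separation = vapply(models, function(m) m$separation, logical(1)),
    stringsAsFactors = FALSE
  )
  attr(out, "models") <- models
  out
}
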