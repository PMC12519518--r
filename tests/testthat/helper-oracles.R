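# Independent oracles used to check package implementations. These are
# deliberately naive (brute force / numeric inversion) and share no code
# with the functions they verify.

# Wilson interval by numeric inversion of the score test: the bounds are the
# p for which |phat - p| / sqrt(p (1 - p) / n) equals z.
oracle_wilson <- function(x, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  phat <- x / n
  g <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
  lower <- if (phat == 0) 0 else
    uniroot(g, c(1e-12, phat - 1e-9), tol = 1e-12)$root
  upper <- if (phat == 1) 1 else
    uniroot(g, c(phat + 1e-9, 1), tol = 1e-12)$root
  c(lower = lower, upper = upper)
}

# Confusion counts by explicit looping.
oracle_confusion <- function(calls, amyloid) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(calls)) {
    if (amyloid[i] == "unknown") next
    pos <- calls[i] == "positive"
    amy <- amyloid[i] == "positive"
    if (pos && amy) tp <- tp + 1L
    if (pos && !amy) fp <- fp + 1L
    if (!pos && !amy) tn <- tn + 1L
    if (!pos && amy) fn <- fn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# AUC by enumerating every (positive, negative) pair.
oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Raw predictiveness values at a screened-out count k, by direct subsetting
# of the risk-sorted cohort (no tie handling: caller supplies tie-free risks).
oracle_predictiveness <- function(risk, truth, k) {
  ord <- order(risk)
  truth <- truth[ord]
  n <- length(truth)
  list(
    one_minus_npv = if (k > 0) mean(truth[seq_len(k)]) else NA_real_,
    ppv = if (k < n) mean(truth[(k + 1):n]) else NA_real_
  )
}

# Least-squares monotone (non-decreasing) fit by brute force over all
# partitions of 1..n into consecutive blocks (each candidate fit is constant
# at the block mean); returns the feasible fit minimizing the SSE. Exact for
# small n because the isotonic solution has this block structure.
oracle_isotonic <- function(y) {
  n <- length(y)
  best <- NULL
  best_sse <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    bounds <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    starts <- c(1, bounds + 1)
    ends <- c(bounds, n)
    fit <- numeric(n)
    means <- numeric(length(starts))
    for (b in seq_along(starts)) {
      means[b] <- mean(y[starts[b]:ends[b]])
      fit[starts[b]:ends[b]] <- means[b]
    }
    if (is.unsorted(means)) next
    sse <- sum((fit - y)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- fit
    }
  }
  best
}

# Exhaustive cutoff search sharing the package's declared tie-break rules
# but written as plain loops with raw arithmetic.
oracle_grid_search <- function(df, apoe_grid, ptau_grid,
                               min_so = 0.40, max_onm = 0.02) {
  best <- NULL
  for (a in sort(apoe_grid)) for (t in sort(ptau_grid)) {
    pos <- df$apoe4p_conc > a | (df$apoe4p_conc <= a & df$ptau181 >= t)
    known <- df$composite_amyloid != "unknown"
    amy <- df$composite_amyloid == "positive"
    tn <- sum(known & !pos & !amy)
    fp <- sum(known & pos & !amy)
    fn <- sum(known & !pos & amy)
    npa <- if (tn + fp > 0) tn / (tn + fp) else NA
    onm <- if (tn + fn > 0) fn / (tn + fn) else NA
    feasible <- !is.na(npa) && npa > min_so && !is.na(onm) && onm <= max_onm
    if (!feasible) next
    cand <- list(apoe = a, ptau = t, crit = npa, onm = onm)
    if (is.null(best) ||
        cand$crit > best$crit + 1e-12 ||
        (abs(cand$crit - best$crit) <= 1e-12 && cand$onm < best$onm - 1e-12) ||
        (abs(cand$crit - best$crit) <= 1e-12 && abs(cand$onm - best$onm) <= 1e-12 &&
           cand$ptau > best$ptau) ||
        (abs(cand$crit - best$crit) <= 1e-12 && abs(cand$onm - best$onm) <= 1e-12 &&
           cand$ptau == best$ptau && cand$apoe > best$apoe)) {
      best <- cand
    }
  }
  best
}

# Tiny hand-written cohort used by cutoff-derivation tests: 20 rows with a
# clear positive association between both markers and amyloid status.
make_hand_cohort <- function() {
  data.frame(
    apoe4p_conc = c(0.10, 0.20, 0.30, 0.40, 0.50, 0.55, 0.60, 0.62, 0.64,
                    0.66, 0.70, 0.80, 0.90, 1.20, 2.00, 0.15, 0.25, 0.35,
                    0.45, 3.00),
    ptau181 = c(0.40, 0.50, 0.55, 0.60, 0.65, 0.70, 0.75, 0.78, 0.80,
                0.82, 0.90, 1.00, 1.10, 1.30, 1.50, 0.45, 0.52, 0.58,
                0.95, 1.60),
    composite_amyloid = c("negative", "negative", "negative", "negative",
                          "negative", "negative", "negative", "negative",
                          "negative", "negative", "positive", "negative",
                          "positive", "positive", "positive", "negative",
                          "negative", "unknown", "positive", "positive"),
    stringsAsFactors = FALSE
  )
}
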