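# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#'
#' All stochastic operations in the package funnel through this helper so that
#' a given seed yields a bit-identical result without clobbering the caller's
#' random number stream.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Derive a reproducible child seed < 2^31 from a parent seed and a stream index.
derive_seed <- function(seed, stream) {
  s <- (abs(as.numeric(seed)) %% 1e6) * 1009 + stream * 7919
  as.integer(s %% 2147483647)
}

# Convert a fractional assay coefficient of variation into the standard
# deviation of multiplicative lognormal noise on the log10 scale:
# if X = mu * exp(N(0, s^2)) has CV c then s = sqrt(log(1 + c^2)).
cv_to_log10_sd <- function(cv) {
  sqrt(log(1 + cv^2)) / log(10)
}

is_probability <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

check_probability <- function(x, name) {
  if (!is_probability(x)) {
    stop(sprintf("`%s` must be a single probability in [0, 1].", name),
         call. = FALSE)
  }
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number.", name), call. = FALSE)
  }
  invisible(x)
}

# FNV-1a hash of a character scalar; used for config provenance only.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648), as.integer(b))
    h <- (h * 16777619) %% 2147483648
  }
  sprintf("%08x", as.integer(h))
}

# Uniform display rounding convention: proportions to 3 significant figures,
# percentages to 1 decimal place.
fmt_prop <- function(x) ifelse(is.na(x), "NA", signif(x, 3))
fmt_pct <- function(x) ifelse(is.na(x), "NA", sprintf("%.1f%%", 100 * x))
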