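#' Read and write cohort tables
#'
#' The on-disk cohort format is a plain CSV with header `id, amyloid_true,
#' apoe4p_carrier_true, apoe4p_conc, ptau181, gfap, abeta42, abeta40,
#' pet_result, csf_ptau181, csf_abeta42`; missing values (including a
#' missing PET read) are written as empty fields. Any extra columns a
#' pipeline has added (`composite_amyloid`, `bbbm_call`, ...) are preserved.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a
#'   `bbbm_cohort` data frame.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  if ("pet_result" %in% names(out)) {
    out$pet_result[out$pet_result == "missing"] <- ""
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  required <- c("id", "amyloid_true", "apoe4p_carrier_true", "apoe4p_conc",
                "ptau181", "gfap", "abeta42", "abeta40", "pet_result",
                "csf_ptau181", "csf_abeta42")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("Cohort CSV lacks column(s): %s.",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df$pet_result <- as.character(df$pet_result)
  df$pet_result[is.na(df$pet_result) | df$pet_result == ""] <- "missing"
  structure(df, class = c("bbbm_cohort", "data.frame"))
}

#' Serialize a cohort specification as a flat key-value config
#'
#' Plain-text `key: value` lines, one field per line, written with full
#' numeric precision so that write -> read round-trips exactly.
#'
#' @param spec A [cohort_spec()].
#' @param path File path.
#' @return `write_cohort_spec()` returns `path` invisibly;
#'   `read_cohort_spec()` a validated `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  validate_cohort_spec(spec)
  lines <- vapply(names(spec), function(k) {
    sprintf("%s: %s", k, format(spec[[k]], digits = 17, scientific = FALSE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[[1L]]), character(1))
  vals <- vapply(kv, function(x) trimws(paste(x[-1L], collapse = ":")),
                 character(1))
  args <- as.list(as.numeric(vals))
  names(args) <- keys
  args$n <- as.integer(args$n)
  args$seed <- as.integer(args$seed)
  do.call(cohort_spec, args)
}
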