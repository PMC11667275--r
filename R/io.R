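#' Write and read a simulated cohort as CSV
#'
#' `write_cohort()` writes `cohort.csv` and `tracts.csv` into `path`
#' (created if needed); doubles are serialized at full precision
#' (`%.17g`) so the round trip is bit-for-bit, and missing values are
#' empty cells. `read_cohort()` reads them back, checking the tract table
#' schema (all 96 tract columns must be present; unknown extra columns are
#' kept with a warning).
#'
#' @param cohort clinical data.frame from [simulate_patients()].
#' @param tracts tract table data.frame.
#' @param path directory to write into / read from.
#' @return `write_cohort()` the path, invisibly; `read_cohort()` a list with
#'   `cohort` and `tracts`.
#' @export
write_cohort <- function(cohort, tracts, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_full_precision(cohort, file.path(path, "cohort.csv"))
  write_full_precision(tracts, file.path(path, "tracts.csv"))
  invisible(path)
}

write_full_precision <- function(df, file) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      x <- out[[j]]
      out[[j]] <- ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
    }
  }
  utils::write.csv(out, file, row.names = FALSE, na = "")
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cfile <- file.path(path, "cohort.csv")
  tfile <- file.path(path, "tracts.csv")
  for (f in c(cfile, tfile))
    if (!file.exists(f)) stop("expected file not found: ", f)
  cohort <- utils::read.csv(cfile, stringsAsFactors = FALSE)
  tracts <- utils::read.csv(tfile, stringsAsFactors = FALSE, check.names = FALSE)
  tc <- tract_columns()
  need <- c("subject_id", "scanner_id", "age", "sex", "days_since_injury",
            "mr_abnormality", tc$fa, tc$md)
  missing_cols <- setdiff(need, names(tracts))
  if (length(missing_cols))
    stop("tract table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(tracts), need)
  if (length(extra))
    warning("ignoring unknown tract-table column(s): ",
            paste(extra, collapse = ", "))
  tracts$mr_abnormality <- as.logical(tracts$mr_abnormality)
  list(cohort = cohort, tracts = tracts)
}
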