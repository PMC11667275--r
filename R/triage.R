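#' Biomarker cutoff under a minimum-sensitivity constraint
#'
#' Scans every candidate cutoff (midpoints between sorted unique
#' concentrations, plus extremes below the minimum and above the maximum)
#' with the positivity convention concentration `>=` cutoff (configurable to
#' strict `>`). Among cutoffs whose sensitivity for incomplete recovery meets
#' the floor, the one maximizing specificity is returned, ties broken toward
#' the higher cutoff.
#'
#' @param concentrations positive biomarker concentrations.
#' @param outcomes binary incomplete-recovery flags.
#' @param min_sensitivity the sensitivity floor (0.90 in the primary
#'   analysis; 1.00, 0.95, 0.80 as sensitivity analyses).
#' @param strict if `TRUE`, positivity is concentration `>` cutoff.
#' @return list with `cutoff`, `sensitivity`, `specificity` achieved, and an
#'   `infeasible` flag (no cutoff met the floor; the minimum concentration is
#'   returned so that every subject is scanned).
#' @export
choose_cutoff <- function(concentrations, outcomes, min_sensitivity = 0.90,
                          strict = FALSE) {
  x <- concentrations; y <- as.integer(outcomes)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (any(x <= 0)) stop("concentrations must be positive")
  if (length(unique(y)) < 2L) stop("both outcome classes are required")
  if (min_sensitivity < 0 || min_sensitivity > 1)
    stop("min_sensitivity must lie in [0, 1]")
  u <- sort(unique(x))
  cand <- c(u[1] / 2, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] * 2)
  sens_spec <- function(cut) {
    pos <- if (strict) x > cut else x >= cut
    c(sens = sum(pos & y == 1) / sum(y == 1),
      spec = sum(!pos & y == 0) / sum(y == 0))
  }
  grid <- t(vapply(cand, sens_spec, numeric(2)))
  feasible <- grid[, "sens"] >= min_sensitivity
  if (!any(feasible)) {
    best <- which.min(cand)
    return(list(cutoff = min(x), sensitivity = grid[best, "sens"],
                specificity = grid[best, "spec"], infeasible = TRUE))
  }
  gi <- which(feasible)
  best <- gi[order(-grid[gi, "spec"], -cand[gi])][1]
  list(cutoff = cand[best], sensitivity = unname(grid[best, "sens"]),
       specificity = unname(grid[best, "spec"]), infeasible = FALSE,
       # a zero floor optimizes specificity alone: nobody gets scanned
       degenerate = min_sensitivity == 0 && grid[best, "sens"] == 0)
}

#' Scan-triage consequences of a biomarker rule
#'
#' Converts a triage confusion matrix (positive = scan, event = incomplete
#' recovery) into the reporting quantities: avoided MRIs are true negatives
#' (not scanned, recovered), unnecessary MRIs are false positives (scanned,
#' recovered), missed incomplete recoveries are false negatives (not
#' scanned, did not recover). Display percentages are of the window total N,
#' rounded half-up; number needed to scan is scans performed per
#' incomplete-recovery patient scanned, `(TP + FP) / TP`, to one decimal.
#'
#' @param tp,fp,tn,fn confusion counts.
#' @return object of class `triage_result` (a list of all fields).
#' @export
triage_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  pct <- function(k) floor(100 * k / n + 0.5)  # round half-up for display
  structure(list(
    n = n, tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NaN,
    avoided_mris = tn, avoided_pct = pct(tn),
    unnecessary_mris = fp, unnecessary_pct = pct(fp),
    missed = fn, missed_pct = pct(fn),
    number_needed_to_scan = if (tp > 0) round((tp + fp) / tp, 1) else NaN,
    nns_undefined = tp == 0
  ), class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf(
    "Triage (N = %d): sens %.2f, spec %.2f | avoided %d (%d%%), unnecessary %d (%d%%), missed %d (%d%%), NNS %s\n",
    x$n, x$sensitivity, x$specificity,
    x$avoided_mris, x$avoided_pct, x$unnecessary_mris, x$unnecessary_pct,
    x$missed, x$missed_pct,
    if (x$nns_undefined) "undefined" else format(x$number_needed_to_scan)
  ))
  invisible(x)
}

#' Biomarker-triage table over markers and sampling windows
#'
#' For each biomarker and sampling window (`<12 h`, `12-24 h`), chooses the
#' cutoff under the sensitivity floor and reports the scan-triage
#' consequences; optionally sweeps additional sensitivity floors as a
#' companion table. Apparent (resubstitution) sensitivity and specificity
#' are reported, matching the exploratory character of the analysis.
#'
#' @param cohort clinical data.frame with `gfap`, `s100b`, `nfl`,
#'   `sample_time_h` and `outcome` columns (rows with missing outcome or
#'   marker are dropped per row of the table).
#' @param min_sensitivity primary sensitivity floor.
#' @param sweep optional vector of additional floors for the companion table.
#' @param strict positivity convention, as in [choose_cutoff()].
#' @return list with `table` (one row per biomarker x window) and, when
#'   `sweep` is given, `sweep_table`; windows with fewer than 10 subjects are
#'   flagged in column `small_sample`.
#' @export
triage_table <- function(cohort, min_sensitivity = 0.90, sweep = NULL,
                         strict = FALSE) {
  windows <- list(`<12 h` = c(0, 12), `12-24 h` = c(12, 24))
  markers <- c("gfap", "s100b", "nfl")
  one_row <- function(marker, wname, floor_) {
    w <- windows[[wname]]
    sel <- !is.na(cohort$outcome) & !is.na(cohort[[marker]]) &
      !is.na(cohort$sample_time_h) &
      cohort$sample_time_h >= w[1] & cohort$sample_time_h < w[2]
    x <- cohort[[marker]][sel]; y <- cohort$outcome[sel]
    n <- sum(sel)
    if (n == 0L || length(unique(y)) < 2L) {
      return(data.frame(biomarker = marker, window = wname, n = n,
                        min_sensitivity = floor_, cutoff = NA_real_,
                        sensitivity = NA_real_, specificity = NA_real_,
                        avoided = NA, avoided_pct = NA, unnecessary = NA,
                        unnecessary_pct = NA, missed = NA, missed_pct = NA,
                        nns = NA_real_, infeasible = NA,
                        small_sample = n < 10L))
    }
    cc <- choose_cutoff(x, y, floor_, strict = strict)
    pos <- if (strict) x > cc$cutoff else x >= cc$cutoff
    tm <- triage_metrics(tp = sum(pos & y == 1), fp = sum(pos & y == 0),
                         tn = sum(!pos & y == 0), fn = sum(!pos & y == 1))
    data.frame(
      biomarker = marker, window = wname, n = n, min_sensitivity = floor_,
      cutoff = cc$cutoff, sensitivity = tm$sensitivity,
      specificity = tm$specificity,
      avoided = tm$avoided_mris, avoided_pct = tm$avoided_pct,
      unnecessary = tm$unnecessary_mris, unnecessary_pct = tm$unnecessary_pct,
      missed = tm$missed, missed_pct = tm$missed_pct,
      nns = tm$number_needed_to_scan, infeasible = cc$infeasible,
      small_sample = n < 10L, stringsAsFactors = FALSE
    )
  }
  grid <- expand.grid(marker = markers, window = names(windows),
                      stringsAsFactors = FALSE)
  tab <- do.call(rbind, Map(one_row, grid$marker, grid$window,
                            MoreArgs = list(floor_ = min_sensitivity)))
  rownames(tab) <- NULL
  out <- list(table = tab)
  if (!is.null(sweep)) {
    sg <- expand.grid(marker = markers, window = names(windows),
                      floor_ = sweep, stringsAsFactors = FALSE)
    st <- do.call(rbind, Map(one_row, sg$marker, sg$window, sg$floor_))
    rownames(st) <- NULL
    out$sweep_table <- st
  }
  out
}
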