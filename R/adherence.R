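# Wear-day classification, the patient-inclusion rule, and cohort
# completeness accounting.

#' Classify a study day by data completeness
#'
#' A day with more than 100 recorded steps is a FULL day of data
#' collection, a recorded day with at most 100 steps (including 0) is
#' PARTIAL, and a day with no recording is NONE. The threshold is strict:
#' exactly 100 steps is PARTIAL.
#'
#' @param steps Integer vector of daily step counts; `NA` marks a day with
#'   no recording.
#' @return Factor with levels `FULL`, `PARTIAL`, `NONE`.
#' @export
#' @examples
#' classify_day(c(101, 100, 0, NA))
classify_day <- function(steps) {
  if (any(!is.na(steps) & steps < 0))
    st_stop("steps must be non-negative", class = "steptrack_validation_error")
  out <- ifelse(is.na(steps), "NONE", ifelse(steps > 100, "FULL", "PARTIAL"))
  factor(out, levels = c("FULL", "PARTIAL", "NONE"))
}

# FULL-day count of a series within a phase
full_day_count <- function(series, phase) {
  s <- phase_slice(series, phase)
  sum(classify_day(s$steps) == "FULL")
}

#' Patient-level adequacy rule
#'
#' A patient's data are adequate when the series has at least three FULL
#' days (>100 steps) in the 7-day prechemotherapy window *and* at least
#' three FULL days in the 14-day postchemotherapy window.
#'
#' @param series A [step_series()].
#' @return `TRUE`/`FALSE`.
#' @export
is_adequate <- function(series) {
  full_day_count(series, "pre") >= 3 && full_day_count(series, "post") >= 3
}

#' Apply the adequacy rule to a cohort
#'
#' @param x A `steptrack_cohort`.
#' @return List with `cohort` (the included patients; MSAS tables subset
#'   accordingly) and `exclusions`, a data frame with one row per excluded
#'   patient and logical columns `failed_pre`, `failed_post`. Filtering is
#'   idempotent.
#' @export
filter_cohort <- function(x) {
  stopifnot(inherits(x, "steptrack_cohort"))
  ids <- x$patients$patient_id
  pre_full <- vapply(ids, function(id) {
    s <- x$steps[[id]]
    if (is.null(s)) 0L else full_day_count(s, "pre")
  }, integer(1))
  post_full <- vapply(ids, function(id) {
    s <- x$steps[[id]]
    if (is.null(s)) 0L else full_day_count(s, "post")
  }, integer(1))
  ok <- pre_full >= 3 & post_full >= 3
  excl <- data.frame(patient_id = ids[!ok],
                     failed_pre = pre_full[!ok] < 3,
                     failed_post = post_full[!ok] < 3,
                     stringsAsFactors = FALSE)
  rownames(excl) <- NULL
  keep <- ids[ok]
  sub <- function(tab) {
    if (is.null(tab)) NULL else tab[tab$patient_id %in% keep, , drop = FALSE]
  }
  inc <- cohort(x$steps[keep],
                patients = x$patients[ok, , drop = FALSE],
                msas_pre = sub(x$msas_pre), msas_post = sub(x$msas_post))
  list(cohort = inc, exclusions = excl)
}

#' Cohort completeness report for one phase
#'
#' Counts FULL / PARTIAL / NONE days over *all* patients supplied
#' (pre-filtering), with denominator `n_patients x 7` (pre) or
#' `n_patients x 14` (post). Integer percentages are allocated by the
#' largest-remainder method so they sum to 100 (ties favour the
#' less-complete category); `mean_full_days_per_patient` is rounded
#' half-up to the nearest day. Raw (unrounded) values are reported
#' alongside.
#'
#' @param x A `steptrack_cohort`.
#' @param phase `"pre"` or `"post"`.
#' @return A `completeness_report` list; see fields in the description.
#' @export
completeness_report <- function(x, phase = c("pre", "post")) {
  stopifnot(inherits(x, "steptrack_cohort"))
  phase <- match.arg(phase)
  if (n_patients(x) == 0)
    st_stop("completeness report requires a non-empty cohort",
            class = "steptrack_validation_error")
  days <- phase_days(phase)
  ids <- x$patients$patient_id
  per_patient <- t(vapply(ids, function(id) {
    s <- x$steps[[id]]
    cl <- classify_day(if (is.null(s)) rep(NA_integer_, length(days))
                       else steps_on_day(s, days))
    c(FULL = sum(cl == "FULL"), PARTIAL = sum(cl == "PARTIAL"),
      NONE = sum(cl == "NONE"))
  }, c(FULL = 0L, PARTIAL = 0L, NONE = 0L)))
  counts <- colSums(per_patient)
  total <- length(days) * length(ids)
  stopifnot(sum(counts) == total)
  pct <- pct_integer(counts)
  structure(list(
    phase = phase,
    n_patients = length(ids),
    n_days_total = total,
    n_full = unname(counts["FULL"]),
    n_partial = unname(counts["PARTIAL"]),
    n_none = unname(counts["NONE"]),
    pct_full = unname(pct["FULL"]),
    pct_partial = unname(pct["PARTIAL"]),
    pct_none = unname(pct["NONE"]),
    pct_full_raw = unname(100 * counts["FULL"] / total),
    pct_partial_raw = unname(100 * counts["PARTIAL"] / total),
    pct_none_raw = unname(100 * counts["NONE"] / total),
    mean_full_days_per_patient =
      round_half_up(unname(counts["FULL"]) / length(ids)),
    mean_full_days_raw = unname(counts["FULL"]) / length(ids),
    full_days_per_patient = stats::setNames(per_patient[, "FULL"], ids)
  ), class = "completeness_report")
}

#' @export
print.completeness_report <- function(x, ...) {
  cat(sprintf(
    "<completeness_report> %schemotherapy: %d patients, %d days\n",
    x$phase, x$n_patients, x$n_days_total))
  cat(sprintf("  FULL    %4d (%d%%)\n  PARTIAL %4d (%d%%)\n  NONE    %4d (%d%%)\n",
              x$n_full, x$pct_full, x$n_partial, x$pct_partial,
              x$n_none, x$pct_none))
  cat("  mean FULL days/patient:", x$mean_full_days_per_patient, "\n")
  invisible(x)
}
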