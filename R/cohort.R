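# Core data containers and tabular I/O.
#
# Study-day convention: day 0 is the C1D1 clinic/treatment day and belongs
# to neither phase; valid study days are -7..14. A day absent from a
# series is "no recording" and is distinct from a recorded 0-step day.

CHEMO_TYPES <- c("adjuvant", "neoadjuvant", "metastatic")

#' One patient's daily step-count series
#'
#' Stores the recorded days only: a study day not present in the series is
#' an explicit "no recording" state, which downstream classification keeps
#' distinct from a recorded count of 0 steps.
#'
#' @param patient_id Single non-empty string.
#' @param days Integer study days in \[-7, 14\], no duplicates.
#' @param steps Non-negative integer counts, same length as `days`. `NA`
#'   entries are dropped (an `NA` count is "no recording").
#' @return A `step_series` object: a data frame with columns `day`, `steps`
#'   sorted by day, with a `patient_id` attribute.
#' @export
#' @examples
#' s <- step_series("P1", c(-1, 1, 2), c(5200, 0, 4100))
#' steps_on_day(s, 1)   # 0 (recorded)
#' steps_on_day(s, 3)   # NA (no recording)
step_series <- function(patient_id, days = integer(), steps = integer()) {
  if (!is.character(patient_id) || length(patient_id) != 1 || !nzchar(patient_id))
    st_stop("patient_id must be a single non-empty string")
  if (length(days) != length(steps))
    st_stop("days and steps must have equal length")
  keep <- !is.na(steps)
  days <- as.integer(days[keep])
  steps <- steps[keep]
  rng <- study_day_range()
  if (any(is.na(days)) || any(days < rng[1] | days > rng[2]))
    st_stop("study days must lie in [", rng[1], ", ", rng[2], "]",
            class = "steptrack_validation_error")
  if (anyDuplicated(days))
    st_stop("duplicate study day for patient ", patient_id,
            class = "steptrack_duplicate_error")
  if (!is_count(steps))
    st_stop("steps must be non-negative integers",
            class = "steptrack_validation_error")
  ord <- order(days)
  out <- data.frame(day = days[ord], steps = as.integer(steps[ord]))
  attr(out, "patient_id") <- patient_id
  class(out) <- c("step_series", "data.frame")
  out
}

#' @export
print.step_series <- function(x, ...) {
  cat("<step_series> patient", attr(x, "patient_id"),
      "-", nrow(x), "recorded day(s)\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Step count recorded on a study day
#'
#' @param series A [step_series()].
#' @param day Integer study day(s).
#' @return Integer steps, `NA` where the day has no recording.
#' @export
steps_on_day <- function(series, day) {
  series$steps[match(as.integer(day), series$day)]
}

#' Restrict a step series to one phase
#'
#' @inheritParams steps_on_day
#' @param phase `"pre"` or `"post"`.
#' @return A `step_series` containing only the phase's recorded days.
#' @export
phase_slice <- function(series, phase) {
  keep <- series$day %in% phase_days(phase)
  step_series(attr(series, "patient_id"), series$day[keep], series$steps[keep])
}

#' Assemble a cohort
#'
#' A cohort bundles patient metadata, one step series per patient, and the
#' optional MSAS-SF response tables for the baseline (pre) and C2D1 (post)
#' visits. Every series and questionnaire row must map to a known patient;
#' when `patients` is omitted a minimal metadata table is derived from the
#' step series (all clinical fields `NA`).
#'
#' @param steps List of [step_series()] objects.
#' @param patients Data frame with columns `patient_id`, `ecog`, `age`,
#'   `sex`, `chemo_type` (see [read_patient_meta()]), or `NULL`.
#' @param msas_pre,msas_post Optional MSAS-SF response data frames
#'   (`patient_id` plus the 32 canonical item columns).
#' @return A `steptrack_cohort` object.
#' @export
cohort <- function(steps, patients = NULL, msas_pre = NULL, msas_post = NULL) {
  ids <- vapply(steps, function(s) attr(s, "patient_id"), character(1))
  if (anyDuplicated(ids))
    st_stop("duplicate patient_id among step series",
            class = "steptrack_duplicate_error")
  names(steps) <- ids
  if (is.null(patients)) {
    patients <- data.frame(patient_id = ids,
                           ecog = rep(NA_integer_, length(ids)),
                           age = rep(NA_real_, length(ids)),
                           sex = rep(NA_character_, length(ids)),
                           chemo_type = rep(NA_character_, length(ids)),
                           stringsAsFactors = FALSE)
  } else {
    patients <- validate_patient_meta(patients)
    unknown <- setdiff(ids, patients$patient_id)
    if (length(unknown))
      st_stop("step series for unknown patient(s): ",
              paste(unknown, collapse = ", "),
              class = "steptrack_validation_error")
  }
  for (tab in list(msas_pre, msas_post)) {
    if (!is.null(tab)) {
      unknown <- setdiff(tab$patient_id, patients$patient_id)
      if (length(unknown))
        st_stop("MSAS responses for unknown patient(s): ",
                paste(unknown, collapse = ", "),
                class = "steptrack_validation_error")
    }
  }
  structure(list(patients = patients, steps = steps,
                 msas_pre = msas_pre, msas_post = msas_post),
            class = "steptrack_cohort")
}

#' @export
print.steptrack_cohort <- function(x, ...) {
  cat("<steptrack_cohort>", nrow(x$patients), "patient(s),",
      length(x$steps), "step series,",
      if (is.null(x$msas_pre)) "no" else nrow(x$msas_pre), "pre-visit and",
      if (is.null(x$msas_post)) "no" else nrow(x$msas_post),
      "post-visit MSAS responses\n")
  invisible(x)
}

#' Number of patients in a cohort
#' @param x A `steptrack_cohort`.
#' @return Integer count.
#' @export
n_patients <- function(x) nrow(x$patients)

validate_patient_meta <- function(df) {
  need <- c("patient_id", "ecog", "age", "sex", "chemo_type")
  miss <- setdiff(need, names(df))
  if (length(miss))
    st_stop("patient metadata missing column(s): ", paste(miss, collapse = ", "),
            class = "steptrack_parse_error")
  df <- df[need]
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id))
    st_stop("duplicate patient_id in metadata",
            class = "steptrack_duplicate_error")
  ecog <- df$ecog
  if (!all(is.na(ecog) | (ecog %in% 0:5)))
    st_stop("ecog must be an integer in 0..5",
            class = "steptrack_validation_error")
  df$ecog <- as.integer(ecog)
  if (!all(is.na(df$age) | df$age > 0))
    st_stop("age must be positive", class = "steptrack_validation_error")
  bad <- !is.na(df$chemo_type) & !(df$chemo_type %in% CHEMO_TYPES)
  if (any(bad))
    st_stop("unknown chemo_type: ", paste(unique(df$chemo_type[bad]), collapse = ", "),
            class = "steptrack_validation_error")
  df$sex <- as.character(df$sex)
  rownames(df) <- NULL
  df
}

# ---- readers ---------------------------------------------------------------

read_table_checked <- function(path, need) {
  if (!file.exists(path))
    st_stop("file not found: ", path, class = "steptrack_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  miss <- setdiff(need, names(df))
  if (length(miss))
    st_stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
            class = "steptrack_parse_error")
  df
}

#' Read a long-format step log
#'
#' Expects a CSV with header `patient_id,study_day,steps`. A row whose
#' `steps` field is blank marks a day with no recording and is equivalent
#' to the row being absent entirely; a recorded `0` stays a present record.
#'
#' @param path CSV file path.
#' @return Named list of [step_series()], one per patient (insertion order
#'   of first appearance). An empty file yields an empty list.
#' @export
read_step_log <- function(path) {
  df <- read_table_checked(path, c("patient_id", "study_day", "steps"))
  if (nrow(df) == 0) return(structure(list(), names = character()))
  line <- seq_len(nrow(df)) + 1L   # header is line 1
  day <- parse_int(df$study_day)
  bad <- which(is.na(day) | is.nan(day))
  if (length(bad))
    st_stop(path, ": line ", line[bad[1]], ": malformed study_day '",
            df$study_day[bad[1]], "'", class = "steptrack_parse_error")
  rng <- study_day_range()
  oob <- which(day < rng[1] | day > rng[2])
  if (length(oob))
    st_stop(path, ": line ", line[oob[1]], ": study_day ", day[oob[1]],
            " outside [", rng[1], ", ", rng[2], "]",
            class = "steptrack_validation_error")
  steps <- parse_int(df$steps)
  bad <- which(is.nan(steps) | (!is.na(steps) & steps < 0))
  if (length(bad))
    st_stop(path, ": line ", line[bad[1]], ": malformed steps '",
            df$steps[bad[1]], "'", class = "steptrack_parse_error")
  key <- paste(df$patient_id, day)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    st_stop(path, ": duplicate record for (patient_id, study_day) = (",
            gsub(" ", ", ", d), ")", class = "steptrack_duplicate_error")
  }
  ids <- unique(df$patient_id)
  out <- lapply(ids, function(id) {
    i <- df$patient_id == id
    step_series(id, day[i], steps[i])
  })
  names(out) <- ids
  out
}

#' Read patient metadata
#'
#' Expects a CSV with header `patient_id,ecog,age,sex,chemo_type`. ECOG
#' performance status must be an integer 0..5 and `chemo_type` one of
#' `adjuvant`, `neoadjuvant`, `metastatic`.
#'
#' @param path CSV file path.
#' @return Validated data frame of patient metadata.
#' @export
read_patient_meta <- function(path) {
  df <- read_table_checked(path, c("patient_id", "ecog", "age", "sex", "chemo_type"))
  if (nrow(df) == 0)
    return(validate_patient_meta(
      data.frame(patient_id = character(), ecog = integer(), age = numeric(),
                 sex = character(), chemo_type = character())))
  ecog <- parse_int(df$ecog)
  if (any(is.nan(ecog)))
    st_stop(path, ": malformed ecog value", class = "steptrack_parse_error")
  age <- suppressWarnings(as.numeric(df$age))
  validate_patient_meta(data.frame(patient_id = df$patient_id,
                                   ecog = ecog, age = age, sex = df$sex,
                                   chemo_type = df$chemo_type,
                                   stringsAsFactors = FALSE))
}

#' Read a full cohort from a directory
#'
#' Reads `steps.csv` and `patients.csv` (required) plus `msas_pre.csv` and
#' `msas_post.csv` when present — the same layout [write_cohort()] emits.
#'
#' @param dir Directory path.
#' @return A `steptrack_cohort`.
#' @export
read_cohort <- function(dir) {
  steps <- read_step_log(file.path(dir, "steps.csv"))
  patients <- read_patient_meta(file.path(dir, "patients.csv"))
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) read_msas(p) else NULL
  }
  cohort(steps, patients, msas_pre = rd("msas_pre.csv"),
         msas_post = rd("msas_post.csv"))
}

#' Write a cohort to a directory
#'
#' Emits `steps.csv`, `patients.csv` and, when present, `msas_pre.csv` /
#' `msas_post.csv` in the dialect the readers consume (comma-separated,
#' header row, UTF-8, missing values as empty fields). Only recorded days
#' are written, so an absent day round-trips as absent and a 0-step day as
#' a present record: `read_cohort(write_cohort(x))` reproduces `x`.
#'
#' @param x A `steptrack_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "steptrack_cohort"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) st_stop("cannot create directory ", dir, class = "steptrack_io_error")
  steps <- do.call(rbind, c(lapply(x$steps, function(s) {
    data.frame(patient_id = attr(s, "patient_id"), study_day = s$day,
               steps = s$steps, stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
  if (is.null(steps))
    steps <- data.frame(patient_id = character(), study_day = integer(),
                        steps = integer())
  wr <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                         row.names = FALSE, na = "")
  wr(steps, "steps.csv")
  wr(x$patients, "patients.csv")
  if (!is.null(x$msas_pre)) wr(x$msas_pre, "msas_pre.csv")
  if (!is.null(x$msas_post)) wr(x$msas_post, "msas_post.csv")
  invisible(dir)
}
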