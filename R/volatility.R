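# Day-over-day step-count volatility and annualized summaries.
#
# sigma(t) = (S(t) - S(t-1)) / S(t-1), the relative change versus the
# previous day, computed only across strictly consecutive recorded days
# with S(t-1) > 0: gaps are never bridged and zero-previous-day pairs are
# skipped (logged), not treated as infinite. Positive sigma(t) means an
# increase over the previous day. Log-returns log(S(t)/S(t-1)) are
# available as an alternative functional form.

DAYS_PER_YEAR <- 365

#' Daily step-count volatility within a phase
#'
#' @param series A [step_series()].
#' @param phase `"pre"` or `"post"`.
#' @param method `"relative"` (default) for `(S(t)-S(t-1))/S(t-1)` or
#'   `"log"` for `log(S(t)/S(t-1))` (zero on either day skips the pair).
#' @return A `volatility_series` data frame with columns `day`, `sigma`,
#'   plus attributes `patient_id`, `phase`, `n_usable_pairs`,
#'   `n_skipped_gap` (pairs lost to a missing neighbour) and
#'   `n_skipped_zero` (pairs lost to a zero denominator).
#' @export
#' @examples
#' s <- step_series("P1", 1:4, c(2000, 1000, 1500, 1500))
#' daily_volatility(s, "post")$sigma  # -0.5, 0.5, 0
daily_volatility <- function(series, phase = c("pre", "post"),
                             method = c("relative", "log")) {
  phase <- match.arg(phase)
  method <- match.arg(method)
  days <- phase_days(phase)
  s <- steps_on_day(series, days)
  prev <- s[-length(s)]
  cur <- s[-1]
  consec <- !is.na(prev) & !is.na(cur)
  usable <- consec & prev > 0 & (method == "relative" | cur > 0)
  sigma <- if (method == "relative") (cur - prev) / prev else log(cur / prev)
  out <- data.frame(day = days[-1][usable], sigma = sigma[usable])
  attr(out, "patient_id") <- attr(series, "patient_id")
  attr(out, "phase") <- phase
  attr(out, "n_usable_pairs") <- sum(usable)
  attr(out, "n_skipped_gap") <- sum(!consec)
  attr(out, "n_skipped_zero") <- sum(consec & !usable)
  class(out) <- c("volatility_series", "data.frame")
  out
}

#' Annualized volatility and variance of a patient's step counts
#'
#' The per-day volatilities sigma(t) of the phase are summarised by their
#' sample standard deviation (divisor n-1) and scaled to a yearly time
#' base with the square-root-of-time rule, sqrt(365) (calendar days, not
#' the trading-day convention): `annualized_vol = sd(sigma) * sqrt(365)`,
#' `annualized_var = annualized_vol^2`.
#'
#' @inheritParams daily_volatility
#' @return One-row data frame: `patient_id`, `phase`, `sigma_daily_sd`,
#'   `annualized_vol`, `annualized_var`, `n` (usable pairs). With fewer
#'   than 2 usable pairs the numeric fields are `NA` and the `reason`
#'   column says why.
#' @export
annualized_volatility <- function(series, phase = c("pre", "post"),
                                  method = c("relative", "log")) {
  phase <- match.arg(phase)
  vs <- daily_volatility(series, phase, method)
  n <- nrow(vs)
  if (n < 2) {
    return(data.frame(patient_id = attr(vs, "patient_id"), phase = phase,
                      sigma_daily_sd = NA_real_, annualized_vol = NA_real_,
                      annualized_var = NA_real_, n = n,
                      reason = "insufficient data",
                      stringsAsFactors = FALSE))
  }
  sdv <- stats::sd(vs$sigma)
  data.frame(patient_id = attr(vs, "patient_id"), phase = phase,
             sigma_daily_sd = sdv,
             annualized_vol = sdv * sqrt(DAYS_PER_YEAR),
             annualized_var = sdv^2 * DAYS_PER_YEAR,
             n = n, reason = NA_character_, stringsAsFactors = FALSE)
}

#' Cohort counts of up, down and flat days
#'
#' Pools every usable consecutive-day pair over all patients in the phase
#' and counts days where the step count rose (`sigma > 0`), fell
#' (`sigma < 0`) or was unchanged.
#'
#' @param x A `steptrack_cohort` (normally after [filter_cohort()]).
#' @inheritParams daily_volatility
#' @return Named integer vector `c(n_up, n_down, n_flat)`; the three
#'   always sum to the total number of usable pairs.
#' @export
direction_day_counts <- function(x, phase = c("pre", "post")) {
  stopifnot(inherits(x, "steptrack_cohort"))
  phase <- match.arg(phase)
  sig <- unlist(lapply(x$steps, function(s) daily_volatility(s, phase)$sigma),
                use.names = FALSE)
  c(n_up = sum(sig > 0), n_down = sum(sig < 0), n_flat = sum(sig == 0))
}

#' Pre/post change in annualized variance, by patient and ECOG group
#'
#' @param x A `steptrack_cohort`.
#' @param method Passed to [annualized_volatility()].
#' @return List with `per_patient` (columns `patient_id`, `ecog`,
#'   `pre_var`, `post_var`, `increased` — strict increase), `by_ecog`
#'   (per-ECOG `n`, `n_increased`, `pct_increased`), and `excluded`
#'   (patients lacking a computable phase, with the failing phase noted).
#' @export
annualized_change_summary <- function(x, method = c("relative", "log")) {
  stopifnot(inherits(x, "steptrack_cohort"))
  method <- match.arg(method)
  ids <- x$patients$patient_id
  rows <- lapply(ids, function(id) {
    s <- x$steps[[id]]
    pre <- annualized_volatility(s, "pre", method)
    post <- annualized_volatility(s, "post", method)
    data.frame(patient_id = id,
               ecog = x$patients$ecog[x$patients$patient_id == id],
               pre_var = pre$annualized_var, post_var = post$annualized_var,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$pre_var) & !is.na(tab$post_var)
  excluded <- data.frame(
    patient_id = tab$patient_id[!ok],
    missing_phase = ifelse(is.na(tab$pre_var[!ok]),
                           ifelse(is.na(tab$post_var[!ok]), "both", "pre"),
                           "post"),
    stringsAsFactors = FALSE)
  tab <- tab[ok, , drop = FALSE]
  tab$increased <- tab$post_var > tab$pre_var
  lv <- sort(unique(tab$ecog[!is.na(tab$ecog)]))
  by_ecog <- data.frame(
    ecog = lv,
    n = vapply(lv, function(e) sum(tab$ecog == e, na.rm = TRUE), integer(1)),
    n_increased = vapply(lv, function(e)
      sum(tab$increased[!is.na(tab$ecog) & tab$ecog == e]), integer(1)))
  by_ecog$pct_increased <- round_half_up(
    100 * by_ecog$n_increased / pmax(by_ecog$n, 1))
  rownames(tab) <- NULL
  list(per_patient = tab, by_ecog = by_ecog, excluded = excluded)
}
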