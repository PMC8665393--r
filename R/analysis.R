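# Cohort-level analyses: phase summaries, pre/post correlation matrices,
# per-day correlation profiles, and group comparisons (ECOG, MSAS
# improvement, age).
#
# Phase summaries use FULL days (>100 steps) only: days with <=100
# recorded steps are treated as non-wear, not near-zero activity.

SUMMARY_STATS <- c("mean", "median", "max", "min")

full_day_steps <- function(series, phase) {
  s <- phase_slice(series, phase)
  s$steps[s$steps > 100]
}

#' Order statistics of a patient's FULL-day step counts in a phase
#'
#' @param series A [step_series()].
#' @param phase `"pre"` or `"post"`.
#' @return One-row data frame `patient_id`, `phase`, `mean`, `median`,
#'   `max`, `min`, `n_days_used`; all statistics `NA` with a `reason`
#'   when the phase has no FULL day.
#' @export
phase_summary <- function(series, phase = c("pre", "post")) {
  phase <- match.arg(phase)
  v <- full_day_steps(series, phase)
  id <- attr(series, "patient_id")
  if (length(v) == 0) {
    return(data.frame(patient_id = id, phase = phase, mean = NA_real_,
                      median = NA_real_, max = NA_real_, min = NA_real_,
                      n_days_used = 0L, reason = "no FULL days",
                      stringsAsFactors = FALSE))
  }
  data.frame(patient_id = id, phase = phase, mean = mean(v),
             median = stats::median(v), max = as.numeric(max(v)),
             min = as.numeric(min(v)), n_days_used = length(v),
             reason = NA_character_, stringsAsFactors = FALSE)
}

#' Phase summaries for every patient in a cohort
#'
#' @param x A `steptrack_cohort`.
#' @inheritParams phase_summary
#' @return Data frame, one row per patient (see [phase_summary()]).
#' @export
phase_summaries <- function(x, phase = c("pre", "post")) {
  stopifnot(inherits(x, "steptrack_cohort"))
  phase <- match.arg(phase)
  out <- do.call(rbind, lapply(x$patients$patient_id, function(id) {
    s <- x$steps[[id]]
    if (is.null(s)) s <- step_series(id)
    phase_summary(s, phase)
  }))
  rownames(out) <- NULL
  out
}

cor_result <- function(est, p, n, method, reason = NA_character_) {
  data.frame(method = method, estimate = est, p_value = p, n = n,
             reason = reason, stringsAsFactors = FALSE)
}

safe_cor <- function(x, y, method = "pearson") {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3)
    return(cor_result(NA_real_, NA_real_, n, method, "n<3"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(cor_result(NA_real_, NA_real_, n, method, "zero variance"))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, alternative = "two.sided",
                    exact = FALSE))
  cor_result(unname(ct$estimate), ct$p.value, n, method)
}

#' Pre/post correlation matrix of the four phase summary statistics
#'
#' Entry (i, j) is the across-patient correlation between postchemotherapy
#' statistic i and prechemotherapy statistic j, for i, j in
#' mean/median/max/min of FULL-day steps. Patients lacking either phase
#' summary are dropped pairwise.
#'
#' @param x A `steptrack_cohort`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A `prepost_correlation` object: list of `estimate`, `p_value`
#'   and `n` 4x4 matrices (rows = post statistics, cols = pre statistics).
#' @export
prepost_summary_correlation <- function(x, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  pre <- phase_summaries(x, "pre")
  post <- phase_summaries(x, "post")
  both <- !is.na(pre$mean) & !is.na(post$mean)
  if (sum(both) < 3)
    st_stop("insufficient patients with both phase summaries (need >= 3)",
            class = "steptrack_validation_error")
  est <- p <- n <- matrix(NA_real_, 4, 4,
                          dimnames = list(post = SUMMARY_STATS,
                                          pre = SUMMARY_STATS))
  for (i in SUMMARY_STATS) for (j in SUMMARY_STATS) {
    r <- safe_cor(post[[i]], pre[[j]], method)
    est[i, j] <- r$estimate; p[i, j] <- r$p_value; n[i, j] <- r$n
  }
  structure(list(estimate = est, p_value = p, n = n, method = method),
            class = "prepost_correlation")
}

#' @export
print.prepost_correlation <- function(x, ...) {
  cat("<prepost_correlation> post (rows) vs pre (cols),", x$method, "\n")
  print(round(x$estimate, 3))
  invisible(x)
}

#' Per-day correlation profile (day count vs opposite-phase summary)
#'
#' For each study day d of `phase`, correlates the day-d FULL-day step
#' count across patients with each patient's chosen summary statistic from
#' the *opposite* phase. This is one plausible reading of a per-day
#' "activity level" correlation table and is marked as such in the output.
#'
#' @param x A `steptrack_cohort`.
#' @param phase Phase whose individual days are profiled.
#' @param statistic One of `"mean"`, `"median"`, `"max"`, `"min"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Data frame: `day`, `estimate`, `p_value`, `n`, `reason`
#'   (non-`NA` where the correlation is undefined), with attribute
#'   `interpretation`.
#' @export
daywise_correlation <- function(x, phase = c("pre", "post"),
                                statistic = SUMMARY_STATS,
                                method = c("pearson", "spearman")) {
  phase <- match.arg(phase)
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  other <- if (phase == "pre") "post" else "pre"
  summ <- phase_summaries(x, other)
  ids <- x$patients$patient_id
  rows <- lapply(phase_days(phase), function(d) {
    steps_d <- vapply(ids, function(id) {
      s <- x$steps[[id]]
      v <- if (is.null(s)) NA_integer_ else steps_on_day(s, d)
      if (!is.na(v) && v <= 100) v <- NA_integer_   # FULL days only
      as.numeric(v)
    }, numeric(1))
    r <- safe_cor(steps_d, summ[[statistic]][match(ids, summ$patient_id)],
                  method)
    cbind(day = d, r)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "interpretation") <-
    paste0("day-", phase, " FULL-day count vs patient ", other, "-phase ",
           statistic)
  out
}

rank_biserial <- function(u, n1, n2) 1 - 2 * u / (n1 * n2)

two_group_test <- function(values, group) {
  lv <- unique(group)
  a <- values[group == lv[1]]
  b <- values[group == lv[2]]
  exact <- length(a) <= 20 && length(b) <= 20
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  list(test = "Mann-Whitney U", statistic = unname(wt$statistic),
       p_value = wt$p.value,
       rank_biserial = rank_biserial(unname(wt$statistic),
                                     length(a), length(b)))
}

#' Step counts by ECOG performance-status group
#'
#' Summarises per-patient phase-mean FULL-day steps by baseline ECOG
#' group; with exactly two groups runs a two-sided Mann-Whitney U test
#' (exact for group sizes <= 20) and always reports the Spearman
#' correlation of ECOG with phase-mean steps. ECOG levels are data-driven,
#' never hard-coded.
#'
#' @param x A `steptrack_cohort`.
#' @param phase `"pre"` or `"post"`.
#' @return List: `groups` (per-ECOG `n`, `mean_steps`, `median_steps`),
#'   `test` (two-group comparison, or `NULL` with `test_reason`),
#'   `spearman` (correlation row, `NA` with reason if a single group).
#' @export
steps_vs_ecog <- function(x, phase = c("pre", "post")) {
  stopifnot(inherits(x, "steptrack_cohort"))
  phase <- match.arg(phase)
  summ <- phase_summaries(x, phase)
  ecog <- x$patients$ecog[match(summ$patient_id, x$patients$patient_id)]
  ok <- !is.na(summ$mean) & !is.na(ecog)
  v <- summ$mean[ok]; g <- ecog[ok]
  groups <- do.call(rbind, lapply(sort(unique(g)), function(e) {
    data.frame(ecog = e, n = sum(g == e), mean_steps = mean(v[g == e]),
               median_steps = stats::median(v[g == e]))
  }))
  test <- NULL; test_reason <- NA_character_
  if (is.null(groups) || nrow(groups) < 2) {
    test_reason <- "fewer than two ECOG groups"
    sp <- cor_result(NA_real_, NA_real_, length(v), "spearman",
                     "fewer than two ECOG groups")
  } else {
    if (nrow(groups) == 2) test <- two_group_test(v, g)
    else test_reason <- "more than two ECOG groups; pairwise test skipped"
    sp <- safe_cor(as.numeric(g), v, "spearman")
  }
  list(phase = phase, groups = groups, test = test,
       test_reason = test_reason, spearman = sp)
}

#' Step counts split by MSAS-SF improvement
#'
#' Partitions patients by whether the chosen subscale improved from the
#' baseline to the C2D1 visit ([msas_improvement()], strict decrease) and
#' reports each group's cross-patient mean of per-patient phase-mean
#' FULL-day steps, for both phases.
#'
#' @param x A `steptrack_cohort` with `msas_pre` and `msas_post` tables.
#' @param subscale One of `"gdi"`, `"phys"`, `"psych"`, `"tmsas"`.
#' @return Data frame with up to two rows (`improved` TRUE/FALSE): `n`,
#'   `mean_steps_pre`, `mean_steps_post`. Empty partitions are absent.
#' @export
improvement_step_comparison <- function(x, subscale = c("gdi", "phys",
                                                        "psych", "tmsas")) {
  stopifnot(inherits(x, "steptrack_cohort"))
  subscale <- match.arg(subscale)
  if (is.null(x$msas_pre) || is.null(x$msas_post))
    st_stop("cohort lacks MSAS responses at both visits",
            class = "steptrack_validation_error")
  imp <- msas_improvement(score_msas(x$msas_pre), score_msas(x$msas_post),
                          subscales = subscale)
  pre <- phase_summaries(x, "pre")
  post <- phase_summaries(x, "post")
  imp$steps_pre <- pre$mean[match(imp$patient_id, pre$patient_id)]
  imp$steps_post <- post$mean[match(imp$patient_id, post$patient_id)]
  imp <- imp[!is.na(imp$improved), , drop = FALSE]
  out <- do.call(rbind, lapply(c(TRUE, FALSE), function(flag) {
    sub <- imp[imp$improved == flag, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    data.frame(subscale = subscale, improved = flag, n = nrow(sub),
               mean_steps_pre = mean(sub$steps_pre, na.rm = TRUE),
               mean_steps_post = mean(sub$steps_post, na.rm = TRUE))
  }))
  rownames(out) <- NULL
  out
}

#' Step counts split by age
#'
#' Compares per-patient phase-median FULL-day steps between patients
#' younger than `threshold` years and those at or above it, reporting the
#' group medians and a two-sided Mann-Whitney p-value.
#'
#' @param x A `steptrack_cohort`.
#' @param phase `"pre"` or `"post"`.
#' @param threshold Age cut in years (default 60; `< threshold` vs
#'   `>= threshold`).
#' @return List: `groups` data frame (`age_group`, `n`, `median_steps`),
#'   `test` (or `NULL`), `reason` when the comparison is undefined.
#' @export
age_split_comparison <- function(x, phase = c("pre", "post"), threshold = 60) {
  stopifnot(inherits(x, "steptrack_cohort"))
  phase <- match.arg(phase)
  summ <- phase_summaries(x, phase)
  age <- x$patients$age[match(summ$patient_id, x$patients$patient_id)]
  ok <- !is.na(summ$median) & !is.na(age)
  v <- summ$median[ok]
  young <- age[ok] < threshold
  lab <- ifelse(young, paste0("<", threshold), paste0(">=", threshold))
  groups <- do.call(rbind, lapply(unique(lab[order(!young)]), function(gl) {
    data.frame(age_group = gl, n = sum(lab == gl),
               median_steps = stats::median(v[lab == gl]))
  }))
  if (is.null(groups) || nrow(groups) < 2)
    return(list(phase = phase, groups = groups, test = NULL,
                reason = "a single age group"))
  list(phase = phase, groups = groups, test = two_group_test(v, lab),
       reason = NA_character_)
}
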