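# End-to-end pipeline orchestration and chart rendering.

log_stage <- function(verbose, stage, ...) {
  if (verbose) message("[", stage, "] ", ...)
}

#' Run the full analysis pipeline
#'
#' Executes read -> adequacy filter -> completeness -> MSAS scoring ->
#' phase summaries -> volatility -> correlation/group analyses, writing a
#' single machine-readable `results.json`, CSV tables for the summary
#' correlation matrices and group comparisons, and (optionally) the
#' volatility and annualized-variance charts. Any stage failure aborts
#' with the stage name and removes partial outputs. Runs on identical
#' inputs are byte-identical in `results.json`.
#'
#' @param config List with elements `steps` (path to steps.csv, required),
#'   `patients` (path, optional), `msas_pre` / `msas_post` (paths,
#'   optional), `out_dir` (required), `figures` (logical, default TRUE),
#'   `sigma_method` (`"relative"`/`"log"`), `age_threshold` (default 60),
#'   `verbose` (default FALSE).
#' @return Invisibly, the results list written to `results.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$steps), !is.null(config$out_dir))
  figures <- isTRUE(config$figures %||% TRUE)
  method <- config$sigma_method %||% "relative"
  thr <- config$age_threshold %||% 60
  verbose <- isTRUE(config$verbose)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(f) { written[[length(written) + 1]] <<- f; f }
  stage <- "setup"
  tryCatch({
    stage <- "read"
    series <- read_step_log(config$steps)
    if (length(series) == 0) st_stop("no step data in ", config$steps)
    meta <- if (!is.null(config$patients)) read_patient_meta(config$patients)
    msas_pre <- if (!is.null(config$msas_pre)) read_msas(config$msas_pre)
    msas_post <- if (!is.null(config$msas_post)) read_msas(config$msas_post)
    coh <- cohort(series, patients = meta, msas_pre = msas_pre,
                  msas_post = msas_post)
    log_stage(verbose, stage, n_patients(coh), " patients in")

    stage <- "completeness"
    comp <- lapply(c(pre = "pre", post = "post"), function(ph) {
      r <- completeness_report(coh, ph)
      r$full_days_per_patient <- as.list(r$full_days_per_patient)
      r
    })

    stage <- "filter"
    flt <- filter_cohort(coh)
    inc <- flt$cohort
    log_stage(verbose, stage, n_patients(inc), " of ", n_patients(coh),
              " patients adequate")
    if (n_patients(inc) == 0) st_stop("no patient passes the adequacy rule")

    stage <- "msas"
    msas <- NULL
    if (!is.null(inc$msas_pre) && !is.null(inc$msas_post)) {
      msas <- list(pre = score_msas(inc$msas_pre),
                   post = score_msas(inc$msas_post))
      msas$improvement <- msas_improvement(msas$pre, msas$post)
    }

    stage <- "summaries"
    summ <- list(pre = phase_summaries(inc, "pre"),
                 post = phase_summaries(inc, "post"))

    stage <- "volatility"
    vol <- lapply(inc$steps, function(s)
      list(pre = daily_volatility(s, "pre", method),
           post = daily_volatility(s, "post", method)))
    direction <- list(pre = as.list(direction_day_counts(inc, "pre")),
                      post = as.list(direction_day_counts(inc, "post")))
    ann <- annualized_change_summary(inc, method)

    stage <- "analysis"
    ppc <- prepost_summary_correlation(inc)
    daywise <- lapply(c(pre = "pre", post = "post"), function(ph)
      daywise_correlation(inc, ph, "mean"))
    ecog_cmp <- lapply(c(pre = "pre", post = "post"), function(ph)
      steps_vs_ecog(inc, ph))
    imp_cmp <- if (!is.null(msas))
      lapply(c(gdi = "gdi", phys = "phys", tmsas = "tmsas"), function(sc)
        improvement_step_comparison(inc, sc))
    age_cmp <- lapply(c(pre = "pre", post = "post"), function(ph)
      age_split_comparison(inc, ph, thr))

    stage <- "write"
    results <- list(
      n_patients_in = n_patients(coh),
      n_patients_included = n_patients(inc),
      exclusions = flt$exclusions,
      completeness = comp,
      msas = msas,
      phase_summaries = summ,
      direction_day_counts = direction,
      annualized_change = ann[c("per_patient", "by_ecog")],
      prepost_correlation = list(estimate = ppc$estimate,
                                 p_value = ppc$p_value, n = ppc$n),
      daywise_correlation = daywise,
      steps_vs_ecog = ecog_cmp,
      improvement_comparison = imp_cmp,
      age_comparison = age_cmp)
    jsonlite::write_json(results, emit(file.path(out_dir, "results.json")),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE, matrix = "rowmajor", force = TRUE)
    utils::write.csv(as.data.frame(round(ppc$estimate, 3)),
                     emit(file.path(out_dir, "prepost_correlation.csv")))
    utils::write.csv(do.call(rbind, lapply(names(daywise), function(ph)
      cbind(phase = ph, daywise[[ph]]))),
      emit(file.path(out_dir, "daywise_correlation.csv")), row.names = FALSE)
    if (!is.null(imp_cmp))
      utils::write.csv(do.call(rbind, imp_cmp),
                       emit(file.path(out_dir, "improvement_comparison.csv")),
                       row.names = FALSE)

    if (figures) {
      stage <- "figures"
      render_volatility_chart(vol, emit(file.path(out_dir, "volatility.png")))
      render_annualized_chart(ann$per_patient,
                              emit(file.path(out_dir, "annualized_variance.png")))
    }
    log_stage(verbose, "done", "wrote ", length(written), " file(s) to ",
              out_dir)
    invisible(results)
  }, error = function(e) {
    unlink(unlist(written))
    st_stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
            class = "steptrack_pipeline_error")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render the per-patient step-volatility chart
#'
#' One panel per patient, daily sigma(t) drawn as bars across the study
#' timeline with the pre/post phase boundary (day 0) marked. Layout is
#' deterministic given the input order.
#'
#' @param vol Named list (by patient) of lists with `pre` and `post`
#'   [daily_volatility()] results.
#' @param file Output image path (PNG).
#' @return `file`, invisibly.
#' @export
render_volatility_chart <- function(vol, file) {
  if (length(vol) == 0)
    st_stop("nothing to plot", class = "steptrack_validation_error")
  np <- length(vol)
  nc <- ceiling(sqrt(np))
  nr <- ceiling(np / nc)
  grDevices::png(file, width = 280 * nc, height = 200 * nr)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(nr, nc), mar = c(2.5, 3, 2, 0.5))
  on.exit(graphics::par(op), add = TRUE)
  rng <- range(unlist(lapply(vol, function(v) c(v$pre$sigma, v$post$sigma)),
                      use.names = FALSE), 0, na.rm = TRUE)
  for (id in names(vol)) {
    v <- rbind(vol[[id]]$pre, vol[[id]]$post)
    graphics::plot(NA, xlim = study_day_range(), ylim = rng,
                   xlab = "", ylab = "sigma(t)", main = id)
    graphics::abline(h = 0, col = "grey60")
    graphics::abline(v = 0, col = "grey60", lty = 2)
    if (nrow(v))
      graphics::segments(v$day, 0, v$day, v$sigma,
                         col = ifelse(v$sigma >= 0, "steelblue", "firebrick"),
                         lwd = 4)
  }
  invisible(file)
}

#' Render the paired pre/post annualized-variance chart
#'
#' One pre/post point pair per patient, joined by a segment coloured by
#' direction of change (increase, decrease or unchanged).
#'
#' @param per_patient Data frame with `patient_id`, `pre_var`, `post_var`
#'   (as in [annualized_change_summary()]`$per_patient`).
#' @param file Output image path (PNG).
#' @return `file`, invisibly.
#' @export
render_annualized_chart <- function(per_patient, file) {
  if (is.null(per_patient) || nrow(per_patient) == 0)
    st_stop("nothing to plot", class = "steptrack_validation_error")
  grDevices::png(file, width = 640, height = 480)
  on.exit(grDevices::dev.off())
  n <- nrow(per_patient)
  dir <- sign(per_patient$post_var - per_patient$pre_var)
  col <- c("grey40", "grey40", "firebrick")[dir + 2]
  col[dir > 0] <- "steelblue"
  ylim <- range(per_patient$pre_var, per_patient$post_var)
  graphics::plot(NA, xlim = c(0.5, n + 0.5), ylim = ylim, xaxt = "n",
                 xlab = "patient", ylab = "annualized variance",
                 main = "Annualized step-count variance, pre vs post")
  graphics::axis(1, at = seq_len(n), labels = per_patient$patient_id,
                 las = 2, cex.axis = 0.7)
  graphics::segments(seq_len(n), per_patient$pre_var,
                     seq_len(n), per_patient$post_var, col = col)
  graphics::points(seq_len(n), per_patient$pre_var, pch = 1, col = col)
  graphics::points(seq_len(n), per_patient$post_var, pch = 16, col = col)
  graphics::legend("topleft", pch = c(1, 16), legend = c("pre", "post"),
                   bty = "n")
  invisible(file)
}
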