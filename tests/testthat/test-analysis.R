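test_that("phase_summary: order statistics over FULL days only", {
  s <- step_series("P", 1:3, c(2000L, 4000L, 6000L))
  ps <- phase_summary(s, "post")
  expect_equal(unlist(ps[c("mean", "median", "max", "min")]),
               c(mean = 4000, median = 4000, max = 6000, min = 2000))
  one <- phase_summary(step_series("P", 5, 5000L), "post")
  expect_true(all(unlist(one[c("mean", "median", "max", "min")]) == 5000))
  mix <- step_series("P", 1:4, c(2000L, 50L, 100L, 4000L))
  pm <- phase_summary(mix, "post")
  expect_equal(pm$mean, 3000)               # PARTIAL days excluded
  expect_equal(pm$n_days_used, 2L)
  none <- phase_summary(step_series("P", 1:2, c(50L, 80L)), "post")
  expect_true(is.na(none$mean))
  expect_equal(none$reason, "no FULL days")
})

test_that("prepost correlation: identity diagonal and brute-force oracle", {
  # post identical to pre for every patient -> diagonal exactly 1
  set.seed(41)
  series <- lapply(1:6, function(i) {
    v <- rpois(7, 1000 * i) + 200L
    step_series(paste0("P", i), c(-7:-1, 1:7), c(v, v))
  })
  m <- prepost_summary_correlation(cohort(series))
  expect_equal(unname(diag(m$estimate)), rep(1, 4), tolerance = 1e-12)

  # 5-patient dataset vs direct covariance/sd formula
  coh <- cohort(lapply(1:5, function(i) {
    step_series(paste0("Q", i), c(-7:-1, 1:14),
                rpois(21, 800 + 700 * i) + 150L)
  }))
  got <- prepost_summary_correlation(coh)
  pre <- phase_summaries(coh, "pre"); post <- phase_summaries(coh, "post")
  for (i in c("mean", "median", "max", "min"))
    for (j in c("mean", "median", "max", "min")) {
      x <- post[[i]]; y <- pre[[j]]
      r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      expect_equal(got$estimate[i, j], r, tolerance = 1e-12)
    }

  # a patient lacking post data is dropped pairwise
  coh2 <- cohort(c(coh$steps, list(step_series("R", -7:-1, rpois(7, 900)))))
  got2 <- prepost_summary_correlation(coh2)
  expect_equal(unique(as.vector(got2$n)), 5)
  expect_error(prepost_summary_correlation(cohort(coh$steps[1:2])),
               "insufficient", class = "steptrack_validation_error")
})

test_that("daywise correlation handles degeneracies with reasons", {
  const <- constant_cohort(5)
  dw <- daywise_correlation(const, "pre", "mean")
  expect_true(all(dw$reason == "zero variance"))
  expect_true(all(is.na(dw$estimate)))

  set.seed(42)
  series <- lapply(1:6, function(i) {
    d <- c(-7:-1, 1:14)
    v <- rpois(21, 2000 + 900 * i) + 150L
    step_series(paste0("P", i), d, v)
  })
  # day -7 recorded for only 2 patients
  series[3:6] <- lapply(series[3:6], function(s)
    step_series(attr(s, "patient_id"), s$day[s$day != -7],
                s$steps[s$day != -7]))
  dw2 <- daywise_correlation(cohort(series), "pre", "mean")
  expect_equal(dw2$reason[dw2$day == -7], "n<3")
  expect_true(all(is.na(dw2$estimate[dw2$day == -7])))
  expect_true(all(!is.na(dw2$estimate[dw2$day != -7])))
})

test_that("a strong shared patient effect makes all daily correlations positive", {
  cfg <- sim_config(n_patients = 60, between_patient_sd = 0.6,
                    nb_dispersion = 50, wear_prob_start = 1,
                    wear_decay_per_day = 0, wear_logit_sd = 0,
                    partial_day_prob = 0, treatment_day_effect = 1,
                    seed = 5)
  dw <- daywise_correlation(gen_cohort(cfg), "pre", "mean")
  expect_true(all(dw$estimate > 0))
})

test_that("steps_vs_ecog: symmetric case, enumeration oracle, edge cases", {
  series <- c(lapply(1:4, function(i)
    full_series(paste0("A", i), pre = 1000 * i)),
    lapply(1:4, function(i)
      full_series(paste0("B", i), pre = 1000 * i + 1)))
  meta <- data.frame(patient_id = c(paste0("A", 1:4), paste0("B", 1:4)),
                     ecog = rep(c(0L, 1L), each = 4), age = 60, sex = "M",
                     chemo_type = "adjuvant")
  res <- steps_vs_ecog(cohort(series, meta), "pre")
  expect_equal(abs(res$test$rank_biserial) < 0.3, TRUE)  # near-identical dists
  expect_equal(nrow(res$groups), 2)

  # {1,2,3} vs {101,102,103}: exact two-sided p = 0.1 (2/20 arrangements)
  series2 <- c(lapply(1:3, function(i) full_series(paste0("L", i), pre = i)),
               lapply(1:3, function(i)
                 full_series(paste0("H", i), pre = 100 + i)))
  # pre values above are <=100 -> PARTIAL; use large distinct values instead
  series2 <- c(lapply(1:3, function(i)
    full_series(paste0("L", i), pre = 1000 + i)),
    lapply(1:3, function(i) full_series(paste0("H", i), pre = 5000 + i)))
  meta2 <- data.frame(patient_id = c(paste0("L", 1:3), paste0("H", 1:3)),
                      ecog = rep(c(0L, 1L), each = 3), age = 60, sex = "M",
                      chemo_type = "adjuvant")
  res2 <- steps_vs_ecog(cohort(series2, meta2), "pre")
  expect_equal(res2$test$p_value, 0.1, tolerance = 1e-12)

  # single ECOG group -> correlation absent with reason
  meta3 <- meta2; meta3$ecog <- 0L
  res3 <- steps_vs_ecog(cohort(series2, meta3), "pre")
  expect_null(res3$test)
  expect_equal(res3$spearman$reason, "fewer than two ECOG groups")
})

test_that("Mann-Whitney exact p equals full enumeration for sizes <= 5", {
  set.seed(43)
  for (i in 1:12) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    v <- sample(1:1000, n1 + n2)           # distinct, no ties
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    wt <- wilcox.test(x, y, exact = TRUE)
    expect_equal(wt$p.value, oracle_mw_p(x, y), tolerance = 1e-12)
  }
})

test_that("improvement split: hand cohort with 6000 vs 4000 steps/day", {
  ids <- paste0("P", 1:4)
  series <- lapply(seq_along(ids), function(i)
    full_series(ids[i], pre = c(6000, 6000, 4000, 4000)[i],
                post = c(6000, 6000, 4000, 4000)[i]))
  mk_msas <- function(vals) {
    df <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
    for (it in msas_catalog()$item) df[[it]] <- vals
    df
  }
  coh <- cohort(series, msas_pre = mk_msas(c(2L, 2L, 1L, 1L)),
                msas_post = mk_msas(c(1L, 1L, 1L, 1L)))  # P1,P2 improve
  cmp <- improvement_step_comparison(coh, "tmsas")
  expect_equal(cmp$mean_steps_pre[cmp$improved], 6000)
  expect_equal(cmp$mean_steps_pre[!cmp$improved], 4000)
  expect_equal(cmp$mean_steps_post[cmp$improved], 6000)
  expect_equal(cmp$n, c(2L, 2L))

  # all improved -> single row
  coh2 <- cohort(series, msas_pre = mk_msas(rep(2L, 4)),
                 msas_post = mk_msas(rep(1L, 4)))
  cmp2 <- improvement_step_comparison(coh2, "gdi")
  expect_equal(nrow(cmp2), 1)
  expect_true(cmp2$improved)
})

test_that("age split compares medians of phase-median steps", {
  series <- list(full_series("Y1", pre = 6000), full_series("Y2", pre = 5600),
                 full_series("O1", pre = 4700), full_series("O2", pre = 4800))
  meta <- data.frame(patient_id = c("Y1", "Y2", "O1", "O2"),
                     ecog = 0L, age = c(50, 55, 70, 75), sex = "F",
                     chemo_type = "metastatic")
  res <- age_split_comparison(cohort(series, meta), "pre")
  young <- res$groups$median_steps[res$groups$age_group == "<60"]
  old <- res$groups$median_steps[res$groups$age_group == ">=60"]
  expect_equal(young, 5800)
  expect_equal(old, 4750)
  expect_gt(young, old)
  expect_false(is.null(res$test))

  same <- age_split_comparison(cohort(series, within(meta, age <- 70)), "pre")
  expect_null(same$test)
  expect_equal(same$reason, "a single age group")
  thr0 <- age_split_comparison(cohort(series, meta), "pre", threshold = 0)
  expect_null(thr0$test)
})
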