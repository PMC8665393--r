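test_that("daily_volatility matches the relative-change definition", {
  s <- step_series("P", 1:2, c(1000, 1100))
  expect_equal(daily_volatility(s, "post")$sigma, 0.10)
  cst <- step_series("P", 1:3, c(500, 500, 500))
  expect_equal(daily_volatility(cst, "post")$sigma, c(0, 0))
  s3 <- step_series("P", 1:4, c(2000, 1000, 1500, 1500))
  expect_equal(daily_volatility(s3, "post")$sigma, c(-0.5, 0.5, 0))
})

test_that("gaps are never bridged and zero-previous pairs are skipped", {
  s <- step_series("P", c(1, 2, 4, 5, 6), c(100, 0, 200, 300, 400))
  dv <- daily_volatility(s, "post")
  # pair (1,2) usable; (2,4) is a gap; (4,5),(5,6) usable but (4,5) has
  # zero-free denominators; (2,?) zero-denominator would be skipped
  expect_equal(dv$day, c(2, 5, 6))
  expect_equal(attr(dv, "n_skipped_gap") > 0, TRUE)
  z <- step_series("P", 1:3, c(0, 10, 20))
  dz <- daily_volatility(z, "post")
  expect_equal(dz$sigma, 1)                 # only the (10,20) pair
  expect_equal(attr(dz, "n_skipped_zero"), 1L)
})

test_that("annualized volatility: closed-form oracle and degenerate cases", {
  cst <- step_series("P", 1:5, rep(500L, 5))
  expect_equal(annualized_volatility(cst, "post")$annualized_vol, 0)
  s <- step_series("P", 1:4, c(2000, 1000, 1500, 1500))  # sigma -0.5,0.5,0
  av <- annualized_volatility(s, "post")
  expect_equal(av$sigma_daily_sd, 0.5)
  expect_equal(av$annualized_vol, 0.5 * sqrt(365))
  expect_equal(av$annualized_var, av$annualized_vol^2)
  one <- step_series("P", 1:2, c(100L, 110L))
  av1 <- annualized_volatility(one, "post")
  expect_true(is.na(av1$annualized_vol))
  expect_equal(av1$reason, "insufficient data")
})

test_that("volatility equals the hand-loop oracle on random series", {
  set.seed(31)
  for (i in 1:40) {
    days <- sort(sample(-7:14, sample(5:22, 1)))
    s <- step_series("P", days, rpois(length(days), 3000))
    for (ph in c("pre", "post")) {
      got <- daily_volatility(s, ph)$sigma
      want <- oracle_sigma(s, ph)
      expect_equal(got, want, tolerance = 1e-12)
      av <- annualized_volatility(s, ph)$annualized_vol
      ov <- oracle_annualized_vol(s, ph)
      if (is.na(ov)) expect_true(is.na(av))
      else expect_equal(av, ov, tolerance = 1e-12)
    }
  }
})

test_that("sigma is scale-invariant but not translation-invariant", {
  set.seed(32)
  s <- step_series("P", 1:10, rpois(10, 4000))
  base <- daily_volatility(s, "post")$sigma
  scaled <- step_series("P", 1:10, s$steps * 3L)
  expect_equal(daily_volatility(scaled, "post")$sigma, base,
               tolerance = 1e-12)
  expect_equal(annualized_volatility(scaled, "post")$annualized_vol,
               annualized_volatility(s, "post")$annualized_vol,
               tolerance = 1e-12)
  shifted <- step_series("P", 1:10, s$steps + 1000L)
  expect_false(isTRUE(all.equal(daily_volatility(shifted, "post")$sigma,
                                base)))
})

test_that("log-return alternative agrees in sign and skips zeros", {
  s <- step_series("P", 1:4, c(1000, 2000, 2000, 0))
  dv <- daily_volatility(s, "post", method = "log")
  expect_equal(dv$sigma, c(log(2), 0))
  expect_equal(attr(dv, "n_skipped_zero"), 1L)
})

test_that("direction counts pool correctly and sum to usable pairs", {
  one <- cohort(list(step_series("P", 1:3, c(1000, 1100, 880))))
  expect_equal(direction_day_counts(one, "post"),
               c(n_up = 1L, n_down = 1L, n_flat = 0L))
  flat <- constant_cohort(3)
  expect_equal(direction_day_counts(flat, "post"),
               c(n_up = 0L, n_down = 0L, n_flat = 3L * 13L))

  coh <- gen_cohort(sim_config(n_patients = 27, seed = 9))
  for (ph in c("pre", "post")) {
    cnt <- direction_day_counts(coh, ph)
    pooled <- unlist(lapply(coh$steps, oracle_sigma, phase = ph))
    expect_equal(unname(cnt),
                 c(sum(pooled > 0), sum(pooled < 0), sum(pooled == 0)))
    expect_equal(sum(cnt), length(pooled))
  }
})

test_that("annualized_change_summary flags strict increases and logs gaps", {
  up <- step_series("U", c(-7:-1, 1:14),
                    c(1000, 1200, 900, 1100, 1000, 1050, 980,
                      rep(c(500, 2500), 7)))
  dn <- step_series("D", c(-7:-1, 1:14),
                    c(rep(c(500, 2500), 3), 600, rep(c(1000, 1010), 7)))
  gap <- step_series("G", c(-1, 1:5), c(100, 200, 300, 250, 280, 300))
  meta <- data.frame(patient_id = c("U", "D", "G"), ecog = c(0L, 1L, 0L),
                     age = 50, sex = "M", chemo_type = "adjuvant")
  res <- annualized_change_summary(cohort(list(up, dn, gap), meta))
  expect_equal(res$per_patient$increased,
               c(TRUE, FALSE))
  expect_equal(res$excluded$patient_id, "G")
  expect_equal(res$excluded$missing_phase, "pre")
  expect_equal(sum(res$by_ecog$n), 2)
  # strict inequality at the boundary
  same <- constant_cohort(1)
  r2 <- annualized_change_summary(same)
  expect_false(r2$per_patient$increased)
})
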