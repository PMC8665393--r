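test_that("step_series enforces its invariants", {
  s <- step_series("P1", c(2, -1, 1), c(10L, 0L, 5L))
  expect_s3_class(s, "step_series")
  expect_equal(s$day, c(-1L, 1L, 2L))            # sorted
  expect_equal(steps_on_day(s, c(-1, 3)), c(0L, NA))
  expect_error(step_series("P1", c(1, 1), c(5, 5)), "duplicate",
               class = "steptrack_duplicate_error")
  expect_error(step_series("P1", 15, 5), class = "steptrack_validation_error")
  expect_error(step_series("P1", 1, -3), class = "steptrack_validation_error")
  # NA steps are dropped: an NA count is "no recording"
  expect_equal(nrow(step_series("P1", 1:2, c(NA, 7))), 1L)
})

test_that("phase partition: 7 pre days, 14 post days, day 0 in neither", {
  expect_length(phase_days("pre"), 7)
  expect_length(phase_days("post"), 14)
  expect_false(0L %in% c(phase_days("pre"), phase_days("post")))
  s <- full_series("P1")
  s0 <- step_series("P1", c(-7:-1, 0, 1:14), rep(1000L, 22))
  expect_equal(nrow(phase_slice(s0, "pre")), 7)
  expect_equal(nrow(phase_slice(s0, "post")), 14)
})

test_that("read_step_log parses, validates and reports line numbers", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,study_day,steps",
               "P1,-1,1200", "P1,1,0", "P1,2,"), f)
  got <- read_step_log(f)
  expect_named(got, "P1")
  expect_equal(got$P1$day, c(-1L, 1L))           # blank steps day is absent
  expect_equal(steps_on_day(got$P1, 1), 0L)      # 0 steps is a present record

  writeLines("patient_id,study_day,steps", f)
  expect_length(read_step_log(f), 0)             # empty file, no error

  writeLines(c("patient_id,study_day,steps", "P1,3,10", "P1,3,11"), f)
  expect_error(read_step_log(f), "P1, 3", class = "steptrack_duplicate_error")

  writeLines(c("patient_id,study_day,steps", "P1,1,5", "P1,x,5"), f)
  expect_error(read_step_log(f), "line 3", class = "steptrack_parse_error")

  writeLines(c("patient_id,study_day,steps", "P1,20,5"), f)
  expect_error(read_step_log(f), "study_day",
               class = "steptrack_validation_error")
})

test_that("read_patient_meta validates records", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,ecog,age,sex,chemo_type",
               "P1,0,58,M,metastatic"), f)
  meta <- read_patient_meta(f)
  expect_equal(meta$ecog, 0L)
  expect_equal(meta$chemo_type, "metastatic")

  writeLines(c("patient_id,ecog,age,sex,chemo_type", "P1,7,58,M,adjuvant"), f)
  expect_error(read_patient_meta(f), "ecog",
               class = "steptrack_validation_error")
  writeLines(c("patient_id,ecog,age,sex,chemo_type",
               "P1,1,58,M,palliative"), f)
  expect_error(read_patient_meta(f), "chemo_type",
               class = "steptrack_validation_error")
})

test_that("a 27-patient metadata file reproduces the baseline ECOG split", {
  f <- withr::local_tempfile(fileext = ".csv")
  rows <- sprintf("P%02d,%d,%d,%s,adjuvant", 1:27,
                  rep(c(0, 1), c(17, 10)), 40 + (1:27), rep("M", 27))
  writeLines(c("patient_id,ecog,age,sex,chemo_type", rows), f)
  meta <- read_patient_meta(f)
  expect_equal(unname(table(meta$ecog)["0"]), 17)
  expect_equal(unname(table(meta$ecog)["1"]), 10)
})

test_that("cohort checks id uniqueness and membership", {
  expect_error(cohort(list(full_series("A"), full_series("A"))),
               class = "steptrack_duplicate_error")
  meta <- data.frame(patient_id = "A", ecog = 0L, age = 60, sex = "F",
                     chemo_type = "adjuvant")
  expect_error(cohort(list(full_series("B")), patients = meta),
               "unknown", class = "steptrack_validation_error")
  msas <- data.frame(patient_id = "Z")
  expect_error(cohort(list(full_series("A")), patients = meta,
                      msas_pre = msas),
               class = "steptrack_validation_error")
})

test_that("write/read round-trip is the identity, absent day != 0-step day", {
  dir <- withr::local_tempdir()
  s1 <- step_series("P1", c(-3, -2, 1, 5), c(0L, 500L, 101L, 99L))
  s2 <- step_series("P2", c(-1, 2), c(1000L, 2000L))
  meta <- data.frame(patient_id = c("P1", "P2"), ecog = c(0L, 1L),
                     age = c(55, 70), sex = c("M", "F"),
                     chemo_type = c("adjuvant", "metastatic"))
  coh <- cohort(list(s1, s2), patients = meta)
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_true(cohorts_equal(coh, back))
  # absent vs zero preserved
  expect_equal(steps_on_day(back$steps$P1, -3), 0L)
  expect_true(is.na(steps_on_day(back$steps$P1, -1)))
})

test_that("a generated 40-patient cohort round-trips field-for-field", {
  coh <- gen_cohort(sim_config(n_patients = 40, seed = 11))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(cohorts_equal(coh, read_cohort(dir)))
})
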