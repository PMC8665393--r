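# Fixture builders and independent oracles. Everything here is
# deliberately brute-force and separate from the package's own code paths.

# series covering whole phases with constant or given counts
full_series <- function(id, pre = 5000, post = 5000) {
  pre <- rep_len(pre, 7)
  post <- rep_len(post, 14)
  step_series(id, c(-7:-1, 1:14), c(pre, post))
}

# cohort with n patients, each with a full grid of `value` steps
constant_cohort <- function(n, value = 5000) {
  cohort(lapply(sprintf("C%02d", seq_len(n)), full_series,
                pre = value, post = value))
}

# Cohort whose phase day-classes match exact counts: n_full days >100,
# n_partial days recorded <=100, rest absent. Days are allocated
# patient-by-patient, filling FULL first.
completeness_fixture <- function(n_patients, phase, n_full, n_partial) {
  days <- phase_days(phase)
  len <- length(days)
  total <- n_patients * len
  stopifnot(n_full + n_partial <= total)
  cls <- rep("NONE", total)
  cls[seq_len(n_full)] <- "FULL"
  if (n_partial > 0) cls[n_full + seq_len(n_partial)] <- "PARTIAL"
  series <- lapply(seq_len(n_patients), function(i) {
    ci <- cls[(i - 1) * len + seq_len(len)]
    keep <- ci != "NONE"
    step_series(sprintf("F%03d", i), days[keep],
                as.integer(ifelse(ci[keep] == "FULL", 5000L, 50L)))
  })
  cohort(series)
}

# Cohort where exactly `n_pass` of `n` patients satisfy the >=3 FULL days
# rule in both phases; failures mirror the published split (8 pre-only,
# 3 post-only, 2 both, scaled/truncated as needed).
adequacy_fixture <- function(n = 40, n_pass = 27) {
  n_fail <- n - n_pass
  fail_mode <- rep(c("pre", "post", "both"), length.out = 0)
  if (n_fail > 0)
    fail_mode <- rep(c("pre", "post", "both"),
                     c(8, 3, 2))[seq_len(min(n_fail, 13))]
  if (n_fail > 13) fail_mode <- c(fail_mode, rep("pre", n_fail - 13))
  series <- c(
    lapply(seq_len(n_pass), function(i) full_series(sprintf("A%03d", i))),
    lapply(seq_along(fail_mode), function(i) {
      m <- fail_mode[i]
      pre <- if (m %in% c("pre", "both")) c(rep(5000L, 2), rep(50L, 5))
             else rep(5000L, 7)
      post <- if (m %in% c("post", "both")) c(rep(5000L, 2), rep(NA, 12))
              else rep(5000L, 14)
      step_series(sprintf("X%03d", i), c(-7:-1, 1:14), c(pre, post))
    }))
  cohort(series)
}

# ---- oracles ---------------------------------------------------------------

# hand-loop sigma(t) over consecutive recorded pairs
oracle_sigma <- function(series, phase) {
  days <- phase_days(phase)
  out <- numeric(0)
  for (t in days[-1]) {
    a <- steps_on_day(series, t - 1L)
    b <- steps_on_day(series, t)
    if (!is.na(a) && !is.na(b) && a > 0) out <- c(out, (b - a) / a)
  }
  out
}

oracle_annualized_vol <- function(series, phase) {
  s <- oracle_sigma(series, phase)
  if (length(s) < 2) return(NA_real_)
  m <- mean(s)
  sqrt(sum((s - m)^2) / (length(s) - 1)) * sqrt(365)
}

# membership-list sum/divide MSAS scoring for a single response row
oracle_msas_scores <- function(row) {
  members <- list(
    gdi = c("sadness", "irritability", "nervousness", "anxiety",
            "lack_of_appetite", "lack_of_energy", "drowsiness", "pain",
            "constipation", "dry_mouth"),
    phys = c("lack_of_appetite", "pain", "constipation", "lack_of_energy",
             "drowsiness", "nausea", "vomiting", "dry_mouth",
             "change_in_taste", "feeling_bloated", "dizziness",
             "weight_loss"),
    psych = c("anxiety", "nervousness", "sadness", "difficulty_sleeping",
              "difficulty_concentrating", "irritability"),
    tmsas = msas_catalog()$item)
  sapply(members, function(mm) {
    v <- unlist(row[mm])
    miss <- sum(is.na(v))
    if (miss > length(mm) / 2) return(NA_real_)
    sum(v, na.rm = TRUE) / (length(mm) - miss)
  })
}

random_msas_response <- function(id, p_missing = 0) {
  items <- msas_catalog()$item
  row <- data.frame(patient_id = id, stringsAsFactors = FALSE)
  for (it in items) {
    v <- sample(0:4, 1)
    if (p_missing > 0 && stats::runif(1) < p_missing) v <- NA_integer_
    row[[it]] <- v
  }
  row
}

# full-enumeration two-sided Mann-Whitney p (no ties), mirroring the
# exact-distribution two-sided rule 2*min(P(U<=u), P(U>=u)) capped at 1
oracle_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  stopifnot(!anyDuplicated(pool))
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# day-by-day recount of completeness classes over a cohort
oracle_completeness_counts <- function(coh, phase) {
  days <- phase_days(phase)
  counts <- c(FULL = 0, PARTIAL = 0, NONE = 0)
  for (id in coh$patients$patient_id) {
    s <- coh$steps[[id]]
    for (d in days) {
      v <- if (is.null(s)) NA else steps_on_day(s, d)
      k <- if (is.na(v)) "NONE" else if (v > 100) "FULL" else "PARTIAL"
      counts[k] <- counts[k] + 1
    }
  }
  counts
}

cohorts_equal <- function(a, b) {
  ok <- identical(dim(a$patients), dim(b$patients)) &&
    isTRUE(all.equal(a$patients, b$patients, check.attributes = FALSE)) &&
    identical(sort(names(a$steps)), sort(names(b$steps)))
  if (!ok) return(FALSE)
  for (id in names(a$steps)) {
    if (!isTRUE(all.equal(as.data.frame(a$steps[[id]]),
                          as.data.frame(b$steps[[id]]),
                          check.attributes = FALSE)))
      return(FALSE)
  }
  for (tab in c("msas_pre", "msas_post")) {
    ta <- a[[tab]]; tb <- b[[tab]]
    if (is.null(ta) != is.null(tb)) return(FALSE)
    if (!is.null(ta) &&
        !isTRUE(all.equal(ta[order(ta$patient_id), ],
                          tb[order(tb$patient_id), ],
                          check.attributes = FALSE)))
      return(FALSE)
  }
  TRUE
}
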