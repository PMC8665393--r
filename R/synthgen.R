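# Synthetic cohort generator.
#
# Generative model, per patient i:
#   ECOG g_i ~ ecog_probs; daily latent mean
#     mu_i(d) = M[g_i] * exp(b_i - sd_b^2/2) * f(d)
#   with b_i ~ N(0, sd_b) on the log scale (the -sd_b^2/2 offset makes
#   M[g] the *mean* daily steps of group g), and f(d) a treatment-day dip:
#   f = treatment_day_effect on days 0 and 1, recovering linearly to 1
#   over recovery_days. Daily steps ~ NegBinom(mu = mu_i(d), size =
#   nb_dispersion). A day is recorded (worn) with probability
#     plogis(qlogis(start_phase) + u_i_phase) * (1 - decay)^(days into phase)
#   where u_i_phase ~ N(0, wear_logit_sd) independently per phase (the
#   observed pre/post inadequacy patterns are close to independent);
#   non-worn days are absent. A worn day is additionally PARTIAL with
#   partial_day_prob (steps resampled uniformly on 0..100).
#
# MSAS items are ordered-categorical: item j, visit v score = number of
# cutpoints exceeded by eta_ijv = alpha_j + h_i + symptom_coupling * z_i
# + improvement_shift * improved_i * [v = post] + logistic noise, with
# z_i the standardized log activity level and h_i ~ N(0, msas_patient_sd)
# a patient burden effect. improved_i ~ Bernoulli(plogis(
# qlogis(improvement_prob_base) + improvement_coupling * z_i)): with
# positive improvement_coupling, more active patients are more likely to
# improve after the first cycle. The level and improvement channels are
# separate parameters because they pull the observed improvement split in
# opposite directions: strong level coupling floors the active patients'
# baseline scores, and a floored score cannot strictly decrease.

#' Synthetic cohort configuration
#'
#' Validates and completes a generator configuration. All probabilities
#' are in \[0, 1\]; `group_log_mean_steps` holds the log of the *mean*
#' daily steps of each ECOG group (natural scale recovered exactly in
#' expectation).
#'
#' @param n_patients Number of patients.
#' @param ecog_probs Named probability vector over ECOG levels (names are
#'   the integer levels), summing to 1.
#' @param group_log_mean_steps Named vector, log mean daily steps per ECOG
#'   level; names must match `ecog_probs`.
#' @param between_patient_sd Log-scale SD of the patient activity effect.
#' @param nb_dispersion Negative-binomial size parameter (> 0).
#' @param treatment_day_effect Multiplicative activity factor on the
#'   treatment day and post day 1 (1 = no dip).
#' @param recovery_days Days over which the dip recovers linearly to 1.
#' @param symptom_coupling Effect (logit scale) of standardized patient
#'   activity on MSAS item propensity; negative = more steps, lower
#'   burden.
#' @param improvement_prob_base Baseline probability that a patient's
#'   symptom burden improves after the first cycle.
#' @param improvement_coupling Effect (logit scale) of standardized
#'   activity on the improvement odds; positive = more steps, higher
#'   improvement probability. Set to 0 together with `symptom_coupling`
#'   for a fully uncoupled null world.
#' @param improvement_shift Latent-scale shift applied at the post visit
#'   for improved patients (negative lowers scores).
#' @param wear_prob_start Start-of-phase wear probability; length 1, or
#'   length 2 `c(pre, post)`.
#' @param wear_decay_per_day Geometric per-day decay of wear probability
#'   within each phase.
#' @param wear_logit_sd Between-patient adherence heterogeneity (logit
#'   scale), drawn independently per phase.
#' @param partial_day_prob Probability a worn day logs <= 100 steps.
#' @param msas_cutpoints Increasing latent cutpoints for item scores 1..4.
#' @param msas_patient_sd SD of the patient symptom-burden effect.
#' @param psych_item_offset Latent offset added to the 4 psychological
#'   frequency items (they run higher than physical severities).
#' @param sigma_method Unused by the generator; recorded for pipelines.
#' @param seed Integer RNG seed; the generator is fully reproducible.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 40,
                       ecog_probs = c(`0` = 0.63, `1` = 0.37),
                       group_log_mean_steps = c(`0` = log(7023),
                                                `1` = log(5405)),
                       between_patient_sd = 0.45,
                       nb_dispersion = 6,
                       treatment_day_effect = 0.5,
                       recovery_days = 3,
                       symptom_coupling = -1.0,
                       improvement_prob_base = 0.3,
                       improvement_coupling = 2.5,
                       improvement_shift = -2.0,
                       wear_prob_start = c(0.92, 0.99),
                       wear_decay_per_day = 0.03,
                       wear_logit_sd = 3.5,
                       partial_day_prob = 0.02,
                       msas_cutpoints = c(0.4, 2.2, 3.8, 5.2),
                       msas_patient_sd = 0.8,
                       psych_item_offset = 1.2,
                       sigma_method = "relative",
                       seed = 1L) {
  cfg <- list(n_patients = n_patients, ecog_probs = ecog_probs,
              group_log_mean_steps = group_log_mean_steps,
              between_patient_sd = between_patient_sd,
              nb_dispersion = nb_dispersion,
              treatment_day_effect = treatment_day_effect,
              recovery_days = recovery_days,
              symptom_coupling = symptom_coupling,
              improvement_prob_base = improvement_prob_base,
              improvement_coupling = improvement_coupling,
              improvement_shift = improvement_shift,
              wear_prob_start = wear_prob_start,
              wear_decay_per_day = wear_decay_per_day,
              wear_logit_sd = wear_logit_sd,
              partial_day_prob = partial_day_prob,
              msas_cutpoints = msas_cutpoints,
              msas_patient_sd = msas_patient_sd,
              psych_item_offset = psych_item_offset,
              sigma_method = sigma_method,
              seed = seed)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond)
    st_stop("sim_config: ", msg, class = "steptrack_validation_error")
  chk(is_count(cfg$n_patients) && length(cfg$n_patients) == 1,
      "n_patients must be a non-negative integer")
  chk(all(cfg$ecog_probs >= 0) && abs(sum(cfg$ecog_probs) - 1) < 1e-8,
      "ecog_probs must be non-negative and sum to 1")
  chk(!is.null(names(cfg$ecog_probs)), "ecog_probs must be named by ECOG level")
  chk(identical(sort(names(cfg$ecog_probs)),
                sort(names(cfg$group_log_mean_steps))),
      "group_log_mean_steps names must match ecog_probs")
  chk(all(as.integer(names(cfg$ecog_probs)) %in% 0:5),
      "ECOG levels must be integers 0..5")
  chk(cfg$between_patient_sd >= 0, "between_patient_sd must be >= 0")
  chk(cfg$nb_dispersion > 0, "nb_dispersion must be > 0")
  chk(cfg$treatment_day_effect > 0, "treatment_day_effect must be > 0")
  chk(cfg$recovery_days >= 0, "recovery_days must be >= 0")
  chk(length(cfg$wear_prob_start) %in% 1:2 &&
        all(cfg$wear_prob_start >= 0 & cfg$wear_prob_start <= 1),
      "wear_prob_start must be 1 or 2 probabilities")
  chk(cfg$wear_decay_per_day >= 0 && cfg$wear_decay_per_day < 1,
      "wear_decay_per_day must be in [0, 1)")
  chk(cfg$wear_logit_sd >= 0, "wear_logit_sd must be >= 0")
  chk(cfg$partial_day_prob >= 0 && cfg$partial_day_prob <= 1,
      "partial_day_prob must be a probability")
  chk(cfg$improvement_prob_base >= 0 && cfg$improvement_prob_base <= 1,
      "improvement_prob_base must be a probability")
  chk(!is.unsorted(cfg$msas_cutpoints, strictly = TRUE) &&
        length(cfg$msas_cutpoints) == 4,
      "msas_cutpoints must be 4 strictly increasing values")
  chk(cfg$msas_patient_sd >= 0, "msas_patient_sd must be >= 0")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 && is.finite(cfg$seed),
      "seed must be a single integer")
  structure(cfg, class = "sim_config")
}

# day -> activity factor (treatment dip on days 0..1, linear recovery)
dip_factor <- function(days, effect, recovery) {
  f <- rep(1, length(days))
  f[days %in% c(0L, 1L)] <- effect
  if (recovery > 0) {
    rec <- days > 1 & days <= 1 + recovery
    f[rec] <- effect + (1 - effect) * (days[rec] - 1) / (recovery + 1)
  }
  f
}

wear_probability <- function(cfg, phase, u) {
  start <- if (length(cfg$wear_prob_start) == 2)
    cfg$wear_prob_start[if (phase == "pre") 1 else 2]
  else cfg$wear_prob_start
  base <- if (start >= 1) rep(1, length(u))
          else if (start <= 0) rep(0, length(u))
          else stats::plogis(stats::qlogis(start) + u)
  days_in <- seq_len(length(phase_days(phase))) - 1L
  outer(base, (1 - cfg$wear_decay_per_day)^days_in)
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort (metadata, step series over study days -7..14, and
#' MSAS-SF responses at both visits) from the generative model described
#' in the configuration; see [sim_config()]. Identical seeds give
#' field-for-field identical cohorts.
#'
#' @param cfg A [sim_config()].
#' @return A `steptrack_cohort`.
#' @export
#' @examples
#' coh <- gen_cohort(sim_config(n_patients = 5, seed = 42))
#' n_patients(coh)
gen_cohort <- function(cfg) {
  cfg <- validate_sim_config(unclass(cfg))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(cfg$seed))

  n <- cfg$n_patients
  levels <- names(cfg$ecog_probs)
  ids <- sprintf("P%03d", seq_len(n))
  if (n == 0)
    return(cohort(list(), patients = validate_patient_meta(
      data.frame(patient_id = character(), ecog = integer(), age = numeric(),
                 sex = character(), chemo_type = character()))))
  ecog <- sample(levels, n, replace = TRUE, prob = cfg$ecog_probs)
  age <- round(stats::rnorm(n, 60, 11))
  age <- pmin(pmax(age, 30), 90)
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.63, 0.37))
  chemo <- sample(CHEMO_TYPES, n, replace = TRUE, prob = c(0.30, 0.22, 0.48))
  patients <- data.frame(patient_id = ids, ecog = as.integer(ecog), age = age,
                         sex = sex, chemo_type = chemo,
                         stringsAsFactors = FALSE)

  # latent activity
  b <- stats::rnorm(n, 0, cfg$between_patient_sd)
  log_mu <- cfg$group_log_mean_steps[ecog] - cfg$between_patient_sd^2 / 2 + b
  z <- if (n > 1 && stats::sd(log_mu) > 0) as.numeric(scale(log_mu))
       else rep(0, n)

  days <- study_day_range()[1]:study_day_range()[2]
  f <- dip_factor(days, cfg$treatment_day_effect, cfg$recovery_days)
  mu <- exp(log_mu) %o% f
  steps <- matrix(stats::rnbinom(n * length(days), mu = mu,
                                 size = cfg$nb_dispersion),
                  nrow = n, dimnames = list(ids, days))

  # adherence: independent per-phase heterogeneity
  u_pre <- stats::rnorm(n, 0, cfg$wear_logit_sd)
  u_post <- stats::rnorm(n, 0, cfg$wear_logit_sd)
  worn <- matrix(FALSE, n, length(days), dimnames = list(ids, days))
  p_pre <- wear_probability(cfg, "pre", u_pre)
  p_post <- wear_probability(cfg, "post", u_post)
  worn[, match(phase_days("pre"), days)] <-
    matrix(stats::runif(n * 7), n, 7) < p_pre
  worn[, match(phase_days("post"), days)] <-
    matrix(stats::runif(n * 14), n, 14) < p_post
  # treatment day itself: wear at the post start rate
  worn[, match(0L, days)] <- stats::runif(n) < p_post[, 1]

  partial <- matrix(stats::runif(n * length(days)) < cfg$partial_day_prob,
                    n, length(days)) & worn
  steps[partial] <- sample(0:100, sum(partial), replace = TRUE)

  series <- lapply(seq_len(n), function(i) {
    w <- worn[i, ]
    step_series(ids[i], days[w], steps[i, w])
  })

  improved <- stats::runif(n) <
    stats::plogis(stats::qlogis(cfg$improvement_prob_base) +
                    cfg$improvement_coupling * z)
  h <- stats::rnorm(n, 0, cfg$msas_patient_sd)
  msas_pre <- draw_msas(cfg, ids, h, z, post = FALSE, improved = improved)
  msas_post <- draw_msas(cfg, ids, h, z, post = TRUE, improved = improved)

  cohort(series, patients = patients, msas_pre = msas_pre,
         msas_post = msas_post)
}

draw_msas <- function(cfg, ids, h, z, post, improved) {
  cat32 <- msas_catalog()
  n <- length(ids)
  k <- nrow(cat32)
  # deterministic item difficulty spread, psych frequency items offset up
  alpha <- seq(-1, 0.5, length.out = k)[rank(cat32$item, ties.method = "first")]
  alpha <- alpha + ifelse(cat32$scale == "psychological",
                          cfg$psych_item_offset, 0)
  eta <- outer(h + cfg$symptom_coupling * z +
                 if (post) cfg$improvement_shift * improved else 0,
               alpha, "+")
  noise <- matrix(stats::rlogis(n * k), n, k)
  lat <- eta + noise
  score <- matrix(0L, n, k)
  for (cp in cfg$msas_cutpoints) score <- score + (lat > cp)
  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (j in seq_len(k)) out[[cat32$item[j]]] <- as.integer(score[, j])
  out
}

#' Named reference scenarios
#'
#' Loads the scenario presets shipped with the package
#' (`inst/extdata/scenarios/*.json`):
#' * `paper_like` - 40 patients, ECOG-linked mean steps, negative
#'   symptom-activity coupling, adherence tuned so roughly two-thirds of
#'   patients meet the 3-full-days rule in both phases;
#' * `null` - no group effect and zero coupling, full wear (for type-I
#'   error calibration);
#' * `high_dropout` - the paper-like world with a much faster within-phase
#'   wear decay, for adherence stress tests.
#'
#' @param seed Seed stored into every returned config.
#' @return Named list of [sim_config()] objects.
#' @export
reference_scenarios <- function(seed = 1L) {
  dir <- system.file("extdata", "scenarios", package = "steptrack")
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  out <- lapply(files, function(f) {
    cfg <- jsonlite::read_json(f, simplifyVector = TRUE)
    cfg$ecog_probs <- unlist(cfg$ecog_probs)
    cfg$group_log_mean_steps <- unlist(cfg$group_log_mean_steps)
    cfg$seed <- seed
    do.call(sim_config, cfg)
  })
  names(out) <- sub("\\.json$", "", basename(files))
  out
}
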