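---
title: "Methods: step-count monitoring of performance status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: step-count monitoring of performance status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steptrack)
```

## The problem

In oncology, a patient's performance status (ECOG-PS) and symptom burden
(MSAS-SF) guide treatment decisions, but both are assessed only at
clinic visits and are subject to rater disagreement. Daily step counts
from a consumer wrist tracker offer a continuous, passive proxy.
`steptrack` implements the analysis layer for a two-visit design: a
7-day baseline window before the first chemotherapy administration
(C1D1) and a 14-day window after it, with ECOG-PS and MSAS-SF collected
at both visits.

## Timeline and data model

Study days are integers relative to C1D1: the prechemotherapy phase is
days −7…−1, the postchemotherapy phase days 1…14, and day 0 (the
treatment/clinic day) belongs to neither phase, keeping the phase
lengths at exactly 7 and 14 days. Whether the treatment day itself
contributed step data is not constrained by the design; excluding day 0
from both phases is this package's convention.

A step series stores *recorded* days only. A recorded 0 is a present
observation (the tracker was worn, the patient barely moved); a day with
no row, or a blank `steps` field, is "no recording". The distinction is
preserved by every reader, writer and transformation, because the two
states classify differently (PARTIAL vs NONE) downstream.

## Wear-day classification and adequacy

A day is **FULL** when its recorded count is strictly greater than 100
steps, **PARTIAL** when a recording of at most 100 steps exists, and
**NONE** otherwise. The source convention defines FULL as ">100" and
PARTIAL as "<100", leaving exactly 100 unassigned; we assign 100 to
PARTIAL to keep the FULL definition strict. A patient is **adequate**
when both phases contain at least three FULL days; only adequate
patients enter the comparative analyses, while completeness reports
deliberately use the full enrolled cohort (denominators n×7 and n×14).

Completeness percentages are *largest-remainder* integers: raw
percentages are floored and the remaining points to 100 are assigned in
order of fractional remainder, ties favouring the less-complete
category. Independent half-up rounding cannot reproduce the published
accounting (195/280 prints as 69% next to 2/280 as 1% and 83/280 as
30%, which sums to 100 only under a largest-remainder allocation); raw
percentages are reported alongside the integers.

## MSAS-SF scoring

The catalog carries 32 items: 28 physical symptoms scored for
severity/distress 0–4 and 4 psychological symptoms (sadness,
irritability, nervousness, anxiety) scored for frequency. The frequency
scale is nominally 1–4; we encode "not present" as 0 so every item
shares one 0–4 numeric range — the standard scoring convention, and the
only one under which an asymptomatic patient attains the scale's lower
bound. Note the instrument descriptions that mention "26 physical
symptoms" are inconsistent with a 32-item total given 4 frequency
items; the catalog follows the 32-item total (28 + 4), which is also
what the 6-item psychological subscale requires, since "difficulty
sleeping" and "difficulty concentrating" are severity-scale items.

Subscales are arithmetic means over fixed member lists: GDI over the 4
frequency items plus 6 physical items, PHYS over 12 physical items,
PSYCH over 6 items, TMSAS over all 32. With missing responses a
subscale is prorated over the observed members when at least half are
present, otherwise reported absent — the conventional fallback for
patient-reported-outcome instruments; it keeps all scores in [0, 4].
Improvement between visits is a *strict* decrease (lower = less
burden); `delta = pre − post` so positive deltas are improvements.

## Step-count volatility

For consecutive recorded days the daily volatility is the relative
change

σ(t) = (S(t) − S(t−1)) / S(t−1),

positive when the count rose. Pairs spanning a gap are never bridged (a
multi-day gap is not a one-day behaviour change) and pairs with
S(t−1) = 0 are skipped and logged rather than treated as infinite; both
skip counts are attached to the result. Log-returns are available as an
alternative (`method = "log"`) and agree in sign.

The per-patient, per-phase summary is the sample standard deviation
(divisor n−1) of the σ(t) values, scaled by √365 — calendar days, since
wear is daily and continuous, not the √252 trading-day convention —
giving the annualized volatility; the annualized variance is its
square. At least two usable pairs are required, otherwise the result is
absent with the reason recorded. Because some published text
interchanges "annualized volatility" and "annualized variance", both
are always reported, with variance = volatility² by construction.

## Cohort analyses

Phase summaries (mean, median, max, min of daily steps) use FULL days
only: a ≤100-step recording is treated as non-wear, consistent with the
adequacy logic, not as near-zero activity. The post-vs-pre summary
correlation matrix is Pearson by default (the published values are
consistent with product–moment correlations), Spearman by option, with
pairwise deletion of patients lacking a phase.

The per-day profile correlates each study day's FULL-day count across
patients with the patients' *opposite-phase* summary statistic. The
quantity the original per-day table correlates is never defined; this
reading is one plausible interpretation and the output carries an
`interpretation` attribute saying exactly what was computed. Days with
fewer than 3 patients, or zero variance, are reported absent with a
reason rather than a number.

Group comparisons use the Mann–Whitney U test (exact when both groups
have ≤20 observations, normal approximation with continuity correction
otherwise) plus a rank-biserial effect size, and Spearman correlation
for the ordinal ECOG trend — small samples, ordinal grouping, no
normality assumption. ECOG levels are data-driven throughout; nothing
is hard-coded to the 0/1 (or 1/2) labels that appear inconsistently in
published accounts. P-values are two-sided with no multiplicity
correction. The age comparison splits at 60 years (`< 60` vs `≥ 60`)
over per-patient phase-median steps.

## The synthetic cohort generator

The generator exists because no patient-level data are deposited; it
produces cohorts with the statistical structure the analyses assume, so
every stage can be exercised and calibrated. Per patient:

* **ECOG and activity.** ECOG is drawn from `ecog_probs` (default
  0.63/0.37 over levels 0/1, the published baseline split). The latent
  mean daily count is `exp(group_log_mean − σ²/2 + b)` with
  `b ~ N(0, σ = 0.45)`; the −σ²/2 offset makes `exp(group_log_mean)`
  the *mean* of the group, so group means are recoverable parameters.
  Defaults use the published group means 7023 and 5405 steps/day.
  σ = 0.45 is a deliberately conservative reading of the published
  pooled spread (IQR ≈ 1.19 × median implies a combined day-level
  log-SD near 0.84).
* **Daily counts.** Negative binomial with size 6 — step counts are
  overdispersed counts; size 6 gives a day-to-day CV ≈ 0.4 at these
  means, consistent with the up/down-day behaviour described.
* **Treatment-day dip.** Days 0 and 1 are multiplied by
  `treatment_day_effect` (default 0.5) with linear recovery over
  `recovery_days` (default 3), parameterizing the post-day-1 anomaly
  without claiming a cause.
* **Adherence.** A day is recorded with probability
  `plogis(qlogis(start) + u) · (1 − decay)^(days into phase)`, with
  `u ~ N(0, 3.5)` drawn *independently per phase* — the published
  inadequacy pattern (8 patients pre-only, 3 post-only, 2 both) is
  close to independent, and no homogeneous wear model can produce ~30%
  missing days and ~32% inadequate patients at once. Worn days are
  PARTIAL with probability 0.02 (count resampled uniformly on 0–100).
  The start probabilities (0.92 pre, 0.99 post), heterogeneity and
  decay were calibrated once, by grid search, to the published
  completeness fractions (69/1/30 pre, 72/3/25 post, 68% adequacy) and
  then frozen in the shipped presets.
* **Symptoms.** Item scores are ordered-categorical: the number of
  fixed cutpoints exceeded by a latent logistic variable whose location
  is item difficulty + patient burden + `symptom_coupling` ×
  standardized activity (+ an improvement shift at the post visit).
  Negative coupling (default −1) makes active patients less
  symptomatic. Improvement is a separate channel: a patient improves
  with probability `plogis(qlogis(0.3) + 2.5 × z)`. The two channels
  are separate parameters because they pull in opposite directions —
  strong level-coupling floors the active patients' baseline scores,
  and a floored score cannot strictly decrease — so a single coupling
  cannot reproduce the observed pattern that the improved group walks
  more. The defaults were calibrated to the published ~62% improvement
  rate and ~1.2× improved/non-improved step ratio.

What a green test establishes: the pipeline reproduces the published
*arithmetic* exactly on fixtures built to the printed counts, and its
statistics behave correctly (oracle equivalence, type-I calibration,
parameter recovery) on data from this generative model. What it does
not establish: that the model captures real wear behaviour
(within-week structure, weather, illness episodes), intraday patterns,
or the published patient-level correlations, which are unreproducible
without the undeposited data.

The `null` preset removes the group effect and both couplings under
perfect wear; the two-group comparison then rejects at the nominal 5%
rate (checked over 1000 cohorts of 27). `high_dropout` accelerates the
within-phase decay for adherence stress tests.

## Numerical and design choices

* Integer percentages by largest remainder (ties to the less-complete
  category); means of FULL days per patient rounded half-up; raw values
  always kept alongside.
* Exactly-100-step days are PARTIAL; recorded zeros are PARTIAL, never
  NONE.
* σ(t) requires strictly consecutive recorded days; zero-denominator
  pairs are skipped and logged; fewer than two usable pairs makes the
  annualized summary absent with a reason.
* Correlation entries with n < 3 or zero variance are absent with
  reasons, never numbers.
* The pipeline writes one JSON results document; reruns on identical
  inputs are byte-identical. Any stage failure removes partial outputs
  and names the failing stage.
* Configs and scenario presets are JSON (not YAML), matching the
  package's only serialization dependency.

## Known limitations

Daily totals only — no wear-time-within-day modelling or imputation of
missing days; no mixed-effects longitudinal modelling, toxicity
prediction or survival analysis; the per-day correlation table rests on
a stated interpretation of an ambiguously defined published quantity;
and the generator's adherence and dispersion parameters are artifact
choices tuned to published marginal fractions, not fitted to data.
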