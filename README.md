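# steptrack

Remote monitoring of oncology patients' performance status from
consumer activity-tracker step counts.

Patients starting a new chemotherapy line wear a step tracker for 7 days
before the first administration (C1D1) and 14 days after it. `steptrack`
turns the resulting daily step logs, clinician ECOG-PS ratings and
MSAS-SF symptom questionnaires into the cohort-level statistics used to
ask whether step counts track performance status and symptom burden —
without any patient-level data, thanks to a built-in synthetic cohort
generator.

## What it computes

* **Wear-day adherence** — each study day is classified FULL (>100
  steps), PARTIAL (a recording of ≤100 steps) or NONE (no recording);
  a patient's data are *adequate* when both phases contain ≥3 FULL
  days. Cohort completeness reports use largest-remainder integer
  percentages so each phase row sums to 100%.
* **MSAS-SF scoring** — the 32-item Memorial Symptom Assessment
  Scale–Short Form: GDI (10 items), PHYS (12), PSYCH (6) and TMSAS (all
  32), each the arithmetic mean of its member items on the 0–4 scale,
  prorated when at least half a subscale's items are present. Pre/post
  improvement is a strict score decrease.
* **Step volatility** — the day-over-day relative change
  σ(t) = (S(t) − S(t−1)) / S(t−1) across strictly consecutive recorded
  days, its per-patient sample SD scaled to a yearly base
  (annualized volatility = sd(σ)·√365, variance = volatility²), and
  cohort counts of up/down/flat days.
* **Cohort analyses** — per-patient mean/median/max/min of FULL-day
  steps per phase; the 4×4 post-vs-pre Pearson correlation matrix of
  those summaries; per-day correlation profiles; ECOG-group comparisons
  (Mann–Whitney U, exact for small groups, plus Spearman); MSAS
  improvement and age-60 splits.
* **Synthetic cohorts** — negative-binomial daily counts with lognormal
  between-patient effects linked to ECOG, a treatment-day activity dip
  with linear recovery, geometrically decaying wear probability with
  between-patient heterogeneity, and latent ordinal MSAS items coupled
  to activity. Presets: `paper_like`, `null`, `high_dropout`.

## Worked example

```r
library(steptrack)
coh <- gen_cohort(reference_scenarios(seed = 7)$paper_like)
flt <- filter_cohort(coh)
completeness_report(coh, "pre")
#> <completeness_report> prechemotherapy: 40 patients, 280 days
#>   FULL     206 (74%)
#>   PARTIAL    4 (1%)
#>   NONE      70 (25%)
#>   mean FULL days/patient: 5

inc <- flt$cohort                       # 32 of 40 patients adequate
prepost_summary_correlation(inc)
#> <prepost_correlation> post (rows) vs pre (cols), pearson
#>         pre
#> post      mean median   max   min
#>   mean   0.726  0.663 0.788 0.566
#>   median 0.736  0.666 0.807 0.599
#>   max    0.653  0.607 0.722 0.445
#>   min    0.622  0.633 0.569 0.499

improvement_step_comparison(inc, "tmsas")
#>   subscale improved  n mean_steps_pre mean_steps_post
#> 1    tmsas     TRUE 24       7717.080        7140.069
#> 2    tmsas    FALSE  8       5810.252        4909.246
```

The completeness report says how many of the 280 possible
prechemotherapy patient-days carried usable data. The correlation
matrix shows that patients' post-chemotherapy activity summaries track
their pre-chemotherapy ones (here r ≈ 0.5–0.8). The improvement split
shows patients whose total symptom score improved after the first cycle
walked more in both phases — the generator's negative symptom–activity
coupling at work.

Run the whole pipeline on files and get a JSON/CSV/PNG bundle:

```r
run_pipeline(list(steps = "steps.csv", patients = "patients.csv",
                  msas_pre = "msas_pre.csv", msas_post = "msas_post.csv",
                  out_dir = "results"))
```

or from the shell via the wrapper in `inst/cli/`:

```sh
Rscript inst/cli/steptrack.R simulate --scenario paper_like --seed 7 --out simdir
Rscript inst/cli/steptrack.R analyze --steps simdir/steps.csv \
    --patients simdir/patients.csv --msas-pre simdir/msas_pre.csv \
    --msas-post simdir/msas_post.csv --out results
```

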