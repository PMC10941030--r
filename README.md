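# soleplay

Game-based screening of peripheral neuropathy (PNP) and cognitive
dysfunction (CD) from plantar-pressure insoles, as a tested, reusable R
pipeline.

Elderly patients with diabetes frequently develop PNP and CD, yet both are
screened with time-consuming, examiner-dependent instruments: the
Neuropathy Disability and Symptom Scores (PNP diagnosed when NDS ≥ 6, or
NDS ≥ 3 with NSS ≥ 5) and the Montreal Cognitive Assessment (one point
added for ≤ 12 years of education; education-adjusted MoCA < 26 indicates
CD). An alternative assessment has patients play a 15-minute session of
four video games — Apple-Catch, Balloon-Flying, Cross-Pressure,
Island-Jump — steered entirely by plantar pressure measured with
sensor-equipped insoles (8 force-sensing resistors per foot, 3.4 mbar
resolution over 250–7000 mbar). Game behavior reflects reaction time,
sensation, endurance and coordination, so features extracted per task and
per *task combination* (TC; sum/mean/SD over the left-foot, right-foot, or
bilateral tasks of a game) carry diagnostic signal for both conditions.

`soleplay` implements the full analysis chain for this design, for
methodologists and digital-biomarker researchers who want to study or
extend it without access to clinical data:

* a configurable **game catalogue** (task schedules, pressure bands,
  calibration, quantization, TC and feature enumeration);
* a **synthetic cohort generator** with the four-group structure
  (−PNP−CD / +PNP−CD / −PNP+CD / +PNP+CD), covariates moment-matched to
  published group summaries, and clinical scores consistent with the
  diagnostic rules by construction;
* a mechanistic **session simulator** (first-order lag control with
  correlated noise; impairment-dependent latency, decision errors,
  pressure noise and sensation thresholds; fatigue drift; 25 s
  Cross-Pressure timeouts);
* **feature extraction** (per-task primaries, TC secondaries,
  drop/impute pre-processing);
* **cohort statistics** (normality-gated tests, Holm–Bonferroni,
  gated correlations, grouped summary tables);
* **cardinality matching** under standardized-mean-difference (SMD)
  constraints, plus logistic odds-ratio models 1–4
  (univariate/adjusted × pre/post matching), with the closed-form
  2×2 odds ratio `OR = ad/bc` and Woolf CI
  `exp(ln OR ± 1.96·√(1/a+1/b+1/c+1/d))`;
* the **classification pipeline**: |r| > 0.5 correlation pruning,
  model-based importance ranking, top-10 predictor selection, stratified
  10-fold × 10-repeat cross-validation (AUC-ROC via the Mann–Whitney
  pair-counting formulation; sensitivity/specificity at the Youden
  point), comparing individual-risk-profile (IRP: gender, age, weight,
  BMI, diabetes type/duration) models against IRP+game models for the
  three contrasts against the −PNP−CD reference group.

Everything is tidyverse-shaped: tibbles in and out, `tidy()`/`glance()`
methods on fitted objects, `autoplot()` for match balance and
cross-validation results.

## Worked example

```r
library(soleplay)

# a synthetic cohort with the published group structure (80/92/28/61)
cohort <- simulate_cohort(cohort_config(), seed = 1)
prevalence(cohort$pnp_label)
#> # A tibble: 1 × 4
#>       n total proportion percent
#>   <int> <int>      <dbl>   <dbl>
#> 1   153   261      0.586    58.6

# odds ratio of CD given PNP from the pre-matching 2x2 counts
odds_ratio_2x2(61, 28, 92, 80)
#> # A tibble: 1 × 7
#>      or ci_low ci_high log_or    se p_value corrected
#>   <dbl>  <dbl>   <dbl>  <dbl> <dbl>   <dbl> <lgl>
#> 1  1.89   1.11    3.25  0.639 0.275  0.0200 FALSE

# small end-to-end run: simulate sessions, extract features, match,
# fit association models, evaluate one classification contrast
run <- run_study(group_counts = c(20, 20, 20, 20), seed = 1,
                 families = "glmnet", folds = 5, repeats = 5,
                 contrasts = "both")
run
#> <study_run>
#>   participants: 80; valid sessions: 80
#>   game features: 220 extracted, 216 retained after pre-processing
#>   matching: 35 per group (greedy_fallback)
#>   both: IRP AUC 0.522 -> IRP+game AUC 0.975
```

The prevalence row says 153 of 261 synthetic participants (58.6 %) carry
the PNP label — exactly the group quotas it was asked to generate. The
odds-ratio row is the association between PNP and CD implied by the
published pre-matching counts: patients with PNP have 1.89 times the odds
of CD (95 % CI 1.11–3.25). In the pipeline run, the game features lift
the combined-conditions contrast from chance-adjacent performance with
covariates alone (AUC 0.52 at this small n) to 0.97 with game features —
the planted impairment signal is recoverable from the simulated pressure
traces.

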