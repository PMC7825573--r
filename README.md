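# dvhtox

Dose–volume histogram (DVH) reduction and logistic NTCP modelling of late
bladder toxicity after prostate radiotherapy.

## What it is for

Radiation oncologists constrain treatment plans through the bladder's
cumulative DVH — the fraction of organ volume receiving at least each dose
level. dvhtox is for analysts relating those DVHs to graded late
genitourinary toxicity (RTOG/CTCAE grades 0–4). It implements:

- **DVH handling** — validated cumulative/differential containers,
  per-patient linear interpolation (`volume_at_dose()`, the *Vdose*
  predictor), a long-form CSV dialect with percent/cc/fraction volume
  units (`read_cohort()` / `write_cohort()`).
- **Dose-response mathematics** — the generalized equivalent uniform dose
  (power mean) `EUD = (Σᵢ vᵢ Dᵢᵃ)^(1/a)` with bladder exponent `a = 1.4`,
  and the logistic NTCP sigmoid
  `NTCP = 1 / (1 + (TD₅₀/EUD)^(4γ₅₀))`,
  fitted by maximum likelihood (`compute_eud()`, `ntcp()`, `fit_ntcp()`).
- **Vdose selection** — an iterative scan fitting
  `logit P(tox) = a + b·V_d` at every candidate dose `d` and selecting the
  dose with minimal AIC among models with slope p < 0.05, with a 0.1-Gy
  refinement pass (`scan_vdose()`).
- **Risk tables** — algebraic inversion of the fitted logistic model into
  dose–volume constraints, e.g. with the published coefficients
  (a = −2.5, b = 4.3 on V51.43) "keep V51.43 < 25.9% to keep grade ≥ 2
  risk below 20%" (`build_risk_table()`).
- **Internal validation** — TRIPOD type 1b bootstrap (B resamples with
  replacement, median AUC), rank-formulation AUC, Hosmer–Lemeshow
  calibration (`bootstrap_validate()`, `hosmer_lemeshow()`).
- **Synthetic cohorts** — a seeded generator of sigmoid bladder DVHs with
  toxicity drawn from a logistic truth model, so the whole pipeline is
  testable without patient data (`generate_cohort()`).
- **Orchestration** — `run_pipeline()` chains every stage and writes JSON/CSV
  reports; `inst/scripts/dvhtox.R` exposes the same pipeline as a command
  line.

## Worked example

```r
library(dvhtox)

cohort <- generate_cohort(cohort_spec(n = 175, seed = 42))
scan   <- scan_vdose(cohort, rule = outcome_rule(2, subset_grade_ge = 0),
                     quiet = TRUE)
scan
#> Vdose scan over 99 dose levels (n = 175 patients)
#> Selected Vdose = 47.10 Gy (AIC 205.228, slope 5.511, p = 9.995e-08)

val <- bootstrap_validate(cohort, predictor_dose_gy = scan$selected_dose_gy,
                          rule = outcome_rule(2, 0), B = 1000, seed = 42)
val
#> Bootstrap internal validation (B = 1000, seed = 42, n = 175, apparent)
#>   AUC: apparent 0.767, bootstrap median 0.769, mean 0.766
#>   Hosmer-Lemeshow: chi2 = 3.419 on 8 df, p = 0.9054

f <- scan$selected_fit
build_risk_table(logistic_risk_model(f$intercept, f$slope,
                                     scan$selected_dose_gy))
#> Risk of toxicity related to V47.1 (%)
#> V47.1 volume (%)   Risk
#> <32.2%             <10%
#> <46.9%             <20%
#> <72.1%             <50%
```

Reading: on this synthetic 175-patient cohort (toxicity generated from a
logistic law on V51.43) the AIC scan localizes the threshold to 47.1 Gy —
a few Gy of scatter is what a cohort this size supports; at n = 2000 the
scan lands within ±2.5 Gy of the generating 51.43 Gy in essentially every
replicate. The bootstrap median AUC of 0.769 measures in-sample
discrimination of the selected model, and the Hosmer–Lemeshow p of 0.91
shows no detectable miscalibration. The risk table translates the fitted
coefficients into constraints a planner can act on.

The methods vignette (`vignettes/bladder-toxicity-modelling.Rmd`) documents
the models, the generator's assumptions and what the synthetic checks do
and do not demonstrate about real data.

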