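# tamipd — model-informed precision dosing for tamoxifen

Tamoxifen, the standard adjuvant endocrine therapy for ER-positive breast
cancer, is a prodrug: its effect is carried mainly by the CYP2D6-formed
metabolite **endoxifen**, and steady-state endoxifen below **16 nM**
(5.97 ng/mL) has been associated with a higher recurrence risk. Because
tamoxifen needs ~3 months to reach steady state, dose corrections based on
measured levels (TDM) come late. *Model-informed precision dosing* (MIPD)
instead predicts each patient's steady-state endoxifen from baseline
covariates and starts them directly on 20, 30 or 40 mg/day — or flags a
switch to an aromatase inhibitor (AI) when even 40 mg is predicted
insufficient.

`tamipd` is an R implementation of that workflow for pharmacometricians and
methods researchers:

* **CYP2D6 scoring** — diplotypes (`"*1/*4"`, `"*1x2/*1"`) on the continuous
  activity scale with `*1/*1` ≡ 1.0, and the five activity bins
  (`activity_score()`, `assign_bin()`).
* **Prediction** — a log-linear steady-state population model with
  log-normal between-patient variability and first-order accumulation,

  C_ss(D) = (D/20) · tvc20 · exp(θ_AS (AS − AS_ref)) · (age/age_ref)^θ_age ·
  (BMI/BMI_ref)^θ_BMI · (height/height_ref)^θ_height · e^η,  η ~ N(0, ω²),

  with C(t) = C_ss (1 − 2^(−t/t½)) (`pk_model()`, `predict_css()`,
  `predict_concentration()`).
* **Dose selection** — the threshold rule with boundaries 16, 32/3 and 8 nM
  on the 20 mg prediction (`recommend_dose()`, `classify_attainment()`).
* **Bayesian update** — closed-form empirical-Bayes (MAP) shrinkage of the
  individual deviation from a single pre-steady-state sample, with early
  (< day 22) samples flagged uninformative (`estimate_eta()`,
  `update_recommendation()`).
* **Evaluation** — median-centred MAPE/bias, RMSE, F80–125 %, uncorrected
  Pearson chi-squared and exact Fisher tests, analytic and Monte-Carlo
  power (`prediction_metrics()`, `chisq_2x2()`, `fisher_2x2()`,
  `empirical_power()`), and MCID comparisons (`mcid_compare()`).
* **Simulation** — calibrated virtual cohorts and whole-trial simulation
  under `FIXED_20`, `MIPD` and `MIPD_WITH_UPDATE` dosing policies
  (`generate_cohort()`, `simulate_trial()`).
* **Files & pipeline** — CSV readers with row-level validation, YAML
  configuration, a JSON report writer, and the end-to-end
  `run_pipeline()`; a thin command-line front end ships at
  `inst/cli/tamipd` (subcommands `genotype-score`, `predict`, `recommend`,
  `update`, `evaluate`, `simulate`, `power`).

## Worked example

An intermediate metaboliser (`*4/*41`, activity 0.25), 62 years, BMI 29,
height 164 cm:

```r
library(tamipd)
model <- pk_model()
act   <- activity_score("*4/*41")              # 0.25
css20 <- predict_css(model, dose = 20, activity = act,
                     age = 62, bmi = 29, height = 164)
recommend_dose(css20)
#>   category administered_dose predicted_css_at_administered predicted_css_20
#> 1      D30                30                      17.76634         11.84423
```

The 20 mg prediction (11.8 nM) misses the 16 nM target, but 1.5 × 11.8 =
17.8 nM clears it, so the patient starts on 30 mg. A day-35 sample one third
below the model prediction then pulls the individual estimate down:

```r
obs <- data.frame(time = 35, dose = 30,
                  concentration = predict_concentration(model, dose = 30,
                    activity = act, time = 35, age = 62, bmi = 29,
                    height = 164) * 2/3)
ebe <- estimate_eta(model, obs, activity = act, age = 62, bmi = 29,
                    height = 164)
ebe
#> Empirical-Bayes update (1 of 1 samples used)
#>   eta_hat -0.3495 (shrinkage 0.862)
#>   updated Css at 20 mg: 8.35 nM
update_recommendation(ebe)
#>   category administered_dose predicted_css_at_administered predicted_css_20
#> 1      D40                40                      16.70067         8.350335
```

The −0.35 log deviation (86 % of the observed residual, the single-sample
shrinkage at ω = 0.5, σ = 0.2) drops the updated 20 mg prediction to
8.35 nM: the patient is escalated to 40 mg, predicted 16.7 nM at steady
state. A whole simulated trial on a 5 000-patient virtual cohort:

```r
simulate_trial(cohort_config(n = 5000, seed = 7), model, policy = "MIPD")
#> Simulated trial under policy MIPD (n = 5000, threshold 16 nM)
#>   attainment at day 90 : 82.9 % (as treated)
#>   switched counted     : 90.3 %
#>   sub-therapeutic by dose category:
#>      group n_below n_total pct_below
#>        D20     454    4295      10.6
#>        D30       0       0        NA
#>        D40      32      74      43.2
#>  SWITCH_AI     369     631      58.5
#>   ...
```

"Switched counted" treats the switch-to-AI group as attained (they would
have left tamoxifen); "as treated" evaluates them on the 40 mg they actually
received. Under the one-dose-fits-all comparator (`policy = "FIXED_20"`) the
same cohort attains ~78 %.

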