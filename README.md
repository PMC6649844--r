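# das2c

Derivation and validation of a two-component, imaging-weighted disease
activity score for early rheumatoid arthritis.

## The problem

The 28-joint Disease Activity Score (DAS28) combines tender and swollen
joint counts (TJC28, SJC28), an acute-phase reactant (CRP or ESR) and the
patient's global health VAS (GHVAS). Its weights were derived from
rheumatologists' treatment decisions, not from measured joint inflammation.
When synovitis is measured directly — by ultrasound grey-scale (GS) and
power Doppler (PD) scoring of individual joints, summarised as a scalar
GSPD — only SJC28 and CRP carry independent association with it; TJC28 and
GHVAS do not. This motivates a re-weighted two-component score,

```
2C-DAS28CRP = sqrt(SJC28) + 0.6 * ln(CRP + 1)
2C-DAS28ESR = sqrt(SJC28) + 0.32 * ln(ESR)
```

whose acute-phase weight is the reciprocal of the observation-weighted mean
of the per-cohort ratios `beta_sqrt(SJC28) / beta_acute-phase` taken from
two-component random-intercept linear models of GSPD fitted in several
development cohorts. Ratios — not raw coefficients — are pooled because each
cohort scans a different joint set, so the GSPD outcome scale differs while
the relative weighting of the two components does not.

`das2c` implements that full derivation pipeline as reusable, tested
functions, exercised end-to-end on synthetic cohorts that emulate the
development data structure:

* joint-level GS/PD combination (composite 22-joint and plain-sum 10-joint
  conventions) into GSPD — `combine_joint()`, `gspd_total()`;
* conventional composite scores (4C/3C DAS28, partial SDAI/CDAI) with exact
  unit conventions — `das28_4c_crp()` and friends, `score_visits()`;
* left-censored CRP (< 5 mg/L) imputation by robust regression on order
  statistics, and selection of a single clinical substitute value —
  `ros_impute()`, `select_single_substitute()`;
* multiple imputation by chained equations with predictive mean matching
  and Rubin pooling — `mice_pmm()`, `rubin_pool()`;
* random-intercept linear models (ML via lme4) compared by patient-clustered
  20-fold cross-validated R² and out-of-sample log-likelihood with a 2.6
  natural-log-unit evidence threshold — `fit_lmm()`, `kfold_cv()`,
  `test_loglik()`, `compare_models()`;
* score-weight derivation from coefficient ratios — `coefficient_ratio()`,
  `combine_ratios()`, `emit_equation()`;
* longitudinal radiographic validation: GEE with exchangeable working
  correlation and QIC for erosion presence, random-intercept log-link
  models for Larsen damage scores — `fit_gee_erosion()`, `qic()`,
  `fit_larsen_longitudinal()`;
* synthetic-cohort generators with recorded ground truth —
  `generate_development_cohorts()`, `generate_validation_cohort()`;
* a pipeline orchestrator — `run_pipeline()`, plus a thin CLI at
  `inst/scripts/das2c-pipeline.R`.

## Worked example: deriving the score weights

The published two-component model coefficients and observation counts of the
three development cohorts ship with the package and are the inputs from
which the final weights are recomputed:

```r
library(das2c)
pub <- published_coefficients()
crp <- subset(pub, acute_phase == "CRP")
ratios <- lapply(seq_len(nrow(crp)), function(i)
  coefficient_ratio(c(sjc = crp$beta_sjc[i], ap = crp$beta_ap[i]),
                    n_weight = crp$n_obs[i] - crp$n_missing_ap[i],
                    cohort = crp$cohort[i]))
emit_equation(combine_ratios(ratios), "CRP", provenance = ratios)
```

prints

```
2C-DAS28CRP = sqrt(SJC28) + (0.6 x ln(CRP+1))
  combined SJC:CRP ratio 1.6968 over 3 cohort(s)
    IACON: ratio 1.9812 (n = 836)
    IDEA: ratio 0.7790 (n = 154)
    PEAC: ratio 1.1552 (n = 178)
```

Each cohort line shows the within-cohort ratio of the `sqrt(SJC28)`
coefficient to the `ln(CRP+1)` coefficient and the number of observations
with a non-missing CRP measurement used as its weight; their weighted mean
(1.6968) is inverted and rounded to one decimal place to give the 0.6
acute-phase weight. The ESR path (`acute_phase == "ESR"`, two decimal
places) yields 0.32. Scoring a visit is then a one-liner:

```r
das28_2c_crp(sjc28 = 2, crp = 6)   # 2.581760
```

The full synthetic pipeline — simulate three cohorts, reduce ultrasound
scans to GSPD, impute, derive the equation, validate radiographically —
runs from a single config:

```r
man <- run_pipeline(run_config(seed = 1), outdir = "das2c_run")
```

and writes `score_equation.json`, `cv_report.csv`, `validation_report.csv`
and a hash manifest; rerunning the same config reproduces identical files.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package: the acute-phase weights of the final CRP and ESR equations from
the shipped published coefficient table, and the single censored-CRP
substitute from robust-ROS imputation of lognormal CRP samples calibrated
to the development cohort's quartiles. Run it as

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Limitations

The real development cohorts are private; nothing here reproduces their
patient-level data, and cross-validated R² values on the synthetic cohorts
are not comparable to the published ones. The package deliberately provides
no remission or activity cut-offs for the 2C scores and does not rescale
them onto conventional DAS28 thresholds. See the methods vignette
(`vignettes/two-component-das.Rmd`) for modelling assumptions, generator
calibration and numerical choices.
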