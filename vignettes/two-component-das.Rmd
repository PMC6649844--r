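---
title: "Deriving a two-component imaging-weighted DAS28: methods and design notes"
author: "das2c"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving a two-component imaging-weighted DAS28}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(das2c)
```

This vignette records the statistical model behind `das2c`, the assumptions
it makes, what the synthetic-data generators do and do not emulate, and the
design decisions taken where the methodology left genuine latitude. It
states no empirical result that the test suite or `scripts/acceptance.R` do
not themselves compute.

## The outcome: GSPD

Ultrasound synovitis is scored per joint on semiquantitative grey-scale
(GS) and power Doppler (PD) scales. Two summation conventions are
supported:

* **composite22** — the joint-level composite grade (0 iff GS = PD = 0,
  otherwise `max(GS, PD)`, grades 0–3) summed over 22 joints (bilateral
  wrists, MCPs 2–3, PIPs 2–3, knees, MTPs 1–5); maximum 66.
* **sum10** — raw GS + PD (0–4 scales) summed over bilateral MCPs 1–5;
  maximum 80.

The composite rule is exposed as `combine_joint()` and is deliberately
swappable: the published scoring table is reproduced by the max rule for
all grade combinations, including the atypical case of PD signal without
GS hypertrophy, which we score by the same rule rather than forcing to 0.
Raw 0–4 grades in the sum10 convention are summed without rescaling: the
downstream derivation uses within-cohort coefficient *ratios*, which absorb
any cohort-specific scaling of the outcome.

## The derivation model

For visit $j$ of patient $i$, GSPD is modelled by a random-intercept linear
model estimated by maximum likelihood (lme4, `REML = FALSE` so that
log-likelihoods are comparable across fixed-effect sets):

$$\mathrm{GSPD}_{ij} = \beta_0 + \beta_1\sqrt{\mathrm{SJC28}_{ij}}
  + \beta_2\ln(\mathrm{CRP}_{ij}+1) + \dots + b_i + \varepsilon_{ij},
  \qquad b_i \sim N(0, \tau^2),\ \varepsilon_{ij} \sim N(0, \sigma^2).$$

Model comparison uses patient-clustered 20-fold cross-validation: patients
(never visits) are partitioned, predictions for held-out patients use fixed
effects only ($b_i = 0$), R² is the squared Pearson correlation over the
concatenated test folds, and the out-of-sample evidence is the
log-likelihood of each held-out patient's residual vector under the
compound-symmetry covariance $\sigma^2 I + \tau^2 J$, summed over patients
and folds (`test_loglik()`, closed form via the Sherman–Morrison identity;
tests verify it against a dense multivariate-normal density to 1e-10).

A test-log-likelihood difference of
$\tfrac12\chi^2_{0.99,2} - 2 \approx 2.6$ natural-log units is the evidence
threshold for comparisons with two extra parameters: by the asymptotic
equivalence of leave-one-out cross-validation and AIC, the out-of-sample
comparison pays the parameter-count penalty automatically, so a
likelihood-ratio test at $P = 0.01$ maps to $4.61 - 2 = 2.61$ units
(`evidence_threshold()`).

Patient-level folds are a design decision: the per-individual test
likelihood requires whole patients in test sets. Folds are assigned by a
recorded seed; when multiply imputed datasets are supplied, the fold
assignment is shared and per-dataset metrics are averaged arithmetically
(how the original analysis merged MI and CV metrics is unstated; the
arithmetic mean is the simplest consistent choice). Imputation is performed
once on the full dataset, not nested within training folds, mirroring the
original analysis.

## Censored CRP

CRP assays commonly report "< 5 mg/L". `ros_impute()` implements robust
regression on order statistics under a lognormal assumption with
censoring-adjusted Weibull plotting positions: with $m$ detected and $c$
censored of $n$ values, the threshold exceedance probability is $m/n$;
detected values occupy positions $(1-pe) + pe\,i/(m+1)$, censored values
$(1-pe)\,k/(c+1)$. $\ln(\text{detected})$ is regressed on normal scores and
censored values are replaced by back-transformed predictions at their
positions; detected values are never altered (the "robust" property). The
plotting-position formula is a config-level choice — the original analysis
names the method but not the formula; Weibull positions are the common
default in environmental-statistics practice. Predictions falling at or
above the threshold (possible at the highest censored position in small or
atypical samples) are capped just below it, since censored observations are
known to lie below the reporting limit.

The clinical substitute is the median of the imputed values rounded half-up
to an integer (`select_single_substitute()`); single substitution was the
original design choice, made for clarity of downstream use. All score
functions take the substitute as a parameter (default 2 mg/L).

## Missing covariates

`mice_pmm()` is a self-contained chained-equations imputer with type-0
predictive mean matching (donor pool k = 5, 10 cycles, defaults m = 20),
operating on the transformed analysis scales
($\sqrt{\mathrm{SJC28}}, \sqrt{\mathrm{TJC28}}, \ln \mathrm{ESR},
\ln(\mathrm{CRP}+1)$, GHVAS) plus HAQ-DI, age and sex. GSPD is excluded
from the predictor set and rows without observed GSPD are dropped before
imputation. Donor pool size and cycle count are unstated in the source
methodology; k = 5 and 10 cycles are the conventional defaults of
established MI software. `rubin_pool()` combines per-imputation estimates
with total variance $\bar W + (1 + 1/m)B$ and a Barnard–Rubin t reference.

## Score-weight derivation

`coefficient_ratio()` forms the within-cohort ratio
$\beta_{\sqrt{SJC}} / \beta_{AP}$ from a two-component fit, weighted by the
number of *observations* with a non-missing acute-phase measurement (the
source text is ambiguous between patients and observations; its own
formula description says observations, which we use). `combine_ratios()`
is the weight-normalised sum; `emit_equation()` inverts the combined ratio
and rounds to 1 decimal (CRP) or 2 decimals (ESR), matching the precision
of the published constants. Ratios are carried at full precision
internally: the published combined ratio (1.68) is not reproducible from
the rounded per-cohort ratios, so rounding happens only at emission. For
the ESR equation, the observation weights count visits missing ESR only
(not ESR-and-CRP jointly); this choice reproduces the published 0.32.

## Radiographic validation

Erosion presence is a longitudinal binary outcome, fitted by a Liang–Zeger
GEE with logit link, exchangeable working correlation (moment-estimated
from Pearson residuals), robust sandwich covariance, and Pan's QIC
$-2\,QL + 2\,\mathrm{tr}(\hat\Omega_I \hat V_R)$. On clusters of size one
the coefficients collapse to the ordinary logistic MLE (verified to 1e-6)
and the simplified $QIC_u = -2QL + 2p$ equals the logistic AIC exactly;
the trace-penalised QIC differs from AIC by a finite-sample term of order
$1/\sqrt{n}$, which is why `qic()` reports both.

The Larsen damage total is a non-negative, right-skewed longitudinal
outcome. The original analysis used a generalized linear latent and mixed
model without restating family or link; we implement the declared proxy of
the specification — a patient random-intercept model with log link and
variance proportional to the mean, i.e. a Poisson working likelihood via
`lme4::glmer` (Laplace approximation, the 1-point case of adaptive
quadrature) — with age and disease duration always included. Its adequacy
is established only by parameter recovery against the matching generator,
not by any claim about the original model.

## Synthetic cohorts: the stated world

`default_cohort_specs()` encodes three development cohorts with the
published structure: 434 patients at weeks 0/26/52/104 (composite22, 0–3
grades), 59 at 0/52/78 (composite22), 117 at 0/26 (sum10, 0–4 grades).
Component distributions are calibrated to the published baseline summaries:
lognormal CRP and ESR (e.g. the largest cohort's CRP has log-median
$\ln 6$ and $\sigma = \ln 3 / z_{0.75} \approx 1.63$ so that Q3 = 18 mg/L —
implying ~46% of values below the 5 mg/L censoring threshold, against the
published 431/889 ≈ 48%), joint counts as rounded squares of Gaussians on
the $\sqrt{}$ scale clipped to 0–28, GHVAS as a truncated Gaussian on
0–100 mm. The tender–swollen correlation on the transformed scale is not
published; it is a config parameter defaulting to 0.5. Marginal missingness
rates per component match the published availability counts and are
applied missing-at-random given age and HAQ-DI (logistic dependence,
recalibrated to the marginal rate), so that chained-equation imputation is
exercised non-trivially.

GSPD is realized from the latent linear model with defaults
$\beta_{\sqrt{SJC}} = 4$, $\beta_{\ln CRP} = 2.5$ (ratio 1.6, within the
span of the published per-cohort ratios), $\beta_{TJC} = \beta_{GHVAS} = 0$
(the central structural claim), intercept 12, $\tau^2 = \sigma^2 = 9$ —
chosen once so the realized totals sit inside the 0–66 composite grid with
a typical value near the published GS+PD medians. The integer total is
spread greedily across the joint grid (grade cap respected, PD never
exceeding GS under composite22), so the recombined ultrasound table
reproduces the generated GSPD exactly; only the total enters the analysis,
so the arrangement is otherwise arbitrary. Totals above the grid maximum
raise an error; latent totals rounding below zero (order 1e-4 per visit at
defaults) are clamped to zero and counted in the `n_clamped` attribute —
a documented left-censoring at the empty-joint grid rather than a silent
truncation.

The validation generator emulates a primary-care inception cohort observed
at 0/3/5/10 years: Larsen totals accrue as Poisson increments with log-rate
$\log(\text{baseline}/\text{span}) + \gamma_s\sqrt{SJC} +
\gamma_c\ln(CRP+1) + \gamma_t\sqrt{TJC} + b_i$ (hence monotone
non-decreasing within patient — monotonicity is an imposed design decision,
the original analysis treats Larsen longitudinally without stating it), and
erosion presence is Bernoulli with the same linear predictor plus an
intercept, sharing the patient random effect. Default signs
$\gamma_s, \gamma_c > 0$, $\gamma_t < 0$ encode the published validation
pattern.

What a green test does and does not establish: the generators reproduce the
*structure* the analysis assumes — visit clustering, transformed-scale
linearity, MAR missingness, left-censoring, the null TJC/GHVAS effects —
not the case mix, treatment dynamics, sonographer variability or informative
dropout of the real cohorts. Parameter-recovery and model-preference tests
on these cohorts validate the estimation machinery, not the clinical
claims; conversely, no real-data coefficient from the source tables is
reproducible here because the underlying data are private.

## Numerical choices and degenerate inputs

* ESR = 0 is mapped to 1 mm/h before `ln()` (standard DAS28 convention;
  the source never addresses `ln(0)`).
* Rounding of the censored-CRP substitute and of score weights is
  half-away-from-zero (`round_half_up()`), matching 1.88 → 2; base R's
  banker's rounding would break the published worked examples.
* GEE: maximum 100 iterations, tolerance 1e-8 on the coefficient step;
  the exchangeable correlation is clipped to its feasible range; fitted
  probabilities numerically at 0/1 raise a separation error.
* `fit_lmm` rejects missing cells outright (imputation is a separate,
  explicit step) and singular random-effect fits are allowed to land on the
  boundary $\hat\tau^2 = 0$.
* Pipeline outputs are CSV (UTF-8, 6 significant digits) plus JSON
  sidecars; the manifest records MD5 hashes, seeds and versions, and
  rerunning a config reproduces identical hashes.

## Known limitations

The Larsen model is a proxy for an unstated GLLAMM family; QIC here is
Pan's formulation and other software may differ in the penalty term; the
MICE implementation covers the numeric/binary columns this pipeline needs,
not general categorical data; and the 2C scores carry no remission
thresholds by design.
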