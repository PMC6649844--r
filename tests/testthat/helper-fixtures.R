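# Shared fixture builders. All data are generated in code at test time.

# one small IACON-like cohort, optionally without censoring/missingness so
# parameter-recovery checks are not attenuated
small_cohort <- function(n = 120, seed = 1, truth = truth_record(seed = seed),
                         clean = FALSE, visits = c(0, 26, 52, 104),
                         ultrasound = FALSE) {
  spec <- default_cohort_specs(c(IACON = n))$IACON
  spec$visit_weeks <- visits
  if (clean) {
    spec$crp_censor_threshold <- 0
    spec$missingness_rates[] <- 0
  }
  truth$seed <- as.integer(seed)
  gen <- generate_development_cohorts(list(IACON = spec), truth,
                                      include_ultrasound = ultrasound)
  out <- gen$IACON
  out$visits <- add_transformed_components(out$visits)
  out
}

small_radiographs <- function(n = 200, seed = 1, truth = radiograph_truth()) {
  truth$seed <- as.integer(seed)
  rad <- generate_validation_cohort(validation_cohort_spec(n), truth)
  add_transformed_components(rad)
}

# dense multivariate-normal log-density oracle for the compound-symmetry
# patient covariance (generic linear algebra, independent of test_loglik)
dense_cs_loglik <- function(resid, id, sigma2, tau2) {
  total <- 0
  for (rr in split(resid, id)) {
    q <- length(rr)
    Sigma <- diag(sigma2, q) + matrix(tau2, q, q)
    total <- total +
      mvtnorm::dmvnorm(rr, mean = rep(0, q), sigma = Sigma, log = TRUE)
  }
  total
}

published_ratios <- function(ap) {
  pub <- published_coefficients()
  pub <- pub[pub$acute_phase == ap, ]
  lapply(seq_len(nrow(pub)), function(i)
    coefficient_ratio(c(sjc = pub$beta_sjc[i], ap = pub$beta_ap[i]),
                      n_weight = pub$n_obs[i] - pub$n_missing_ap[i],
                      cohort = pub$cohort[i]))
}
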