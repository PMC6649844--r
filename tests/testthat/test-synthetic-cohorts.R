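test_that("cohort and truth constructors validate their invariants", {
  expect_error(cohort_spec("X", 0, c(0, 26)), "positive")
  expect_error(cohort_spec("X", 10, numeric(0)), "empty")
  expect_error(cohort_spec("X", 10, c(26, 0)), "strictly increasing")
  expect_error(cohort_spec("X", 10, c(0, 26), gs_scale_max = 5), "3 or 4")
  expect_error(cohort_spec("X", 10, c(0, 26),
                           missingness_rates = c(crp = 1.2)), "\\[0, 1\\]")
  expect_error(truth_record(tau2 = -1), "tau2")
  expect_error(truth_record(beta_crp = 0), "finite")
  expect_error(radiograph_truth(gamma_sjc = -0.1), "positive")
  expect_error(radiograph_truth(gamma_tjc = 0.1), "non-positive")
  specs <- default_cohort_specs()
  expect_named(specs, c("IACON", "IDEA", "PEAC"))
  expect_equal(vapply(specs, `[[`, integer(1), "n_patients"),
               c(IACON = 434L, IDEA = 59L, PEAC = 117L))
})

test_that("generation is deterministic under a fixed seed", {
  specs <- default_cohort_specs(c(IACON = 30, IDEA = 15, PEAC = 15))
  a <- generate_development_cohorts(specs, truth_record(seed = 7))
  b <- generate_development_cohorts(specs, truth_record(seed = 7))
  expect_identical(a, b)
  c_ <- generate_development_cohorts(specs, truth_record(seed = 8))
  expect_false(identical(a, c_))
  # byte-identical CSV output
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(a$IACON$visits, f1, row.names = FALSE)
  write.csv(b$IACON$visits, f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  rad1 <- generate_validation_cohort(validation_cohort_spec(40),
                                     radiograph_truth(seed = 3))
  rad2 <- generate_validation_cohort(validation_cohort_spec(40),
                                     radiograph_truth(seed = 3))
  expect_identical(rad1, rad2)
})

test_that("generated component distributions match their calibration targets", {
  spec <- default_cohort_specs(c(IACON = 2500))$IACON
  spec$crp_censor_threshold <- 0       # uncensored values for raw moments
  spec$missingness_rates[] <- 0
  gen <- generate_development_cohorts(list(spec), truth_record(seed = 71),
                                      include_ultrasound = FALSE)
  v <- gen$IACON$visits                # 10,000 visits
  expect_equal(nrow(v), 10000)
  # lognormal CRP calibrated to median 6, Q3 18
  expect_equal(median(v$crp), 6, tolerance = 0.1)
  expect_equal(quantile(v$crp, 0.75)[[1]], 18, tolerance = 0.1)
  # joint counts on the sqrt scale; medians on the count scale
  expect_true(median(v$sjc28) %in% 1:3)      # target 2
  expect_true(median(v$tjc28) %in% 3:5)      # target 4
  expect_equal(mean(v$ghvas), 37, tolerance = 0.1)  # truncation shifts 35 up
  expect_true(all(v$tjc28 >= 0 & v$tjc28 <= 28))
  expect_true(all(v$ghvas >= 0 & v$ghvas <= 100))
  expect_gt(cor(sqrt(v$tjc28), sqrt(v$sjc28)), 0.3)  # config default 0.5
})

test_that("realized GSPD regressed on components recovers the truth betas", {
  truth <- truth_record(beta_sjc = 4, beta_crp = 2.5, beta_tjc = 0,
                        beta_ghvas = 0, seed = 74)
  v <- small_cohort(n = 400, seed = 74, truth = truth, clean = TRUE)$visits
  fit <- fit_lmm(v, c("sqrt_sjc", "ln_crp", "sqrt_tjc", "ghvas"))
  se <- sqrt(diag(fit$vcov_fixed))
  expect_lt(abs(fit$beta[["sqrt_sjc"]] - 4), 2 * se[["sqrt_sjc"]])
  expect_lt(abs(fit$beta[["ln_crp"]] - 2.5), 2 * se[["ln_crp"]])
  expect_lt(abs(fit$beta[["sqrt_tjc"]]), 2 * se[["sqrt_tjc"]])
  expect_lt(abs(fit$beta[["ghvas"]]), 2 * se[["ghvas"]])
})

test_that("null TJC/GHVAS effects are covered by their CIs across replicates", {
  # scaled-down version of the 100-replicate coverage property
  hits <- 0; n_rep <- 20
  for (s in 1:n_rep) {
    v <- small_cohort(n = 120, seed = 900 + s, clean = TRUE,
                      visits = c(0, 26, 52))$visits
    fit <- fit_lmm(v, c("sqrt_sjc", "ln_crp", "sqrt_tjc", "ghvas"))
    se <- sqrt(diag(fit$vcov_fixed))
    hits <- hits + (abs(fit$beta[["sqrt_tjc"]]) < 1.96 * se[["sqrt_tjc"]] &&
                      abs(fit$beta[["ghvas"]]) < 1.96 * se[["ghvas"]])
  }
  expect_gte(hits, 16)
})

test_that("CRP censoring matches the published censored fraction", {
  spec <- default_cohort_specs(c(IACON = 450))$IACON
  gen <- generate_development_cohorts(list(spec), truth_record(seed = 77),
                                      include_ultrasound = FALSE)
  cen_frac <- mean(gen$IACON$visits$crp_censored, na.rm = TRUE)
  expect_lt(abs(cen_frac - 431 / 889), 0.05)
  # censored rows carry the threshold, never a smaller measurement
  cen <- which(gen$IACON$visits$crp_censored)
  expect_true(all(gen$IACON$visits$crp[cen] == 5))
})

test_that("missingness rates are honoured and MAR depends on age/HAQ", {
  spec <- default_cohort_specs(c(IACON = 1000))$IACON
  gen <- generate_development_cohorts(list(spec), truth_record(seed = 79),
                                      include_ultrasound = FALSE)
  v <- gen$IACON$visits
  expect_equal(mean(is.na(v$esr)), 159 / 889, tolerance = 0.25)
  expect_equal(mean(is.na(v$ghvas)), 59 / 889, tolerance = 0.35)
  expect_equal(mean(is.na(v$crp)), 53 / 889, tolerance = 0.35)
  # MAR: missingness probability increases with age + HAQ score
  z <- scale(v$age)[, 1] + scale(v$haq)[, 1]
  expect_gt(mean(z[is.na(v$esr)]), mean(z[!is.na(v$esr)]))
})

test_that("joint-grade decomposition reproduces the realized GSPD exactly", {
  specs <- default_cohort_specs(c(IACON = 25, IDEA = 15, PEAC = 25))
  gen <- generate_development_cohorts(specs, truth_record(seed = 81))
  for (nm in names(gen)) {
    method <- specs[[nm]]$gspd_method
    g <- gspd_table(gen[[nm]]$ultrasound, method = method)
    m <- merge(gen[[nm]]$visits, g, by = c("patient_id", "week"))
    expect_true(all(m$gspd.x == m$gspd.y))
    smax <- specs[[nm]]$gs_scale_max
    expect_true(all(gen[[nm]]$ultrasound$gs <= smax &
                      gen[[nm]]$ultrasound$pd <= smax))
  }
  # a GSPD target beyond the joint grid raises rather than truncating
  big <- truth_record(intercept = 500, seed = 83)
  expect_error(
    generate_development_cohorts(default_cohort_specs(c(IACON = 10))["IACON"],
                                 big),
    "not representable")
})

test_that("the validation cohort has monotone damage and a correct null model", {
  rad <- generate_validation_cohort(validation_cohort_spec(150),
                                    radiograph_truth(seed = 85))
  expect_true(all(rad$larsen >= 0))
  expect_true(all(rad$erosion %in% 0:1))
  mono <- tapply(rad$larsen, rad$patient_id, function(x) all(diff(x) >= 0))
  expect_true(all(mono))
  expect_true(all(diff(rad$years[rad$patient_id == rad$patient_id[1]]) > 0))

  # subject_sd = 0 and vanishing effects: erosion prevalence ~ expit(intercept)
  null_truth <- radiograph_truth(gamma_sjc = 1e-9, gamma_crp = 1e-9,
                                 gamma_tjc = 0, erosion_intercept = -1,
                                 subject_sd = 0, seed = 87)
  rad0 <- generate_validation_cohort(validation_cohort_spec(400), null_truth)
  p <- mean(rad0$erosion)
  expect_lt(abs(p - plogis(-1)), 3 * sqrt(plogis(-1) * (1 - plogis(-1)) / 1600))
  expect_error(generate_validation_cohort(validation_cohort_spec(0)),
               "positive")
})
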