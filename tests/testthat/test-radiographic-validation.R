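test_that("GEE on size-1 clusters equals the logistic MLE", {
  rad <- small_radiographs(n = 250, seed = 41)
  r1 <- rad[rad$years == 0, ]
  g <- fit_gee_erosion(r1, c("sqrt_sjc", "ln_crp"))
  ml <- glm(erosion ~ sqrt_sjc + ln_crp, binomial, r1)
  expect_equal(unname(g$beta), unname(coef(ml)), tolerance = 1e-6)
  # independence limit: QICu equals the logistic AIC
  expect_equal(qic(g)$qicu, AIC(ml), tolerance = 1e-9)
  # the trace-penalised QIC stays close (finite-sample sandwich deviation)
  expect_lt(abs(qic(g)$qic - AIC(ml)), 2)
})

test_that("GEE estimates exchangeable correlation with sane inference", {
  rad <- small_radiographs(n = 250, seed = 43)
  g <- fit_gee_erosion(rad, c("sqrt_tjc", "sqrt_sjc", "ln_crp"))
  expect_true(g$converged)
  expect_gt(g$alpha, -1 / 3)
  expect_lt(g$alpha, 1)
  expect_true(all(is.finite(g$se_robust) & g$se_robust > 0))
  expect_error(fit_gee_erosion(rad, "nonexistent"), "missing column")
  rad0 <- rad; rad0$erosion <- 0
  expect_error(fit_gee_erosion(rad0, "sqrt_sjc"), "does not vary")
})

test_that("GEE recovers the generating sign pattern", {
  # scaled-down sign-recovery (the 100-replicate version runs in the
  # acceptance suite): negative TJC, positive SJC and CRP
  hits <- 0
  for (s in 1:15) {
    rad <- small_radiographs(n = 150, seed = 600 + s)
    g <- fit_gee_erosion(rad, c("sqrt_tjc", "sqrt_sjc", "ln_crp"))
    hits <- hits + (g$beta[["sqrt_tjc"]] < 0 && g$beta[["sqrt_sjc"]] > 0 &&
                      g$beta[["ln_crp"]] > 0)
  }
  expect_gte(hits, 13)
})

test_that("QIC penalises pure-noise predictors on average", {
  set.seed(71)
  diffs <- vapply(1:12, function(s) {
    rad <- small_radiographs(n = 100, seed = 700 + s)
    rad$noise <- rnorm(nrow(rad))
    q0 <- qic(fit_gee_erosion(rad, "sqrt_sjc"))$qic
    q1 <- qic(fit_gee_erosion(rad, c("sqrt_sjc", "noise")))$qic
    q1 - q0
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("the Larsen model recovers signs and handles null effects", {
  rad <- small_radiographs(n = 250, seed = 47)
  L <- fit_larsen_longitudinal(rad, c("sqrt_tjc", "sqrt_sjc", "ln_crp"))
  expect_lt(L$coefficients["sqrt_tjc", "estimate"], 0.05)
  expect_gt(L$coefficients["sqrt_sjc", "estimate"], 0)
  expect_gt(L$coefficients["ln_crp", "estimate"], 0)
  expect_true(is.finite(L$aic) && is.finite(L$bic))

  # near-null effects: slopes ~0, fitted level matches the outcome mean on
  # the log-link scale (up to random-intercept shrinkage)
  null_truth <- radiograph_truth(gamma_sjc = 1e-9, gamma_crp = 1e-9,
                                 gamma_tjc = 0, subject_sd = 0, seed = 49)
  rad0 <- small_radiographs(n = 200, seed = 49, truth = null_truth)
  L0 <- fit_larsen_longitudinal(rad0, "sqrt_sjc")
  expect_lt(abs(L0$coefficients["sqrt_sjc", "estimate"]),
            3 * L0$coefficients["sqrt_sjc", "se"] + 0.02)
  pred_mean <- mean(predict(L0$fit, type = "response"))
  expect_equal(pred_mean, mean(rad0$larsen), tolerance = 0.1)

  rad_bad <- rad; rad_bad$larsen <- rad_bad$larsen + 0.5
  expect_error(fit_larsen_longitudinal(rad_bad, "sqrt_sjc"), "integer")
  rad_zero <- rad; rad_zero$larsen <- 0L
  expect_error(fit_larsen_longitudinal(rad_zero, "sqrt_sjc"), "all-zero")
})

test_that("2C score fits radiographic outcomes better than 3C without a TJC effect", {
  # scaled-down model-comparison property (full version in acceptance)
  wins_qic <- 0; wins_aic <- 0; n_rep <- 10
  for (s in 1:n_rep) {
    rad <- small_radiographs(n = 150, seed = 800 + s)
    rad$das28_2c_crp <- rad$sqrt_sjc + 0.6 * rad$ln_crp
    rad$das28_3c_crp <- (0.56 * rad$sqrt_tjc + 0.28 * rad$sqrt_sjc +
                           0.36 * rad$ln_crp) * 1.10 + 1.15
    q2 <- qic(fit_gee_erosion(rad, "das28_2c_crp"))$qic
    q3 <- qic(fit_gee_erosion(rad, "das28_3c_crp"))$qic
    wins_qic <- wins_qic + (q2 < q3)
    a2 <- fit_larsen_longitudinal(rad, "das28_2c_crp")$aic
    a3 <- fit_larsen_longitudinal(rad, "das28_3c_crp")$aic
    wins_aic <- wins_aic + (a2 < a3)
  }
  expect_gt(wins_qic, n_rep / 2)
  expect_gt(wins_aic, n_rep / 2)
})
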