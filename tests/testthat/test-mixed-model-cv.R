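test_that("fit_lmm recovers generating coefficients and matches nlme", {
  truth <- truth_record(beta_sjc = 4, beta_crp = 2.5, beta_tjc = 0,
                        beta_ghvas = 0, tau2 = 9, sigma2 = 9, seed = 101)
  v <- small_cohort(n = 300, seed = 101, truth = truth, clean = TRUE)$visits
  fit <- fit_lmm(v, c("sqrt_sjc", "ln_crp", "sqrt_tjc", "ghvas"))
  se <- sqrt(diag(fit$vcov_fixed))
  truth_beta <- c(`(Intercept)` = truth$intercept, sqrt_sjc = truth$beta_sjc,
                  ln_crp = truth$beta_crp, sqrt_tjc = 0, ghvas = 0)
  for (term in names(truth_beta))
    expect_lt(abs(fit$beta[term] - truth_beta[term]), 2 * se[term])
  expect_gt(fit$tau2, 0.5 * truth$tau2)
  expect_lt(fit$tau2, 2 * truth$tau2)

  # independent mixed-model oracle (nlme, ML)
  or <- nlme::lme(gspd ~ sqrt_sjc + ln_crp + sqrt_tjc + ghvas,
                  random = ~ 1 | patient_id, data = v, method = "ML")
  expect_equal(unname(fit$beta), unname(nlme::fixef(or)), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(or)), tolerance = 1e-6)

  expect_error(fit_lmm(v, "nonexistent"), "missing column")
  v$ln_crp[1] <- NA
  expect_error(fit_lmm(v, c("sqrt_sjc", "ln_crp")), "missing cells")
})

test_that("a zero random-intercept variance is estimated at the boundary", {
  truth <- truth_record(tau2 = 0, sigma2 = 9, seed = 7)
  v <- small_cohort(n = 150, seed = 7, truth = truth, clean = TRUE)$visits
  fit <- fit_lmm(v, c("sqrt_sjc", "ln_crp"))
  expect_lt(fit$tau2, 1)
})

test_that("predict_fixed is the fixed-effects linear predictor", {
  v <- small_cohort(n = 80, seed = 13, clean = TRUE)$visits
  fit <- fit_lmm(v, c("sqrt_sjc", "ln_crp"))
  zero <- data.frame(sqrt_sjc = 0, ln_crp = 0)
  expect_equal(predict_fixed(fit, zero), unname(fit$beta["(Intercept)"]))
  # linear in ln_crp holding sqrt_sjc fixed
  nd <- data.frame(sqrt_sjc = 1, ln_crp = c(0, 1, 2))
  p <- predict_fixed(fit, nd)
  expect_equal(diff(p), rep(unname(fit$beta["ln_crp"]), 2), tolerance = 1e-12)
  # oracle: lme4 population-level prediction on unseen covariates
  refit <- lme4::lmer(gspd ~ sqrt_sjc + ln_crp + (1 | patient_id), v,
                      REML = FALSE)
  nd2 <- data.frame(sqrt_sjc = c(0.3, 2.1), ln_crp = c(1.2, 3.0))
  expect_equal(predict_fixed(fit, nd2),
               unname(predict(refit, nd2, re.form = NA)), tolerance = 1e-6)
  expect_error(predict_fixed(fit, data.frame(sqrt_sjc = 1)), "lacks")
})

test_that("test_loglik equals the closed form and the dense MVN oracle", {
  fit <- structure(list(beta = c(`(Intercept)` = 0), fixed = character(0),
                        sigma2 = 1, tau2 = 0, outcome = "y",
                        group = "id"), class = "lmm_fit")
  fit$fixed <- character(0)
  # one visit, residual 0, sigma2 = 1, tau2 = 0: -log(2*pi)/2
  d1 <- data.frame(y = 0, id = 1)
  fit1 <- fit; fit1$beta <- c(`(Intercept)` = 0)
  expect_equal(test_loglik(fit1, d1), -0.9189385, tolerance = 1e-6)

  # dense multivariate-normal oracle on clustered residuals
  v <- small_cohort(n = 60, seed = 17, clean = TRUE)$visits
  train <- v[v$patient_id %in% unique(v$patient_id)[1:40], ]
  test <- v[!v$patient_id %in% unique(v$patient_id)[1:40], ]
  f <- fit_lmm(train, c("sqrt_sjc", "ln_crp"))
  resid <- test$gspd - predict_fixed(f, test)
  expect_equal(test_loglik(f, test),
               dense_cs_loglik(resid, test$patient_id, f$sigma2, f$tau2),
               tolerance = 1e-10)
  expect_error(test_loglik(f, test[0, ]), "empty")
})

test_that("fold assignment partitions patients with balanced sizes", {
  folds <- assign_folds(sprintf("p%03d", 1:434), k = 20, seed = 2)
  expect_length(folds, 434)
  expect_true(all(table(folds) %in% c(21, 22)))
  expect_setequal(names(folds), sprintf("p%03d", 1:434))
  expect_error(assign_folds(1:10, k = 1), "at least 2")
  expect_error(assign_folds(1:10, k = 11), "more folds")
})

test_that("kfold_cv concatenates test folds and respects patient clustering", {
  v <- small_cohort(n = 60, seed = 19, clean = TRUE)$visits
  cv <- kfold_cv(v, c("sqrt_sjc", "ln_crp"), k = 5, seed = 3)
  expect_true(cv$r2 >= 0 && cv$r2 <= 1)
  expect_length(cv$folds, 60)
  # near-noiseless linear data: cross-validated R2 approaches 1
  v2 <- v
  v2$gspd <- 10 + 4 * v2$sqrt_sjc + 2 * v2$ln_crp + rnorm(nrow(v2), 0, 1e-3)
  cv2 <- kfold_cv(v2, c("sqrt_sjc", "ln_crp"), k = 5, seed = 3)
  expect_gt(cv2$r2, 0.999)
  # in-sample R2 exceeds cross-validated R2 on average over seeds
  ins <- function(d, fx) {
    f <- fit_lmm(d, fx)
    cor(d$gspd, predict_fixed(f, d))^2
  }
  diffs <- vapply(1:5, function(s) {
    d <- small_cohort(n = 50, seed = 300 + s, clean = TRUE)$visits
    ins(d, c("sqrt_sjc", "ln_crp")) -
      kfold_cv(d, c("sqrt_sjc", "ln_crp"), k = 5, seed = s)$r2
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("kfold_cv averages metrics across completed datasets", {
  v <- small_cohort(n = 50, seed = 23)$visits
  cols <- c("sqrt_tjc", "sqrt_sjc", "ln_crp", "ln_esr", "ghvas", "haq",
            "age", "sex")
  mp <- mice_pmm(v, m = 3, columns = cols, seed = 9)
  cv <- kfold_cv(mp, c("sqrt_sjc", "ln_crp"), k = 5, seed = 3)
  expect_equal(nrow(cv$per_dataset), 3)
  expect_equal(cv$r2, mean(cv$per_dataset$r2))
  expect_equal(cv$test_loglik, mean(cv$per_dataset$test_loglik))
})

test_that("model comparison yields the 2.6 evidence threshold and labels", {
  expect_equal(evidence_threshold(2, 0.01), qchisq(0.99, 2) / 2 - 2)
  expect_equal(round(evidence_threshold(2, 0.01), 1), 2.6)

  v <- small_cohort(n = 50, seed = 29, clean = TRUE)$visits
  a <- kfold_cv(v, c("sqrt_sjc", "ln_crp"), k = 5, seed = 3)
  expect_equal(compare_models(a, a)$delta, 0)
  expect_equal(compare_models(a, a)$preferred, "tie")
  b <- kfold_cv(v, c("sqrt_sjc", "ln_crp", "sqrt_tjc", "ghvas"), k = 5,
                seed = 3)
  cmp <- compare_models(a, b)
  expect_equal(cmp$delta, a$test_loglik - b$test_loglik)
  b2 <- kfold_cv(v, c("sqrt_sjc", "ln_crp"), k = 5, seed = 4)
  expect_error(compare_models(a, b2), "different fold")
})

test_that("the two-component model is preferred when TJC/GHVAS are null", {
  # scaled-down model-selection property (the full 100-seed version runs in
  # the acceptance suite): positive mean test-log-likelihood advantage
  deltas <- vapply(1:6, function(s) {
    v <- small_cohort(n = 80, seed = 400 + s, visits = c(0, 26, 52))$visits
    v <- v[complete.cases(v[c("sqrt_tjc", "sqrt_sjc", "ln_crp", "ghvas",
                              "gspd")]), ]
    folds <- assign_folds(unique(v$patient_id), 5, seed = s)
    cv2 <- kfold_cv(v, c("sqrt_sjc", "ln_crp"), folds = folds)
    cv4 <- kfold_cv(v, c("sqrt_sjc", "ln_crp", "sqrt_tjc", "ghvas"),
                    folds = folds)
    compare_models(cv2, cv4)$delta
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})
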