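#' Add transformed DAS28 component columns
#'
#' The analysis scale of each component: `sqrt_tjc = sqrt(TJC28)`,
#' `sqrt_sjc = sqrt(SJC28)`, `ln_crp = ln(CRP+1)` (after resolving censored
#' values), `ln_esr = ln(ESR)` (0 mm/h mapped to 1), `ghvas` unchanged.
#'
#' @param visits visits data.frame
#' @param crp_substitute substitute for censored CRP, mg/L
#' @return `visits` with transformed columns appended
#' @export
add_transformed_components <- function(visits, crp_substitute = 2) {
  if ("tjc28" %in% names(visits)) visits$sqrt_tjc <- sqrt(visits$tjc28)
  if ("sjc28" %in% names(visits)) visits$sqrt_sjc <- sqrt(visits$sjc28)
  if ("crp" %in% names(visits)) {
    crp <- resolve_censored_crp(visits$crp,
                                visits$crp_censored %||% rep(FALSE, nrow(visits)),
                                crp_substitute)
    visits$ln_crp <- log(crp + 1)
  }
  if ("esr" %in% names(visits)) visits$ln_esr <- ifelse(is.na(visits$esr), NA,
                                                        safe_ln_esr(visits$esr))
  visits
}

#' Fit a random-intercept linear model of GSPD on fixed terms
#'
#' Maximum-likelihood (not REML) fit via [lme4::lmer], so log-likelihoods are
#' comparable across fixed-effect specifications. The fixed terms are either
#' transformed DAS28 components (`sqrt_sjc`, `ln_crp`, ...) or a single
#' composite-score column.
#'
#' @param data completed visits table (no missing cells in modelled columns)
#' @param fixed character vector of fixed-term column names
#' @param outcome outcome column (GSPD)
#' @param group patient identifier column (random intercept)
#' @return object of class `lmm_fit`: `beta` (intercept first), `tau2`
#'   (random-intercept variance), `sigma2` (residual variance), `loglik`,
#'   `n_obs`, `n_patients`, `fixed`, `outcome`, `group`, `vcov_fixed`
#' @export
fit_lmm <- function(data, fixed, outcome = "gspd", group = "patient_id") {
  stopifnot(length(fixed) >= 1)
  need <- c(outcome, fixed, group)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (any(!complete.cases(data[need])))
    stop("modelled columns contain missing cells; impute first", call. = FALSE)
  if (length(unique(data[[group]])) <= length(fixed))
    stop("fewer patients than fixed terms", call. = FALSE)
  fml <- as.formula(paste(outcome, "~",
                          paste(sprintf("`%s`", fixed), collapse = " + "),
                          "+ (1 |", group, ")"))
  fit <- lme4::lmer(fml, data = data, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  vc <- lme4::VarCorr(fit)
  structure(list(beta = lme4::fixef(fit),
                 tau2 = as.numeric(vc[[group]][1, 1]),
                 sigma2 = attr(vc, "sc")^2,
                 loglik = as.numeric(logLik(fit)),
                 vcov_fixed = as.matrix(vcov(fit)),
                 n_obs = nrow(data),
                 n_patients = length(unique(data[[group]])),
                 fixed = fixed, outcome = outcome, group = group),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept LMM (ML):", x$outcome, "~",
      paste(x$fixed, collapse = " + "), "\n")
  print(round(x$beta, 4))
  cat(sprintf("tau2 = %.4f, sigma2 = %.4f, logLik = %.3f (%d obs, %d patients)\n",
              x$tau2, x$sigma2, x$loglik, x$n_obs, x$n_patients))
  invisible(x)
}

lmm_design <- function(fit, data) {
  miss <- setdiff(fit$fixed, names(data))
  if (length(miss)) stop("newdata lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  cbind(1, as.matrix(data[fit$fixed]))
}

#' Fixed-effects-only predictions for unseen patients
#'
#' The random intercept is set to its population mean (zero), as required
#' when predicting for patients absent from the training data.
#'
#' @param fit an [fit_lmm] object
#' @param newdata data.frame with the fixed-term columns
#' @return numeric vector of predicted GSPD
#' @export
predict_fixed <- function(fit, newdata) {
  drop(lmm_design(fit, newdata) %*% fit$beta)
}

#' Out-of-sample log-likelihood under a fitted random-intercept model
#'
#' For each test patient the residuals `r = y - X beta` are scored under a
#' multivariate Gaussian with the compound-symmetry covariance implied by the
#' random intercept, `sigma2 * I + tau2 * J`; per-patient log-densities are
#' summed. Closed form (Sherman-Morrison / matrix determinant lemma): for a
#' patient with `q` visits,
#' `logdet = (q-1) log(sigma2) + log(sigma2 + q tau2)` and
#' `r' V^-1 r = r'r / sigma2 - tau2 (sum r)^2 / (sigma2 (sigma2 + q tau2))`.
#'
#' @param fit an [fit_lmm] object
#' @param testdata visits table for patients unseen in training
#' @return total log-likelihood, natural-log units
#' @export
test_loglik <- function(fit, testdata) {
  if (nrow(testdata) == 0) stop("empty test set", call. = FALSE)
  r <- testdata[[fit$outcome]] - predict_fixed(fit, testdata)
  s2 <- fit$sigma2
  t2 <- fit$tau2
  total <- 0
  for (rr in split(r, testdata[[fit$group]])) {
    q <- length(rr)
    denom <- s2 + q * t2
    logdet <- (q - 1) * log(s2) + log(denom)
    quad <- sum(rr^2) / s2 - t2 * sum(rr)^2 / (s2 * denom)
    total <- total - 0.5 * (q * log(2 * pi) + logdet + quad)
  }
  total
}

#' Assign patients to cross-validation folds
#'
#' @param patients vector of unique patient ids
#' @param k number of folds
#' @param seed integer seed
#' @return named integer vector mapping patient id to fold
#' @export
assign_folds <- function(patients, k, seed = 1) {
  patients <- unique(patients)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > length(patients)) stop("more folds than patients", call. = FALSE)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  f <- sample(rep_len(seq_len(k), length(patients)))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  setNames(f, patients)
}

cv_one_dataset <- function(data, fixed, folds, outcome, group) {
  fold_of <- folds[as.character(data[[group]])]
  pred <- rep(NA_real_, nrow(data))
  tll <- 0
  for (f in sort(unique(folds))) {
    test <- fold_of == f
    fit <- fit_lmm(data[!test, , drop = FALSE], fixed, outcome, group)
    pred[test] <- predict_fixed(fit, data[test, , drop = FALSE])
    tll <- tll + test_loglik(fit, data[test, , drop = FALSE])
  }
  list(r2 = suppressWarnings(cor(data[[outcome]], pred))^2,
       test_loglik = tll, pred = pred)
}

#' Patient-clustered k-fold cross-validation of a GSPD model
#'
#' Patients (not visits) are partitioned into `k` folds; for each fold the
#' model is fitted on the remaining folds and the held-out patients are
#' scored by fixed-effects prediction. R-squared is the squared Pearson
#' correlation between observed and predicted GSPD over the concatenated test
#' folds; the test log-likelihood ([test_loglik]) is summed over all folds.
#' When a [mice_pmm] result (or list of data.frames) is supplied, metrics are
#' computed per completed dataset with a shared fold assignment and averaged
#' arithmetically.
#'
#' @param data visits data.frame, list of data.frames, or `completed_datasets`
#' @param fixed fixed-term column names (components or one score column)
#' @param k number of folds (default 20)
#' @param seed seed for the fold assignment
#' @param outcome,group outcome and patient-id columns
#' @param folds optional pre-computed assignment from [assign_folds]; when
#'   supplied, `k` and `seed` are taken from it
#' @return object of class `cv_report`: `r2`, `test_loglik` (averages),
#'   `per_dataset` (data.frame), `folds`, `k`, `seed`, `fixed`, `n_obs`,
#'   `n_patients`
#' @export
kfold_cv <- function(data, fixed, k = 20, seed = 1, outcome = "gspd",
                     group = "patient_id", folds = NULL) {
  datasets <- if (inherits(data, "completed_datasets")) data$datasets
              else if (is.data.frame(data)) list(data)
              else data
  stopifnot(length(datasets) >= 1, is.data.frame(datasets[[1]]))
  patients <- unique(datasets[[1]][[group]])
  if (is.null(folds)) folds <- assign_folds(patients, k, seed) else
    k <- length(unique(folds))
  if (!setequal(names(folds), as.character(patients)))
    stop("fold assignment does not cover the patients in the data",
         call. = FALSE)
  per <- lapply(datasets, cv_one_dataset, fixed = fixed, folds = folds,
                outcome = outcome, group = group)
  per_df <- data.frame(dataset = seq_along(per),
                       r2 = vapply(per, `[[`, numeric(1), "r2"),
                       test_loglik = vapply(per, `[[`, numeric(1), "test_loglik"))
  structure(list(r2 = mean(per_df$r2), test_loglik = mean(per_df$test_loglik),
                 per_dataset = per_df, folds = folds, k = k, seed = seed,
                 fixed = fixed, n_obs = nrow(datasets[[1]]),
                 n_patients = length(patients)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold patient-clustered CV of gspd ~ %s\n", x$k,
              paste(x$fixed, collapse = " + ")))
  cat(sprintf("  R2 = %.3f, test log-likelihood = %.2f (%d obs, %d patients, %d dataset(s))\n",
              x$r2, x$test_loglik, x$n_obs, x$n_patients, nrow(x$per_dataset)))
  invisible(x)
}

#' Evidence threshold on the test log-likelihood scale
#'
#' By the asymptotic equivalence of leave-one-out cross-validation and AIC,
#' a nested comparison with `extra_params` additional parameters that is
#' significant at level `p` by the likelihood-ratio test corresponds to a
#' difference in test log-likelihood of
#' `qchisq(1 - p, extra_params) / 2 - extra_params` natural-log units
#' (the AIC penalty is paid out-of-sample). For two extra parameters at
#' p = 0.01 this is 2.605, the conventional 2.6 threshold.
#'
#' @param extra_params number of extra parameters in the larger model
#' @param p two-sided significance level
#' @return threshold in natural-log units
#' @export
evidence_threshold <- function(extra_params = 2, p = 0.01) {
  qchisq(1 - p, df = extra_params) / 2 - extra_params
}

#' Compare two cross-validation reports by test log-likelihood
#'
#' @param a,b [kfold_cv] reports computed on the same data with the same folds
#' @param threshold natural-log-unit evidence threshold (default 2.6,
#'   appropriate for comparisons differing by two parameters)
#' @return list with `delta` (`a$test_loglik - b$test_loglik`), `preferred`,
#'   and `evidence` label (`"strong (P<0.01 equivalent)"` when
#'   `|delta| >= threshold`)
#' @export
compare_models <- function(a, b, threshold = 2.6) {
  stopifnot(inherits(a, "cv_report"), inherits(b, "cv_report"))
  if (!identical(a$folds, b$folds))
    stop("reports were computed with different fold assignments", call. = FALSE)
  delta <- a$test_loglik - b$test_loglik
  list(delta = delta,
       preferred = if (delta > 0) "a" else if (delta < 0) "b" else "tie",
       evidence = if (abs(delta) >= threshold) "strong (P<0.01 equivalent)"
                  else "weak")
}
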