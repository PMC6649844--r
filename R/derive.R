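#' Published two-component mixed-model coefficients of the development cohorts
#'
#' Point estimates from the published two-component random-intercept models of
#' GSPD on `sqrt(SJC28)` and an acute-phase reactant (`ln(CRP+1)` or
#' `ln(ESR)`) in the three development cohorts (IACON, IDEA, PEAC), together
#' with each cohort's total observation count and the number of observations
#' missing the acute-phase measurement. These printed values are the inputs
#' from which the final 2C score weights are recomputed.
#'
#' @return data.frame with columns `cohort`, `acute_phase`, `beta_sjc`,
#'   `beta_ap`, `n_obs`, `n_missing_ap`
#' @export
published_coefficients <- function() {
  path <- system.file("extdata", "development_model_coefficients.csv",
                      package = "das2c", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Per-cohort ratio of the SJC28 coefficient to the acute-phase coefficient
#'
#' The GSPD outcome is scaled differently in each development cohort (joint
#' sets and combination rules differ), so coefficients are not comparable
#' across cohorts — but their within-cohort ratio is. The ratio of the
#' `sqrt(SJC28)` coefficient to the acute-phase coefficient, weighted by the
#' number of observations with a non-missing acute-phase measurement, is the
#' quantity pooled across cohorts.
#'
#' @param fit an [fit_lmm] object for a two-component model, or a named
#'   numeric vector `c(sjc = ..., ap = ...)` of coefficients
#' @param n_weight observations with non-missing acute-phase measurement
#' @param cohort cohort label
#' @param sjc_term,ap_term coefficient names when `fit` is an `lmm_fit`
#' @return object of class `cohort_ratio`: `cohort`, `ratio`, `n_weight`,
#'   `beta_sjc`, `beta_ap`
#' @examples
#' coefficient_ratio(c(sjc = 30.61, ap = 15.45), 836, "IACON")  # ratio 1.98
#' @export
coefficient_ratio <- function(fit, n_weight, cohort = "",
                              sjc_term = "sqrt_sjc",
                              ap_term = c("ln_crp", "ln_esr")) {
  if (inherits(fit, "lmm_fit")) {
    ap_term <- intersect(ap_term, names(fit$beta))
    if (length(ap_term) != 1 || !sjc_term %in% names(fit$beta))
      stop("fit must contain exactly sqrt_sjc and one acute-phase term",
           call. = FALSE)
    if (length(fit$fixed) != 2)
      stop("fit is not a two-component model", call. = FALSE)
    b_sjc <- unname(fit$beta[sjc_term])
    b_ap <- unname(fit$beta[ap_term])
  } else {
    stopifnot(is.numeric(fit), all(c("sjc", "ap") %in% names(fit)))
    b_sjc <- unname(fit["sjc"])
    b_ap <- unname(fit["ap"])
  }
  if (b_ap <= 0)
    stop("acute-phase coefficient is not positive; ratio undefined for scoring",
         call. = FALSE)
  if (n_weight <= 0) stop("n_weight must be positive", call. = FALSE)
  structure(list(cohort = cohort, ratio = b_sjc / b_ap, n_weight = n_weight,
                 beta_sjc = b_sjc, beta_ap = b_ap),
            class = "cohort_ratio")
}

#' Observation-weighted combination of per-cohort coefficient ratios
#'
#' Each cohort's ratio is multiplied by its count of observations with a
#' non-missing acute-phase measurement; the products are summed and divided
#' by the total count: `sum(ratio * n) / sum(n)`.
#'
#' @param ratios list of [coefficient_ratio] objects
#' @return the combined (weighted mean) ratio
#' @export
combine_ratios <- function(ratios) {
  if (inherits(ratios, "cohort_ratio")) ratios <- list(ratios)
  stopifnot(length(ratios) >= 1,
            all(vapply(ratios, inherits, logical(1), "cohort_ratio")))
  r <- vapply(ratios, `[[`, numeric(1), "ratio")
  w <- vapply(ratios, `[[`, numeric(1), "n_weight")
  if (sum(w) <= 0) stop("total weight must be positive", call. = FALSE)
  sum(r * w) / sum(w)
}

#' Emit the final two-component score equation
#'
#' The swollen-joint term is fixed at weight 1 on the `sqrt` scale; the
#' acute-phase weight is the reciprocal of the combined ratio, rounded to 1
#' decimal place for CRP and 2 for ESR (matching the precision of the
#' published constants 0.6 and 0.32).
#'
#' @param combined_ratio combined SJC:acute-phase coefficient ratio (> 0)
#' @param acute_phase `"CRP"` or `"ESR"`
#' @param decimals rounding of the acute-phase weight; default 1 for CRP,
#'   2 for ESR
#' @param provenance optional list of [coefficient_ratio] objects recorded in
#'   the equation
#' @return object of class `score_equation`: `acute_phase`, `weight_sjc` (1),
#'   `weight_ap`, `combined_ratio`, `provenance`, `score` (a function of
#'   `(sjc28, ap_value)`), `text`
#' @export
emit_equation <- function(combined_ratio, acute_phase = c("CRP", "ESR"),
                          decimals = NULL, provenance = list()) {
  acute_phase <- match.arg(acute_phase)
  stopifnot(combined_ratio > 0)
  if (is.null(decimals)) decimals <- if (acute_phase == "CRP") 1L else 2L
  w_ap <- round_half_up(1 / combined_ratio, decimals)
  ap_text <- if (acute_phase == "CRP") "ln(CRP+1)" else "ln(ESR)"
  score <- if (acute_phase == "CRP") {
    function(sjc28, ap_value) sqrt(sjc28) + w_ap * log(ap_value + 1)
  } else {
    function(sjc28, ap_value) sqrt(sjc28) + w_ap * safe_ln_esr(ap_value)
  }
  structure(list(acute_phase = acute_phase, weight_sjc = 1,
                 weight_ap = w_ap, combined_ratio = combined_ratio,
                 provenance = provenance, score = score,
                 text = sprintf("2C-DAS28%s = sqrt(SJC28) + (%s x %s)",
                                acute_phase, format(w_ap), ap_text)),
            class = "score_equation")
}

#' @export
print.score_equation <- function(x, ...) {
  cat(x$text, "\n")
  cat(sprintf("  combined SJC:%s ratio %.4f over %d cohort(s)\n",
              x$acute_phase, x$combined_ratio, length(x$provenance)))
  for (p in x$provenance)
    cat(sprintf("    %s: ratio %.4f (n = %d)\n", p$cohort, p$ratio,
                as.integer(p$n_weight)))
  invisible(x)
}

#' Derive the two-component score equation from per-cohort fits
#'
#' Convenience wrapper: per-cohort [coefficient_ratio], [combine_ratios],
#' [emit_equation].
#'
#' @param fits named list of two-component [fit_lmm] objects (or
#'   `c(sjc=, ap=)` vectors), one per cohort
#' @param n_weights numeric vector of non-missing acute-phase observation
#'   counts, aligned with `fits`
#' @param acute_phase `"CRP"` or `"ESR"`
#' @return a `score_equation`
#' @export
derive_score_equation <- function(fits, n_weights, acute_phase = "CRP") {
  stopifnot(length(fits) == length(n_weights))
  labels <- names(fits) %||% paste0("cohort", seq_along(fits))
  ratios <- Map(function(f, w, lab) coefficient_ratio(f, w, lab),
                fits, n_weights, labels)
  emit_equation(combine_ratios(ratios), acute_phase, provenance = ratios)
}
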