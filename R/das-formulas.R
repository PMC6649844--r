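#' Resolve left-censored CRP values to a single substitute
#'
#' CRP assays commonly report a lower limit of 5 mg/L; censored observations
#' are replaced by a single substitute value (default 2 mg/L, the rounded
#' median of values imputed by robust regression on order statistics, see
#' [ros_impute] and [select_single_substitute]) before any score is computed.
#'
#' @param crp CRP in mg/L; censored entries carry the reporting threshold
#' @param censored logical vector flagging censored entries
#' @param substitute value (mg/L) substituted for censored entries, > 0
#' @return numeric vector of resolved CRP values
#' @examples
#' resolve_censored_crp(c(5, 18), c(TRUE, FALSE))        # 2, 18
#' resolve_censored_crp(5, TRUE, substitute = 1.88)      # 1.88
#' @export
resolve_censored_crp <- function(crp, censored, substitute = 2) {
  stopifnot(length(substitute) == 1L, substitute > 0)
  if (is.null(censored)) censored <- rep(FALSE, length(crp))
  stopifnot(length(crp) == length(censored))
  crp[which(censored)] <- substitute
  crp
}

check_components <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (any(is.na(x))) stop("missing ", nm, " component", call. = FALSE)
    if (nm %in% c("tjc28", "sjc28")) {
      if (any(x < 0 | x > 28)) stop(nm, " must lie in 0..28", call. = FALSE)
    } else if (nm == "ghvas") {
      if (any(x < 0 | x > 100)) stop("ghvas must lie in 0..100 mm", call. = FALSE)
    } else if (any(x < 0)) stop(nm, " must be non-negative", call. = FALSE)
  }
  invisible(TRUE)
}

# ESR = 0 is replaced by 1 mm/h before ln(), the standard DAS28 convention.
safe_ln_esr <- function(esr) log(pmax(esr, 1))

#' Conventional and re-weighted 28-joint disease activity scores
#'
#' Exact evaluation of the published composite-score formulas. Units: CRP in
#' mg/L, ESR in mm/h, GHVAS in mm (0-100). Censored CRP must be resolved
#' first ([resolve_censored_crp]).
#'
#' \describe{
#'   \item{4C-DAS28CRP}{`0.56*sqrt(TJC28) + 0.28*sqrt(SJC28) + 0.36*ln(CRP+1)
#'     + 0.014*GHVAS + 0.96`}
#'   \item{4C-DAS28ESR}{`0.56*sqrt(TJC28) + 0.28*sqrt(SJC28) + 0.70*ln(ESR)
#'     + 0.014*GHVAS`}
#'   \item{3C-DAS28CRP}{`(0.56*sqrt(TJC28) + 0.28*sqrt(SJC28) +
#'     0.36*ln(CRP+1)) * 1.10 + 1.15`}
#'   \item{2C-DAS28CRP}{`sqrt(SJC28) + 0.6*ln(CRP+1)` (re-weighted score)}
#'   \item{2C-DAS28ESR}{`sqrt(SJC28) + 0.32*ln(ESR)` (re-weighted score)}
#' }
#' ESR = 0 is replaced by 1 mm/h before taking logs.
#'
#' @param tjc28,sjc28 tender/swollen joint counts over 28 joints
#' @param crp C-reactive protein, mg/L (censoring already resolved)
#' @param esr erythrocyte sedimentation rate, mm/h
#' @param ghvas patient general health VAS, mm
#' @return numeric score
#' @examples
#' das28_4c_crp(4, 2, 6, 35)   # 3.6664
#' das28_2c_crp(2, 6)          # 2.5818
#' @export
das28_4c_crp <- function(tjc28, sjc28, crp, ghvas) {
  check_components(tjc28 = tjc28, sjc28 = sjc28, crp = crp, ghvas = ghvas)
  0.56 * sqrt(tjc28) + 0.28 * sqrt(sjc28) + 0.36 * log(crp + 1) +
    0.014 * ghvas + 0.96
}

#' @rdname das28_4c_crp
#' @export
das28_4c_esr <- function(tjc28, sjc28, esr, ghvas) {
  check_components(tjc28 = tjc28, sjc28 = sjc28, esr = esr, ghvas = ghvas)
  0.56 * sqrt(tjc28) + 0.28 * sqrt(sjc28) + 0.70 * safe_ln_esr(esr) +
    0.014 * ghvas
}

#' @rdname das28_4c_crp
#' @export
das28_3c_crp <- function(tjc28, sjc28, crp) {
  check_components(tjc28 = tjc28, sjc28 = sjc28, crp = crp)
  (0.56 * sqrt(tjc28) + 0.28 * sqrt(sjc28) + 0.36 * log(crp + 1)) * 1.10 + 1.15
}

#' @rdname das28_4c_crp
#' @export
das28_2c_crp <- function(sjc28, crp) {
  check_components(sjc28 = sjc28, crp = crp)
  sqrt(sjc28) + 0.6 * log(crp + 1)
}

#' @rdname das28_4c_crp
#' @export
das28_2c_esr <- function(sjc28, esr) {
  check_components(sjc28 = sjc28, esr = esr)
  sqrt(sjc28) + 0.32 * safe_ln_esr(esr)
}

#' Partial SDAI and CDAI (physician global VAS unavailable)
#'
#' Plain sums of components with SDAI unit conventions: CRP enters in mg/dL
#' (input mg/L is divided by 10) and GHVAS in cm (input mm divided by 10).
#'
#' @inheritParams das28_4c_crp
#' @return numeric score
#' @examples
#' partial_sdai(4, 2, 6, 35)  # 4 + 2 + 0.6 + 3.5 = 10.1
#' partial_cdai(4, 2, 35)     # 9.5
#' @export
partial_sdai <- function(tjc28, sjc28, crp, ghvas) {
  check_components(tjc28 = tjc28, sjc28 = sjc28, crp = crp, ghvas = ghvas)
  tjc28 + sjc28 + crp / 10 + ghvas / 10
}

#' @rdname partial_sdai
#' @export
partial_cdai <- function(tjc28, sjc28, ghvas) {
  check_components(tjc28 = tjc28, sjc28 = sjc28, ghvas = ghvas)
  tjc28 + sjc28 + ghvas / 10
}

#' Add composite score columns to a visits table
#'
#' Resolves censored CRP, then appends the requested score columns. Rows with
#' a missing component yield NA for the scores that need it (the strict
#' scalar formulas above raise instead).
#'
#' @param visits data.frame with columns `tjc28`, `sjc28`, `crp`,
#'   `crp_censored` (logical, optional), `esr`, `ghvas` as needed
#' @param scores character subset of `c("das28_2c_crp", "das28_2c_esr",
#'   "das28_3c_crp", "das28_4c_crp", "das28_4c_esr", "partial_sdai",
#'   "partial_cdai")`
#' @param crp_substitute substitute for censored CRP (mg/L)
#' @return `visits` with one extra numeric column per requested score
#' @export
score_visits <- function(visits,
                         scores = c("das28_2c_crp", "das28_3c_crp",
                                    "das28_4c_crp"),
                         crp_substitute = 2) {
  scores <- match.arg(scores, c("das28_2c_crp", "das28_2c_esr", "das28_3c_crp",
                                "das28_4c_crp", "das28_4c_esr", "partial_sdai",
                                "partial_cdai"),
                      several.ok = TRUE)
  crp <- if ("crp" %in% names(visits)) {
    resolve_censored_crp(visits$crp, visits$crp_censored %||%
                           rep(FALSE, nrow(visits)), crp_substitute)
  } else NULL
  needs <- list(
    das28_2c_crp = c("sjc28", "crp"),
    das28_2c_esr = c("sjc28", "esr"),
    das28_3c_crp = c("tjc28", "sjc28", "crp"),
    das28_4c_crp = c("tjc28", "sjc28", "crp", "ghvas"),
    das28_4c_esr = c("tjc28", "sjc28", "esr", "ghvas"),
    partial_sdai = c("tjc28", "sjc28", "crp", "ghvas"),
    partial_cdai = c("tjc28", "sjc28", "ghvas"))
  cols <- list(tjc28 = visits$tjc28, sjc28 = visits$sjc28, crp = crp,
               esr = visits$esr, ghvas = visits$ghvas)
  for (sc in scores) {
    req <- needs[[sc]]
    miss <- vapply(cols[req], is.null, logical(1))
    if (any(miss))
      stop("score ", sc, " needs column(s): ",
           paste(req[miss], collapse = ", "), call. = FALSE)
    ok <- Reduce(`&`, lapply(cols[req], function(x) !is.na(x)))
    val <- rep(NA_real_, nrow(visits))
    if (any(ok)) {
      args <- lapply(cols[req], function(x) x[ok])
      val[ok] <- do.call(sc, args)
    }
    visits[[sc]] <- val
  }
  visits
}
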