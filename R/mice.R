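#' Multiple imputation by chained equations with predictive mean matching
#'
#' Fills missing cells in a visits table by iterated univariate imputation.
#' Each variable with missing values is regressed (ordinary least squares) on
#' the other predictor variables using currently completed data; missing
#' cells receive the observed value of a donor drawn at random from the `k`
#' observed rows whose predicted means are closest (type-0 predictive mean
#' matching). Every imputed cell therefore belongs to the observed support of
#' its variable. The analysis outcome (GSPD) must be excluded from the
#' predictor set and rows without an observed outcome dropped beforehand.
#'
#' @param data data.frame; only `columns` participate in the imputation
#' @param m number of completed datasets (>= 2; default 20)
#' @param columns variables imputed and used as predictors of one another;
#'   defaults to every column of `data` except `exclude` that contains any
#'   missing value, plus all fully observed columns among the remainder
#' @param exclude columns never imputed nor used as predictors (identifiers
#'   and the modelling outcome)
#' @param k donor pool size for predictive mean matching
#' @param cycles chained-equation sweeps per imputation
#' @param seed integer seed; the procedure is fully reproducible
#' @return object of class `completed_datasets`: list with `datasets` (list of
#'   `m` completed data.frames), `m`, `k`, `cycles`, `seed`, `imputed_cells`
#'   (logical matrix over `columns`)
#' @export
mice_pmm <- function(data, m = 20, columns = NULL,
                     exclude = c("patient_id", "cohort", "week", "gspd"),
                     k = 5, cycles = 10, seed = 1) {
  stopifnot(is.data.frame(data))
  if (m < 2) stop("m must be at least 2 for Rubin pooling", call. = FALSE)
  if (is.null(columns)) {
    columns <- setdiff(names(data), exclude)
    columns <- columns[vapply(data[columns], is.numeric, logical(1)) |
                         vapply(data[columns], is.logical, logical(1))]
  }
  miss <- vapply(data[columns], function(x) any(is.na(x)), logical(1))
  all_miss <- vapply(data[columns], function(x) all(is.na(x)), logical(1))
  if (any(all_miss))
    stop("column(s) entirely missing: ",
         paste(columns[all_miss], collapse = ", "), call. = FALSE)
  targets <- columns[miss]

  na_mask <- as.matrix(is.na(data[columns]))
  datasets <- vector("list", m)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  for (imp in seq_len(m)) {
    work <- data
    # initial fill: random draw from the observed values of each column
    for (v in targets) {
      nas <- which(is.na(work[[v]]))
      obs <- work[[v]][!is.na(work[[v]])]
      work[[v]][nas] <- sample(obs, length(nas), replace = TRUE)
    }
    for (cyc in seq_len(cycles)) {
      for (v in targets) {
        nas <- which(na_mask[, v])
        preds <- setdiff(columns, v)
        X <- as.matrix(cbind(1, work[preds]))
        yobs_idx <- which(!na_mask[, v])
        y <- as.numeric(work[[v]])
        beta <- tryCatch(
          qr.coef(qr(X[yobs_idx, , drop = FALSE]), y[yobs_idx]),
          error = function(e) NULL)
        if (is.null(beta)) next
        beta[is.na(beta)] <- 0
        yhat <- drop(X %*% beta)
        for (i in nas) {
          d <- abs(yhat[yobs_idx] - yhat[i])
          donors <- yobs_idx[order(d, seq_along(d))[seq_len(min(k, length(d)))]]
          work[[v]][i] <- y[donors[sample.int(length(donors), 1)]]
        }
      }
    }
    datasets[[imp]] <- work
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  structure(list(datasets = datasets, m = m, k = k, cycles = cycles,
                 seed = seed, columns = columns, imputed_cells = na_mask),
            class = "completed_datasets")
}

#' @export
print.completed_datasets <- function(x, ...) {
  cat("MICE-PMM:", x$m, "completed datasets,", sum(x$imputed_cells),
      "imputed cells over", ncol(x$imputed_cells), "variables",
      sprintf("(k = %d, %d cycles, seed %d)\n", x$k, x$cycles, x$seed))
  invisible(x)
}

#' Pool estimates across multiply imputed datasets by Rubin's rules
#'
#' Pooled estimate = mean of per-imputation estimates; total variance =
#' mean within-imputation variance + (1 + 1/m) x between-imputation variance.
#' Confidence intervals use a t reference with Barnard-Rubin adjusted degrees
#' of freedom (old-style Rubin df when `dfcom = Inf`).
#'
#' @param estimates m x p matrix (or list of vectors) of per-imputation
#'   coefficient estimates
#' @param variances m x p matrix (or list) of squared standard errors
#' @param conf confidence level
#' @param dfcom complete-data residual degrees of freedom (Inf for the
#'   classical large-sample rule)
#' @return data.frame with columns `estimate`, `se`, `within`, `between`,
#'   `total_var`, `df`, `lower`, `upper`
#' @examples
#' rubin_pool(rbind(1, 2), rbind(1, 1))  # pooled 1.5, total var 1.75
#' @export
rubin_pool <- function(estimates, variances, conf = 0.95, dfcom = Inf) {
  if (is.list(estimates) && !is.data.frame(estimates))
    estimates <- do.call(rbind, estimates)
  if (is.list(variances) && !is.data.frame(variances))
    variances <- do.call(rbind, variances)
  estimates <- as.matrix(estimates)
  variances <- as.matrix(variances)
  if (!all(dim(estimates) == dim(variances)))
    stop("estimates and variances must be aligned", call. = FALSE)
  m <- nrow(estimates)
  if (m < 2) stop("pooling requires m >= 2 imputations", call. = FALSE)
  qbar <- colMeans(estimates)
  w <- colMeans(variances)
  b <- apply(estimates, 2, var)
  total <- w + (1 + 1 / m) * b
  # fraction of missing information and df
  lambda <- (1 + 1 / m) * b / total
  lambda <- pmin(pmax(lambda, 1e-12), 1 - 1e-12)
  df_old <- (m - 1) / lambda^2
  df <- if (is.finite(dfcom)) {
    df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
    df_old * df_obs / (df_old + df_obs)
  } else df_old
  half <- qt(1 - (1 - conf) / 2, df) * sqrt(total)
  out <- data.frame(estimate = qbar, se = sqrt(total), within = w, between = b,
                    total_var = total, df = df,
                    lower = qbar - half, upper = qbar + half)
  rownames(out) <- colnames(estimates)
  out
}
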