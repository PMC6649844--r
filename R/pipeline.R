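#' Build and validate a pipeline run configuration
#'
#' A run configuration is a plain list; `run_config()` fills defaults and
#' validates before any stage executes. A YAML file with the same field names
#' can be loaded via [read_run_config].
#'
#' @param seed master seed; stage-level seeds are derived from it
#' @param specs development cohort specifications ([default_cohort_specs])
#' @param truth [truth_record] for GSPD generation (its seed is overridden by
#'   `seed`)
#' @param radiograph_truth_ [radiograph_truth] for the validation cohort
#' @param validation_spec [cohort_spec] for the validation cohort
#' @param k cross-validation folds (>= 2)
#' @param m multiple imputations (>= 2)
#' @param crp_substitute single substitute for censored CRP, mg/L; `NULL` to
#'   re-derive it from the largest cohort by ROS at run time
#' @param stages subset of `c("simulate", "score", "impute", "derive",
#'   "validate")`, executed in dependency order
#' @return validated config list of class `run_config`
#' @export
run_config <- function(seed = 1, specs = default_cohort_specs(),
                       truth = truth_record(),
                       radiograph_truth_ = radiograph_truth(),
                       validation_spec = validation_cohort_spec(),
                       k = 20, m = 20, crp_substitute = 2,
                       stages = c("simulate", "score", "impute", "derive",
                                  "validate")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (k < 2) stop("config invalid: k must be at least 2", call. = FALSE)
  if (m < 2) stop("config invalid: m must be at least 2", call. = FALSE)
  if (!is.null(crp_substitute) && crp_substitute <= 0)
    stop("config invalid: crp_substitute must be positive", call. = FALSE)
  min_pat <- min(vapply(specs, `[[`, integer(1), "n_patients"))
  if (k > min_pat)
    stop("config invalid: k exceeds the smallest cohort size", call. = FALSE)
  truth$seed <- as.integer(seed)
  radiograph_truth_$seed <- as.integer(seed) + 1L
  structure(list(seed = as.integer(seed), specs = specs, truth = truth,
                 radiograph_truth = radiograph_truth_,
                 validation_spec = validation_spec, k = k, m = m,
                 crp_substitute = crp_substitute, stages = stages),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognised fields: `seed`, `k`, `m`, `crp_substitute`, `stages`,
#' `n_patients` (named map of cohort size overrides), `n_validation_patients`,
#' plus `truth` / `radiograph_truth` maps overriding individual ground-truth
#' parameters. Unspecified fields take [run_config] defaults.
#'
#' @param path YAML file
#' @return validated `run_config`
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configs", call. = FALSE)
  raw <- yaml::yaml.load_file(path)
  specs <- default_cohort_specs(n_patients = unlist(raw$n_patients))
  truth <- do.call(truth_record, raw$truth %||% list())
  rt <- do.call(radiograph_truth, raw$radiograph_truth %||% list())
  vspec <- validation_cohort_spec(raw$n_validation_patients %||% 717)
  args <- list(specs = specs, truth = truth, radiograph_truth_ = rt,
               validation_spec = vspec)
  for (f in c("seed", "k", "m", "crp_substitute", "stages"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  do.call(run_config, args)
}

write_csv6 <- function(x, path) {
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], signif, digits = 6)
  write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
}

#' Run the full derivation/validation pipeline
#'
#' Executes the requested stages in dependency order into `outdir`:
#' \describe{
#'   \item{simulate}{generate development cohorts (`visits_<cohort>.csv`,
#'     `ultrasound_<cohort>.csv`, `truth.json`) and, when the validate stage
#'     is requested, the radiographic cohort (`radiographs.csv`).}
#'   \item{score}{reduce ultrasound tables to per-visit GSPD (`gspd_<cohort>.csv`),
#'     verify agreement with the generator, and append composite score columns
#'     (`scored_<cohort>.csv`). The censored-CRP substitute is re-derived by
#'     ROS on the largest cohort unless fixed in the config.}
#'   \item{impute}{MICE-PMM per cohort; `completed_<cohort>_<i>.csv` and
#'     `imputation_log.json`.}
#'   \item{derive}{per-cohort two-component mixed models pooled over
#'     imputations (Rubin), observation-weighted ratio combination,
#'     `score_equation.json`; cross-validated model comparison shaped like the
#'     published model-comparison table, `cv_report.csv`.}
#'   \item{validate}{GEE (erosions, QIC) and random-intercept log-link models
#'     (Larsen, AIC/BIC) for component and score models,
#'     `validation_report.csv`.}
#' }
#' A `manifest.json` with input hashes, seeds and versions is written last;
#' rerunning the same config reproduces identical hashes.
#'
#' @param config a [run_config] (or list accepted by it)
#' @param outdir output directory, created if needed
#' @param quiet suppress progress messages
#' @return invisibly, the manifest as a list
#' @export
run_pipeline <- function(config = run_config(), outdir = tempfile("das2c_run_"),
                         quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  paths <- character(0)
  add <- function(p) paths <<- c(paths, p)
  stages <- config$stages
  cohorts <- NULL

  if ("simulate" %in% stages) stage("simulate", {
    say("stage simulate")
    cohorts <- generate_development_cohorts(config$specs, config$truth)
    for (nm in names(cohorts)) {
      write_csv6(cohorts[[nm]]$visits, f1 <- file.path(outdir, paste0("visits_", nm, ".csv")))
      write_csv6(cohorts[[nm]]$ultrasound, f2 <- file.path(outdir, paste0("ultrasound_", nm, ".csv")))
      add(f1); add(f2)
    }
    truth_out <- config$truth
    jsonlite::write_json(truth_out[names(truth_out)],
                         tj <- file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    add(tj)
    if ("validate" %in% stages) {
      rads <- generate_validation_cohort(config$validation_spec,
                                         config$radiograph_truth)
      write_csv6(as.data.frame(rads), rf <- file.path(outdir, "radiographs.csv"))
      add(rf)
    }
  })

  load_cohorts <- function() {
    lapply(setNames(nm = names(config$specs)), function(nm) {
      list(visits = read.csv(file.path(outdir, paste0("visits_", nm, ".csv"))),
           ultrasound = read.csv(file.path(outdir, paste0("ultrasound_", nm, ".csv"))))
    })
  }

  crp_substitute <- config$crp_substitute
  scored <- NULL
  if ("score" %in% stages) stage("score", {
    say("stage score")
    cohorts <- load_cohorts()
    if (is.null(crp_substitute)) {
      big <- which.max(vapply(cohorts, function(x) nrow(x$visits), numeric(1)))
      v <- cohorts[[big]]$visits
      ok <- !is.na(v$crp)
      ros <- ros_impute(v$crp[ok], v$crp_censored[ok],
                        config$specs[[big]]$crp_censor_threshold)
      crp_substitute <- select_single_substitute(ros)
      say("  derived censored-CRP substitute: ", crp_substitute, " mg/L")
    }
    for (nm in names(cohorts)) {
      g <- gspd_table(cohorts[[nm]]$ultrasound,
                      method = config$specs[[nm]]$gspd_method)
      write_csv6(g, gf <- file.path(outdir, paste0("gspd_", nm, ".csv")))
      add(gf)
      v <- merge(cohorts[[nm]]$visits, g[c("patient_id", "week", "gspd")],
                 by = c("patient_id", "week"), suffixes = c("", "_us"))
      if (!all(v$gspd == v$gspd_us))
        stop("recombined GSPD does not match the generator totals")
      v$gspd_us <- NULL
      v <- score_visits(v, c("das28_2c_crp", "das28_2c_esr", "das28_3c_crp",
                             "das28_4c_crp", "das28_4c_esr", "partial_sdai",
                             "partial_cdai"),
                        crp_substitute = crp_substitute)
      v <- add_transformed_components(v, crp_substitute)
      write_csv6(v, sf <- file.path(outdir, paste0("scored_", nm, ".csv")))
      add(sf)
    }
  })

  load_scored <- function() lapply(setNames(nm = names(config$specs)),
    function(nm) read.csv(file.path(outdir, paste0("scored_", nm, ".csv"))))

  if ("impute" %in% stages) stage("impute", {
    say("stage impute")
    scored <- load_scored()
    for (nm in names(scored)) {
      comp <- mice_pmm(scored[[nm]], m = config$m,
                       columns = intersect(c("sqrt_tjc", "sqrt_sjc", "ln_crp",
                                             "ln_esr", "ghvas", "haq", "age",
                                             "sex"), names(scored[[nm]])),
                       seed = config$seed + 100L + match(nm, names(scored)))
      for (i in seq_len(config$m)) {
        write_csv6(comp$datasets[[i]],
                   cf <- file.path(outdir, sprintf("completed_%s_%d.csv", nm, i)))
        add(cf)
      }
    }
    jsonlite::write_json(list(seed = config$seed, m = config$m, donor_k = 5,
                              cycles = 10),
                         il <- file.path(outdir, "imputation_log.json"),
                         auto_unbox = TRUE)
    add(il)
  })

  load_completed <- function(nm) {
    files <- file.path(outdir, sprintf("completed_%s_%d.csv", nm,
                                       seq_len(config$m)))
    if (!all(file.exists(files))) return(NULL)
    lapply(files, read.csv)
  }

  if ("derive" %in% stages) stage("derive", {
    say("stage derive")
    scored <- load_scored()
    fits <- list(); n_w <- numeric(0)
    for (nm in names(scored)) {
      completed <- load_completed(nm) %||% list(
        scored[[nm]][complete.cases(scored[[nm]][c("sqrt_sjc", "ln_crp", "gspd")]), ])
      per <- lapply(completed, fit_lmm, fixed = c("sqrt_sjc", "ln_crp"))
      if (length(per) >= 2) {
        est <- do.call(rbind, lapply(per, function(f) f$beta[c("sqrt_sjc", "ln_crp")]))
        vr <- do.call(rbind, lapply(per, function(f)
          diag(f$vcov_fixed)[c("sqrt_sjc", "ln_crp")]))
        pooled <- rubin_pool(est, vr)
        fit_nm <- c(sjc = pooled["sqrt_sjc", "estimate"],
                    ap = pooled["ln_crp", "estimate"])
      } else {
        fit_nm <- c(sjc = unname(per[[1]]$beta["sqrt_sjc"]),
                    ap = unname(per[[1]]$beta["ln_crp"]))
      }
      fits[[nm]] <- fit_nm
      n_w[nm] <- sum(!is.na(scored[[nm]]$crp))
    }
    eq <- derive_score_equation(fits, n_w, "CRP")
    say("  ", eq$text)
    prov <- lapply(eq$provenance, function(p)
      list(cohort = p$cohort, ratio = p$ratio, n_weight = p$n_weight))
    jsonlite::write_json(
      list(acute_phase = eq$acute_phase, weight_sjc = eq$weight_sjc,
           weight_ap = eq$weight_ap, combined_ratio = eq$combined_ratio,
           provenance = prov, seed = config$seed,
           package_version = as.character(utils::packageVersion("das2c")),
           r_version = as.character(getRversion())),
      ef <- file.path(outdir, "score_equation.json"),
      auto_unbox = TRUE, digits = NA)
    add(ef)

    # cross-validated model comparison per cohort
    model_list <- list(
      `ln(CRP) + sqrt(SJC28)` = c("ln_crp", "sqrt_sjc"),
      `ln(CRP) + sqrt(SJC28) + sqrt(TJC28) + GHVAS` =
        c("ln_crp", "sqrt_sjc", "sqrt_tjc", "ghvas"),
      `Re-weighted 2C-DAS28CRP` = "das28_2c_crp",
      `Conventional 3C-DAS28CRP` = "das28_3c_crp",
      `Conventional 4C-DAS28CRP` = "das28_4c_crp")
    rows <- list()
    for (nm in names(scored)) {
      completed <- load_completed(nm)
      data_nm <- if (!is.null(completed)) {
        lapply(completed, function(d)
          score_visits(d, c("das28_2c_crp", "das28_3c_crp", "das28_4c_crp"),
                       crp_substitute %||% 2))
      } else {
        cc <- scored[[nm]][complete.cases(
          scored[[nm]][c("sqrt_tjc", "sqrt_sjc", "ln_crp", "ghvas", "gspd")]), ]
        list(cc)
      }
      # scores on completed data: components were imputed, so recompute
      data_nm <- lapply(data_nm, function(d) {
        d$das28_2c_crp <- d$sqrt_sjc + 0.6 * d$ln_crp
        d$das28_3c_crp <- (0.56 * d$sqrt_tjc + 0.28 * d$sqrt_sjc +
                             0.36 * d$ln_crp) * 1.10 + 1.15
        d$das28_4c_crp <- 0.56 * d$sqrt_tjc + 0.28 * d$sqrt_sjc +
          0.36 * d$ln_crp + 0.014 * d$ghvas + 0.96
        d
      })
      folds <- assign_folds(unique(data_nm[[1]]$patient_id), config$k,
                            seed = config$seed + 200L)
      reports <- lapply(model_list, function(fx)
        kfold_cv(data_nm, fx, folds = folds))
      best <- max(vapply(reports, `[[`, numeric(1), "test_loglik"))
      for (mn in names(reports))
        rows[[length(rows) + 1L]] <- data.frame(
          cohort = nm, model = mn, r2 = reports[[mn]]$r2,
          delta_test_loglik = reports[[mn]]$test_loglik - best)
    }
    write_csv6(do.call(rbind, rows), cvf <- file.path(outdir, "cv_report.csv"))
    add(cvf)
  })

  if ("validate" %in% stages) stage("validate", {
    say("stage validate")
    rads <- read.csv(file.path(outdir, "radiographs.csv"))
    rads <- add_transformed_components(rads, crp_substitute %||% 2)
    rads$das28_2c_crp <- rads$sqrt_sjc + 0.6 * rads$ln_crp
    rads$das28_3c_crp <- (0.56 * rads$sqrt_tjc + 0.28 * rads$sqrt_sjc +
                            0.36 * rads$ln_crp) * 1.10 + 1.15
    rows <- list()
    comp_preds <- c("sqrt_tjc", "sqrt_sjc", "ln_crp")
    gee_multi <- fit_gee_erosion(rads, comp_preds)
    for (p in comp_preds) {
      uni <- fit_gee_erosion(rads, p)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = "erosion", model = "univariable", term = p,
        estimate = uni$coefficients[p, "estimate"],
        lower = uni$coefficients[p, "lower"],
        upper = uni$coefficients[p, "upper"],
        p_value = uni$coefficients[p, "p_value"],
        aic = NA, bic = NA, qic = NA)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = "erosion", model = "multivariable", term = p,
        estimate = gee_multi$coefficients[p, "estimate"],
        lower = gee_multi$coefficients[p, "lower"],
        upper = gee_multi$coefficients[p, "upper"],
        p_value = gee_multi$coefficients[p, "p_value"],
        aic = NA, bic = NA, qic = NA)
    }
    for (sc in c("das28_2c_crp", "das28_3c_crp")) {
      g <- fit_gee_erosion(rads, sc)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = "erosion", model = "score", term = sc,
        estimate = g$coefficients[sc, "estimate"],
        lower = g$coefficients[sc, "lower"], upper = g$coefficients[sc, "upper"],
        p_value = g$coefficients[sc, "p_value"],
        aic = NA, bic = NA, qic = qic(g)$qic)
      l <- fit_larsen_longitudinal(rads, sc)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = "larsen", model = "score", term = sc,
        estimate = l$coefficients[sc, "estimate"],
        lower = l$coefficients[sc, "lower"], upper = l$coefficients[sc, "upper"],
        p_value = l$coefficients[sc, "p_value"],
        aic = l$aic, bic = l$bic, qic = NA)
    }
    larsen_multi <- fit_larsen_longitudinal(rads, comp_preds)
    for (p in comp_preds)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = "larsen", model = "multivariable", term = p,
        estimate = larsen_multi$coefficients[p, "estimate"],
        lower = larsen_multi$coefficients[p, "lower"],
        upper = larsen_multi$coefficients[p, "upper"],
        p_value = larsen_multi$coefficients[p, "p_value"],
        aic = larsen_multi$aic, bic = larsen_multi$bic, qic = NA)
    write_csv6(do.call(rbind, rows),
               vf <- file.path(outdir, "validation_report.csv"))
    add(vf)
  })

  manifest <- list(
    seed = config$seed, k = config$k, m = config$m,
    crp_substitute = crp_substitute,
    stages = stages,
    package_version = as.character(utils::packageVersion("das2c")),
    r_version = as.character(getRversion()),
    files = as.list(tools::md5sum(sort(unique(paths)))))
  names(manifest$files) <- basename(sort(unique(paths)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("wrote ", length(manifest$files), " files to ", outdir)
  invisible(manifest)
}
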