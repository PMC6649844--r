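#' Specify a synthetic cohort
#'
#' Describes one cohort's size, visit schedule, ultrasound convention and
#' component distributions on the analysis (transformed) scales: joint counts
#' are generated as rounded squares of a truncated Gaussian on the sqrt
#' scale (clipped to 0-28), CRP and ESR are lognormal, GHVAS is a truncated
#' Gaussian on 0-100 mm. Missingness is missing-at-random given age and
#' HAQ-DI. Defaults for the three development cohorts are provided by
#' [default_cohort_specs].
#'
#' @param name cohort label
#' @param n_patients number of patients (> 0)
#' @param visit_weeks strictly increasing visit times, weeks
#' @param gspd_method `"composite22"` or `"sum10"` (see [gspd_total])
#' @param gs_scale_max maximum GS/PD grade, 3 or 4
#' @param component_distributions named list of `c(location, scale)` pairs on
#'   the transformed scales: `tjc`, `sjc` (sqrt scale), `crp`, `esr`
#'   (meanlog/sdlog), `ghvas` (mm), `haq`, `age` (raw); plus `sex_female`
#'   (single probability)
#' @param missingness_rates named vector of marginal missingness
#'   probabilities for `tjc28`, `sjc28`, `ghvas`, `esr`, `crp` (in `[0, 1]`)
#' @param crp_censor_threshold left-censoring threshold for CRP, mg/L
#'   (0 disables censoring)
#' @param tjc_sjc_cor correlation of tender and swollen joint counts on the
#'   sqrt scale (the study does not report it; exposed as a parameter)
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(name, n_patients, visit_weeks,
                        gspd_method = c("composite22", "sum10"),
                        gs_scale_max = if (gspd_method == "sum10") 4L else 3L,
                        component_distributions = NULL,
                        missingness_rates = c(tjc28 = 0, sjc28 = 0, ghvas = 0,
                                              esr = 0, crp = 0),
                        crp_censor_threshold = 5,
                        tjc_sjc_cor = 0.5) {
  gspd_method <- match.arg(gspd_method)
  if (n_patients <= 0) stop("n_patients must be positive", call. = FALSE)
  if (length(visit_weeks) == 0) stop("visit schedule is empty", call. = FALSE)
  if (is.unsorted(visit_weeks, strictly = TRUE))
    stop("visit_weeks must be strictly increasing", call. = FALSE)
  if (!gs_scale_max %in% c(3L, 4L)) stop("gs_scale_max must be 3 or 4",
                                         call. = FALSE)
  if (any(missingness_rates < 0 | missingness_rates > 1))
    stop("missingness_rates must lie in [0, 1]", call. = FALSE)
  if (abs(tjc_sjc_cor) >= 1) stop("tjc_sjc_cor must lie in (-1, 1)",
                                  call. = FALSE)
  cd <- component_distributions %||% list(
    tjc = c(2.0, 1.4), sjc = c(1.4, 1.2), crp = c(log(6), 1.63),
    esr = c(log(23), 0.9), ghvas = c(35, 28), haq = c(1.0, 0.7),
    age = c(56, 15), sex_female = 0.70)
  structure(list(name = name, n_patients = as.integer(n_patients),
                 visit_weeks = visit_weeks, gspd_method = gspd_method,
                 gs_scale_max = as.integer(gs_scale_max),
                 joint_set = if (gspd_method == "sum10") joint_set_sum10()
                             else joint_set_composite22(),
                 component_distributions = cd,
                 missingness_rates = missingness_rates,
                 crp_censor_threshold = crp_censor_threshold,
                 tjc_sjc_cor = tjc_sjc_cor),
            class = "cohort_spec")
}

#' Default development-cohort specifications
#'
#' Three cohorts emulating the development data structure: an IACON-like
#' observational cohort (434 patients at 0/26/52/104 weeks, composite 22-joint
#' GSPD on 0-3 grades), an IDEA-like trial (59 patients at 0/52/78 weeks,
#' same convention) and a PEAC-like cohort (117 patients at 0/26 weeks,
#' plain-summed 10-joint GSPD on 0-4 grades). Component distributions are
#' calibrated to the published baseline medians and quartiles; marginal
#' missingness and censoring rates match the published data-availability
#' counts.
#'
#' @param n_patients optional named vector overriding cohort sizes, e.g.
#'   `c(IACON = 100)`
#' @return named list of [cohort_spec] objects
#' @export
default_cohort_specs <- function(n_patients = NULL) {
  specs <- list(
    IACON = cohort_spec(
      "IACON", 434, c(0, 26, 52, 104), "composite22",
      component_distributions = list(
        tjc = c(2.0, 1.4), sjc = c(1.4, 1.2), crp = c(log(6), 1.63),
        esr = c(log(23), 0.9), ghvas = c(35, 28), haq = c(1.0, 0.7),
        age = c(56, 15), sex_female = 0.70),
      missingness_rates = c(tjc28 = 3 / 889, sjc28 = 3 / 889,
                            ghvas = 59 / 889, esr = 159 / 889,
                            crp = 53 / 889)),
    IDEA = cohort_spec(
      "IDEA", 59, c(0, 52, 78), "composite22",
      component_distributions = list(
        tjc = c(3.8, 1.4), sjc = c(2.7, 1.3), crp = c(log(21), 1.2),
        esr = c(log(37), 0.85), ghvas = c(53, 24), haq = c(1.3, 0.7),
        age = c(51, 12), sex_female = 0.72),
      missingness_rates = c(tjc28 = 0, sjc28 = 0, ghvas = 0,
                            esr = 10 / 163, crp = 9 / 163)),
    PEAC = cohort_spec(
      "PEAC", 117, c(0, 26), "sum10",
      component_distributions = list(
        tjc = c(3.1, 1.4), sjc = c(2.2, 1.1), crp = c(log(7), 1.5),
        esr = c(log(30), 0.85), ghvas = c(66, 22), haq = c(1.2, 0.7),
        age = c(51, 16), sex_female = 0.68),
      missingness_rates = c(tjc28 = 22 / 183, sjc28 = 2 / 183,
                            ghvas = 2 / 183, esr = 3 / 183, crp = 5 / 183)))
  if (!is.null(n_patients))
    for (nm in names(n_patients))
      specs[[nm]]$n_patients <- as.integer(n_patients[[nm]])
  specs
}

#' Ground truth for the GSPD-generating model
#'
#' Coefficients of the latent linear model from which GSPD is realized:
#' `gspd = intercept + beta_sjc*sqrt(SJC28) + beta_crp*ln(CRP+1) +
#' beta_tjc*sqrt(TJC28) + beta_ghvas*GHVAS + b_i + e`, with patient random
#' intercept variance `tau2` and residual variance `sigma2`. The defaults
#' encode the study's central structural claim — tender joints and patient
#' global VAS carry no independent association with ultrasound synovitis
#' (`beta_tjc = beta_ghvas = 0`) — on a scale that fits the 22-joint
#' composite GSPD grid.
#'
#' @param beta_sjc,beta_crp,beta_tjc,beta_ghvas fixed effects, GSPD units per
#'   transformed-component unit
#' @param intercept GSPD units
#' @param tau2 random-intercept variance (>= 0)
#' @param sigma2 residual variance (> 0)
#' @param seed integer seed
#' @return object of class `truth_record`
#' @export
truth_record <- function(beta_sjc = 4, beta_crp = 2.5, beta_tjc = 0,
                         beta_ghvas = 0, intercept = 12, tau2 = 9,
                         sigma2 = 9, seed = 1L) {
  if (tau2 < 0 || sigma2 <= 0) stop("tau2 >= 0 and sigma2 > 0 required",
                                    call. = FALSE)
  if (beta_crp == 0 || !is.finite(beta_sjc / beta_crp))
    stop("the implied SJC:CRP ratio must be finite", call. = FALSE)
  structure(list(beta_sjc = beta_sjc, beta_crp = beta_crp, beta_tjc = beta_tjc,
                 beta_ghvas = beta_ghvas, intercept = intercept, tau2 = tau2,
                 sigma2 = sigma2, seed = as.integer(seed)),
            class = "truth_record")
}

#' Ground truth for the radiographic validation generator
#'
#' Effects on the latent damage scale (log of the annual Larsen increment
#' rate and the erosion log-odds). The default sign pattern encodes the
#' validation finding: swollen joints and CRP positively, tender joints
#' non-positively, associated with radiographic damage.
#'
#' @param gamma_sjc,gamma_crp effects per transformed-component unit (> 0)
#' @param gamma_tjc effect (<= 0)
#' @param baseline_larsen expected 10-year Larsen accrual for a null patient
#'   (non-negative)
#' @param erosion_intercept erosion log-odds at zero covariates
#' @param subject_sd SD of the shared patient random intercept (>= 0)
#' @param seed integer seed
#' @return object of class `radiograph_truth`
#' @export
radiograph_truth <- function(gamma_sjc = 0.35, gamma_crp = 0.3,
                             gamma_tjc = -0.2, baseline_larsen = 5,
                             erosion_intercept = -2, subject_sd = 0.7,
                             seed = 1L) {
  if (gamma_sjc <= 0 || gamma_crp <= 0)
    stop("gamma_sjc and gamma_crp must be positive", call. = FALSE)
  if (gamma_tjc > 0) stop("gamma_tjc must be non-positive", call. = FALSE)
  if (baseline_larsen < 0 || subject_sd < 0)
    stop("baseline_larsen and subject_sd must be non-negative", call. = FALSE)
  structure(list(gamma_sjc = gamma_sjc, gamma_crp = gamma_crp,
                 gamma_tjc = gamma_tjc, baseline_larsen = baseline_larsen,
                 erosion_intercept = erosion_intercept,
                 subject_sd = subject_sd, seed = as.integer(seed)),
            class = "radiograph_truth")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

# rounded-square of a sqrt-scale Gaussian, clipped to the 0-28 joint grid
draw_joint_count <- function(z) pmin(pmax(round(z^2 * sign(z)), 0L), 28L)

draw_components <- function(spec, n) {
  cd <- spec$component_distributions
  rho <- spec$tjc_sjc_cor
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  data.frame(
    tjc28 = draw_joint_count(cd$tjc[1] + cd$tjc[2] * z1),
    sjc28 = draw_joint_count(cd$sjc[1] + cd$sjc[2] * z2),
    crp = rlnorm(n, cd$crp[1], cd$crp[2]),
    esr = pmax(round(rlnorm(n, cd$esr[1], cd$esr[2])), 1),
    ghvas = round(rtrunc_norm(n, cd$ghvas[1], cd$ghvas[2], 0, 100)))
}

# spread an integer GSPD total over the cohort's joint grid (greedy);
# only the total enters the analysis, so the arrangement is arbitrary
decompose_gspd <- function(total, joints, method, scale_max) {
  per_joint_max <- if (method == "sum10") 2L * scale_max else scale_max
  grid_max <- length(joints) * per_joint_max
  if (total > grid_max)
    stop("GSPD total ", total, " not representable on the ", method,
         " joint grid (max ", grid_max, ")", call. = FALSE)
  alloc <- integer(length(joints))
  rem <- total
  i <- 1L
  while (rem > 0L) {
    take <- min(per_joint_max, rem)
    alloc[i] <- take
    rem <- rem - take
    i <- i + 1L
  }
  if (method == "sum10") {
    gs <- pmin(alloc, scale_max)
    pd <- alloc - gs
  } else {
    gs <- alloc
    pd <- ifelse(alloc > 0L,
                 vapply(alloc, function(a) sample.int(a + 1L, 1L) - 1L,
                        integer(1)),
                 0L)
  }
  data.frame(joint = joints, gs = as.integer(gs), pd = as.integer(pd),
             stringsAsFactors = FALSE)
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

generate_one_cohort <- function(spec, truth, include_ultrasound = TRUE) {
  n <- spec$n_patients
  weeks <- spec$visit_weeks
  v <- length(weeks)
  nv <- n * v
  pid <- sprintf("%s_%04d", spec$name, rep(seq_len(n), each = v))
  cd <- spec$component_distributions

  comps <- draw_components(spec, nv)
  age <- rep(round(rtrunc_norm(n, cd$age[1], cd$age[2], 18, 95)), each = v)
  sex <- rep(rbinom(n, 1, cd$sex_female), each = v)
  haq <- round(rep(rtrunc_norm(n, cd$haq[1], cd$haq[2], 0, 3), each = v) +
                 rnorm(nv, 0, 0.15), 3)
  haq <- pmin(pmax(haq, 0), 3)

  b <- rep(rnorm(n, 0, sqrt(truth$tau2)), each = v)
  latent <- truth$intercept +
    truth$beta_sjc * sqrt(comps$sjc28) +
    truth$beta_crp * log(comps$crp + 1) +
    truth$beta_tjc * sqrt(comps$tjc28) +
    truth$beta_ghvas * comps$ghvas +
    b + rnorm(nv, 0, sqrt(truth$sigma2))
  gspd <- round(latent)
  n_clamped <- sum(gspd < 0)
  gspd[gspd < 0] <- 0L   # latent scale left-censored at the empty-joint grid

  visits <- data.frame(
    patient_id = pid, cohort = spec$name,
    week = rep(weeks, times = n),
    tjc28 = comps$tjc28, sjc28 = comps$sjc28,
    crp = round(comps$crp, 1), crp_censored = FALSE,
    esr = comps$esr, ghvas = comps$ghvas,
    haq = haq, age = age, sex = sex,
    gspd = as.integer(gspd), stringsAsFactors = FALSE)

  # left-censor CRP at the reporting threshold
  if (spec$crp_censor_threshold > 0) {
    cen <- visits$crp < spec$crp_censor_threshold
    visits$crp[cen] <- spec$crp_censor_threshold
    visits$crp_censored <- cen
  }

  # MAR missingness given age and HAQ-DI, applied after outcome generation
  zage <- zscore(visits$age)
  zhaq <- zscore(visits$haq)
  for (comp in names(spec$missingness_rates)) {
    rate <- spec$missingness_rates[[comp]]
    if (rate <= 0) next
    p <- plogis(qlogis(rate) + 0.4 * zage + 0.4 * zhaq)
    p <- p * rate / mean(p)    # recalibrate the marginal rate
    drop_ix <- which(runif(nv) < pmin(p, 1))
    visits[[comp]][drop_ix] <- NA
    if (comp == "crp") visits$crp_censored[drop_ix] <- NA
  }
  # ultrasound decomposition last, so its RNG use cannot perturb the
  # visits table when include_ultrasound = FALSE
  us <- NULL
  if (include_ultrasound) {
    us <- do.call(rbind, lapply(seq_len(nv), function(i) {
      d <- decompose_gspd(gspd[i], spec$joint_set, spec$gspd_method,
                          spec$gs_scale_max)
      cbind(patient_id = pid[i], week = weeks[((i - 1L) %% v) + 1L], d)
    }))
    rownames(us) <- NULL
  } else {
    grid_max <- length(spec$joint_set) *
      (if (spec$gspd_method == "sum10") 2L else 1L) * spec$gs_scale_max
    if (any(gspd > grid_max))
      stop("GSPD total ", max(gspd), " not representable on the ",
           spec$gspd_method, " joint grid (max ", grid_max, ")", call. = FALSE)
  }
  list(visits = visits, ultrasound = us, n_clamped = n_clamped)
}

#' Generate synthetic development cohorts with recorded ground truth
#'
#' Draws per-visit clinical components on their transformed scales, realizes
#' GSPD from the latent linear model in `truth` (shared across cohorts), and
#' decomposes each integer GSPD total into joint-level GS/PD grades whose
#' recombined total equals the realized value exactly. CRP is left-censored
#' at the cohort threshold and component missingness is applied after
#' outcome generation (MAR given age and HAQ-DI). Deterministic given
#' `truth$seed`.
#'
#' Latent GSPD values that round below zero are set to 0 (left-censoring at
#' the empty-joint grid; under the defaults this affects of the order of 0.1%
#' of visits — the per-cohort count is reported in the `n_clamped`
#' attribute). Totals exceeding the joint-grid maximum raise an error.
#'
#' @param specs list of [cohort_spec] objects (default [default_cohort_specs])
#' @param truth a [truth_record]
#' @param include_ultrasound emit the joint-level ultrasound table (set FALSE
#'   in simulation loops that only use the GSPD total, for speed; the `gspd`
#'   column is identical either way)
#' @return named list per cohort, each with `visits` and `ultrasound`
#'   data.frames; attributes `truth` and `n_clamped`
#' @export
generate_development_cohorts <- function(specs = default_cohort_specs(),
                                         truth = truth_record(),
                                         include_ultrasound = TRUE) {
  stopifnot(all(vapply(specs, inherits, logical(1), "cohort_spec")),
            inherits(truth, "truth_record"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(truth$seed)
  out <- lapply(specs, generate_one_cohort, truth = truth,
                include_ultrasound = include_ultrasound)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  names(out) <- vapply(specs, `[[`, character(1), "name")
  structure(lapply(out, function(x) x[c("visits", "ultrasound")]),
            truth = truth,
            n_clamped = vapply(out, `[[`, integer(1), "n_clamped"))
}

#' Generate a synthetic radiographic validation cohort
#'
#' Emulates a primary-care inception cohort followed radiographically for 10
#' years: per-visit joint counts and CRP, monotone non-decreasing Larsen
#' totals accrued as Poisson increments whose log-rate is
#' `log(baseline_larsen / follow-up years) + gamma_sjc*sqrt(SJC28) +
#' gamma_crp*ln(CRP+1) + gamma_tjc*sqrt(TJC28) + b_i`, and erosion presence
#' drawn from a logistic model with the same linear predictor structure and
#' shared patient intercept `b_i ~ N(0, subject_sd^2)`.
#'
#' @param spec a [cohort_spec] whose `visit_weeks` field is interpreted as
#'   visit times in years (default: 717 patients at 0/3/5/10 years)
#' @param truth a [radiograph_truth]
#' @return data.frame of class `radiograph_table`: `patient_id`, `years`,
#'   `larsen`, `erosion`, `age`, `disease_duration`, `tjc28`, `sjc28`, `crp`,
#'   `crp_censored`
#' @export
generate_validation_cohort <- function(spec = validation_cohort_spec(),
                                       truth = radiograph_truth()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(truth, "radiograph_truth"))
  n <- spec$n_patients
  if (n <= 0) stop("n_patients must be positive", call. = FALSE)
  yrs <- spec$visit_weeks   # interpreted in years for the validation cohort
  v <- length(yrs)
  nv <- n * v
  cd <- spec$component_distributions

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(truth$seed)
  pid <- sprintf("NOAR_%04d", rep(seq_len(n), each = v))
  comps <- draw_components(spec, nv)
  age0 <- round(rtrunc_norm(n, cd$age[1], cd$age[2], 18, 90))
  dur0 <- round(rlnorm(n, log(0.7), 0.8), 2)   # symptom duration, years
  b <- rep(rnorm(n, 0, truth$subject_sd), each = v)

  lin <- truth$gamma_sjc * sqrt(comps$sjc28) +
    truth$gamma_crp * log(comps$crp + 1) +
    truth$gamma_tjc * sqrt(comps$tjc28) + b
  span <- max(yrs) - min(yrs)
  base_rate <- if (truth$baseline_larsen > 0) truth$baseline_larsen / max(span, 1)
               else 0
  dt <- rep(c(max(yrs[1], 0.5), diff(yrs)), times = n)
  incr <- if (base_rate > 0) rpois(nv, base_rate * dt * exp(lin)) else
    rep(0L, nv)
  larsen <- as.integer(unlist(lapply(split(incr, rep(seq_len(n), each = v)),
                                     cumsum), use.names = FALSE))
  erosion <- rbinom(nv, 1, plogis(truth$erosion_intercept + lin))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)

  out <- data.frame(
    patient_id = pid, years = rep(yrs, times = n),
    larsen = larsen, erosion = erosion,
    age = rep(age0, each = v) + rep(yrs, times = n),
    disease_duration = round(rep(dur0, each = v) + rep(yrs, times = n), 2),
    tjc28 = comps$tjc28, sjc28 = comps$sjc28,
    crp = round(comps$crp, 1), crp_censored = FALSE,
    stringsAsFactors = FALSE)
  if (spec$crp_censor_threshold > 0) {
    cen <- out$crp < spec$crp_censor_threshold
    out$crp[cen] <- spec$crp_censor_threshold
    out$crp_censored <- cen
  }
  class(out) <- c("radiograph_table", class(out))
  attr(out, "truth") <- truth
  out
}

#' @rdname generate_validation_cohort
#' @param n_patients cohort size for the default validation spec
#' @export
validation_cohort_spec <- function(n_patients = 717) {
  cohort_spec("NOAR", n_patients, c(0, 3, 5, 10), "composite22",
              component_distributions = list(
                tjc = c(2.2, 1.4), sjc = c(2.2, 1.1), crp = c(log(11), 1.1),
                esr = c(log(25), 0.9), ghvas = c(40, 25), haq = c(1.0, 0.7),
                age = c(58, 14), sex_female = 0.69),
              missingness_rates = c(tjc28 = 0, sjc28 = 0, ghvas = 0,
                                    esr = 0, crp = 0),
              crp_censor_threshold = 0)
}
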