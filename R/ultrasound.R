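#' Standard joint sets for ultrasound synovitis scoring
#'
#' `joint_set_composite22()` returns the 22-joint set scanned with the
#' composite grey-scale/power-Doppler convention: bilateral wrists, MCPs 2-3,
#' PIPs 2-3, knees and MTPs 1-5. `joint_set_sum10()` returns the 10-joint set
#' (bilateral MCPs 1-5) scored on 0-4 scales and combined by plain summation.
#'
#' @return character vector of joint labels, `<joint>_<L|R>`.
#' @export
joint_set_composite22 <- function() {
  one_side <- c("wrist", "mcp2", "mcp3", "pip2", "pip3", "knee",
                paste0("mtp", 1:5))
  as.vector(t(outer(one_side, c("L", "R"), paste, sep = "_")))
}

#' @rdname joint_set_composite22
#' @export
joint_set_sum10 <- function() {
  as.vector(t(outer(paste0("mcp", 1:5), c("L", "R"), paste, sep = "_")))
}

check_grade <- function(g, scale_max, what) {
  if (any(is.na(g)) || any(g != as.integer(g)))
    stop(what, " grades must be non-missing integers", call. = FALSE)
  if (any(g < 0) || any(g > scale_max))
    stop(what, " grades must lie in 0..", scale_max, call. = FALSE)
  invisible(as.integer(g))
}

#' Combine grey-scale and power Doppler grades at the joint level
#'
#' Implements the OMERACT-EULAR composite PDUS rule as a single-joint grade:
#' 0 if and only if both GS and PD are 0, otherwise `max(gs, pd)`. Power
#' Doppler signal without grey-scale hypertrophy (gs = 0, pd > 0) is atypical
#' but scored by the same rule.
#'
#' @param gs grey-scale grade(s), integer 0..`scale_max`
#' @param pd power Doppler grade(s), integer 0..`scale_max`
#' @param scale_max maximum semiquantitative grade (3 or 4)
#' @return integer combined grade(s) on the same scale
#' @examples
#' combine_joint(0, 0)  # 0, absent synovitis
#' combine_joint(1, 2)  # 2
#' combine_joint(3, 0)  # 3
#' @export
combine_joint <- function(gs, pd, scale_max = 3) {
  stopifnot(length(gs) == length(pd))
  gs <- check_grade(gs, scale_max, "GS")
  pd <- check_grade(pd, scale_max, "PD")
  out <- pmax(gs, pd)
  out[gs == 0 & pd == 0] <- 0L
  as.integer(out)
}

#' Construct an ultrasound exam
#'
#' @param patient_id patient identifier
#' @param week visit week
#' @param scans data.frame with columns `joint`, `gs`, `pd`
#' @param method `"composite22"` (combined grade summed over the 22-joint set,
#'   grades 0-3) or `"sum10"` (gs + pd summed over bilateral MCPs 1-5,
#'   grades 0-4)
#' @return object of class `ultrasound_exam`
#' @export
ultrasound_exam <- function(patient_id, week, scans,
                            method = c("composite22", "sum10")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(scans), all(c("joint", "gs", "pd") %in% names(scans)))
  structure(list(patient_id = patient_id, week = week, scans = scans,
                 method = method),
            class = "ultrasound_exam")
}

gspd_scale_max <- function(method) if (method == "sum10") 4L else 3L

#' Total GSPD score for one ultrasound exam
#'
#' Reduces joint-level GS/PD grades to the scalar GSPD outcome. Under
#' `composite22` the joint-level combined grade ([combine_joint]) is summed
#' across the 22-joint set (maximum 66); under `sum10` raw GS and PD grades
#' are summed across bilateral MCPs 1-5 on 0-4 scales (maximum 80).
#'
#' @param exam an [ultrasound_exam], or a data.frame of scans plus `method`
#' @param method scoring convention, used when `exam` is a data.frame
#' @return non-negative integer GSPD total
#' @export
gspd_total <- function(exam, method = NULL) {
  if (inherits(exam, "ultrasound_exam")) {
    scans <- exam$scans
    method <- exam$method
  } else {
    scans <- exam
    if (is.null(method)) stop("method is required for a bare scan table")
    method <- match.arg(method, c("composite22", "sum10"))
  }
  required <- if (method == "composite22") joint_set_composite22() else joint_set_sum10()
  if (!setequal(scans$joint, required) || nrow(scans) != length(required)) {
    missing <- setdiff(required, scans$joint)
    stop("scan set does not match the ", method, " joint set",
         if (length(missing)) paste0(" (missing: ",
                                     paste(head(missing, 4), collapse = ", "), ")"),
         call. = FALSE)
  }
  smax <- gspd_scale_max(method)
  if (method == "composite22") {
    as.integer(sum(combine_joint(scans$gs, scans$pd, scale_max = smax)))
  } else {
    check_grade(scans$gs, smax, "GS")
    check_grade(scans$pd, smax, "PD")
    as.integer(sum(scans$gs + scans$pd))
  }
}

#' Per-visit GSPD totals from a long ultrasound table
#'
#' @param ultrasound data.frame with columns `patient_id`, `week`, `joint`,
#'   `gs`, `pd` (one row per joint per visit)
#' @param method scoring convention, see [gspd_total]
#' @return data.frame with columns `patient_id`, `week`, `gspd`, `method`
#' @export
gspd_table <- function(ultrasound, method = c("composite22", "sum10")) {
  method <- match.arg(method)
  stopifnot(all(c("patient_id", "week", "joint", "gs", "pd") %in% names(ultrasound)))
  key <- interaction(ultrasound$patient_id, ultrasound$week, drop = TRUE)
  pieces <- split(ultrasound, key)
  out <- do.call(rbind, lapply(pieces, function(d) {
    data.frame(patient_id = d$patient_id[1], week = d$week[1],
               gspd = gspd_total(d[, c("joint", "gs", "pd")], method = method),
               method = method, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$patient_id, out$week), , drop = FALSE]
}
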