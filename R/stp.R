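#' TIA estimate table constructor
#'
#' Long-format container for time-integrated activity estimates. Each row
#' carries the patient, the estimation method (`rTIA` reference, `s1TIA`
#' and `s2TIA` single-time-point NLME estimates with the 4- and
#' 3-parameter models, `hTIA` closed-form SOP estimate, `nTIA`
#' no-time-point population estimate), the single time point used (NA for
#' `rTIA`/`nTIA`) and the TIA in hours.
#'
#' @param patient_id Character vector of patient identifiers.
#' @param method One of `"rTIA"`, `"s1TIA"`, `"s2TIA"`, `"hTIA"`, `"nTIA"`
#'   (recycled).
#' @param time_point_h Single time point used, in hours (NA where the
#'   method uses none).
#' @param tia_h Estimated TIA in hours; must be > 0.
#' @return A data frame of class `tia_estimates`.
#' @export
tia_estimates <- function(patient_id, method, time_point_h, tia_h) {
  method <- as.character(method)
  ok <- c("rTIA", "s1TIA", "s2TIA", "hTIA", "nTIA")
  if (!all(method %in% ok))
    stop("unknown TIA method label", call. = FALSE)
  df <- data.frame(patient_id = as.character(patient_id), method = method,
                   time_point_h = as.numeric(time_point_h),
                   tia_h = as.numeric(tia_h), stringsAsFactors = FALSE)
  needs_tp <- df$method %in% c("s1TIA", "s2TIA", "hTIA")
  if (any(needs_tp & is.na(df$time_point_h)))
    stop("single-time-point methods must record the time point used",
         call. = FALSE)
  if (any(!needs_tp & !is.na(df$time_point_h)))
    stop("rTIA/nTIA estimates must not carry a time point", call. = FALSE)
  if (any(!is.finite(df$tia_h)) || any(df$tia_h <= 0))
    stop("TIA estimates must be finite and > 0", call. = FALSE)
  class(df) <- c("tia_estimates", "data.frame")
  df
}

#' Reference TIAs from the all-time-point population fit
#'
#' Fits the 4-parameter retention model to the complete multi-time-point
#' cohort by nonlinear mixed effects and returns each patient's
#' empirical-Bayes analytic TIA as the reference (`rTIA`) against which the
#' single-time-point estimators are judged.
#'
#' @param records Full cohort records.
#' @param config A [fit_config()].
#' @return A [tia_estimates()] table (method `rTIA`) with the underlying
#'   [fit_population()] object attached as attribute `"fit"`.
#' @export
compute_reference_tias <- function(records, config = fit_config()) {
  fit <- fit_population(records, model = "a4c", config = config)
  ind <- individual_estimates(fit)
  out <- tia_estimates(ind$patient_id, "rTIA", NA_real_, ind$tia_h)
  attr(out, "fit") <- fit
  out
}

# Build the STP dataset: all other patients' complete profiles plus the
# target patient's single observation at the requested time point.
.stp_dataset <- function(records, target_patient, time_point_h) {
  target_patient <- as.character(target_patient)
  is_target <- as.character(records$patient_id) == target_patient
  if (!any(is_target))
    stop("unknown target patient: ", target_patient, call. = FALSE)
  sel <- is_target & records$time_h == time_point_h
  if (!any(sel))
    stop(sprintf("patient %s has no observation at %g h",
                 target_patient, time_point_h), call. = FALSE)
  rbind(records[!is_target, , drop = FALSE], records[sel, , drop = FALSE])
}

#' Single-time-point TIA estimate for one patient
#'
#' Implements the STP workflow: the target patient keeps only their
#' observation at `time_point_h` while every other patient contributes
#' their complete profile; the population model is then estimated on that
#' dataset and the target's empirical-Bayes analytic TIA is returned.
#' Fitting with the 4-parameter model yields an `s1TIA`, with the
#' 3-parameter model an `s2TIA`.
#'
#' In the default `"joint_refit"` mode the population parameters are
#' re-estimated jointly with the target's single observation. The
#' `"frozen_prior"` mode (via `config$stp_mode` or `mode`) fits the
#' population to the other patients only and computes the target's MAP
#' estimate under that fixed population -- a faster approximation.
#'
#' @param records Full cohort records.
#' @param target_patient Patient identifier.
#' @param time_point_h The single time point (h) to keep for the target.
#' @param model `"a4c"` or `"a3b"`.
#' @param config A [fit_config()].
#' @param warm_start Optional natural-scale parameter vector (or matrix of
#'   rows) tried before the screened random starts; the STP grid passes
#'   the all-data reference estimate here.
#' @param mode Overrides `config$stp_mode`.
#' @param ref_fit Optional pre-computed [fit_population()] on the other
#'   patients' data, used by `"frozen_prior"` mode to avoid refitting.
#' @return A one-row [tia_estimates()] table with attributes `"fit"` (the
#'   population fit used) and `"audit"` (dataset bookkeeping: total
#'   observations and target observations in the likelihood dataset).
#' @export
stp_fit <- function(records, target_patient, time_point_h,
                    model = c("a4c", "a3b"), config = fit_config(),
                    warm_start = NULL, mode = NULL, ref_fit = NULL) {
  model <- match.arg(model)
  mode <- if (is.null(mode)) config$stp_mode else
    match.arg(mode, c("joint_refit", "frozen_prior"))
  target_patient <- as.character(target_patient)
  d <- .stp_dataset(records, target_patient, time_point_h)
  n_target <- sum(as.character(d$patient_id) == target_patient)

  if (mode == "joint_refit") {
    starts <- random_starts(config$n_starts, config$start_bounds, config$seed)
    if (!is.null(warm_start)) {
      # warm-started cells refine the reference estimate first, backed by
      # the two best screened random starts
      ws <- matrix(warm_start, ncol = 4, byrow = is.null(dim(warm_start)))
      colnames(ws) <- c("lambda1", "lambda2", "lambda3", "a1")
      ord <- order(.screen_objective(d, model, starts, config$error_model))
      starts <- rbind(ws, starts[utils::head(ord, 2L), , drop = FALSE])
      fit <- fit_population(d, model = model, config = config,
                            starts = starts, screen = FALSE,
                            first_success = TRUE)
    } else {
      fit <- fit_population(d, model = model, config = config)
    }
    ind <- individual_estimates(fit)
    tia <- ind$tia_h[ind$patient_id == target_patient]
  } else {
    others <- records[as.character(records$patient_id) != target_patient, ,
                      drop = FALSE]
    if (is.null(ref_fit))
      ref_fit <- fit_population(others, model = model, config = config)
    fit <- ref_fit
    eb <- empirical_bayes(fit, d[as.character(d$patient_id) ==
                                   target_patient, , drop = FALSE])
    tia <- eb$tia_h
  }
  method <- if (model == "a4c") "s1TIA" else "s2TIA"
  out <- tia_estimates(target_patient, method, time_point_h, tia)
  attr(out, "fit") <- fit
  attr(out, "audit") <- data.frame(patient_id = target_patient,
                                   time_point_h = time_point_h,
                                   n_obs_total = nrow(d),
                                   n_target_obs = n_target,
                                   engine = fit$engine,
                                   converged = fit$converged)
  out
}

#' Run the STP estimator over a patients-by-time-points grid
#'
#' Applies [stp_fit()] to every (patient, time point) combination with an
#' observation, mirroring the study's evaluation grid. Patients lacking a
#' requested time point (e.g. the 96 h / 120 h subgroup split) are skipped,
#' not imputed. Every cell is warm-started from the all-data reference
#' estimate, which the function computes once if not supplied.
#'
#' @param records Full cohort records.
#' @param model `"a4c"` (`s1TIA`) or `"a3b"` (`s2TIA`).
#' @param time_points Time points (h); each must occur somewhere in the
#'   observed schedule.
#' @param config A [fit_config()].
#' @param ref_fit Optional [fit_population()] of `model` on the full data,
#'   reused for warm starts.
#' @return A [tia_estimates()] table with one row per computed cell and a
#'   per-cell audit log in attribute `"log"` (observation counts, engine,
#'   convergence).
#' @export
run_stp_grid <- function(records, model = c("a4c", "a3b"),
                         time_points, config = fit_config(),
                         ref_fit = NULL) {
  model <- match.arg(model)
  if (!length(time_points)) stop("empty time-point grid", call. = FALSE)
  observed <- unique(records$time_h)
  missing_tp <- setdiff(time_points, observed)
  if (length(missing_tp))
    stop("time points never observed in the cohort: ",
         paste(missing_tp, collapse = ", "), call. = FALSE)
  if (is.null(ref_fit))
    ref_fit <- fit_population(records, model = model, config = config)
  warm <- with(ref_fit$fixed_effects,
               c(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 a1 = a1))
  ids <- unique(as.character(records$patient_id))
  rows <- list(); logs <- list()
  for (tp in time_points) {
    for (pid in ids) {
      has <- any(as.character(records$patient_id) == pid &
                   records$time_h == tp)
      if (!has) next
      est <- stp_fit(records, pid, tp, model = model, config = config,
                     warm_start = warm)
      rows[[length(rows) + 1L]] <- est
      logs[[length(logs) + 1L]] <- attr(est, "audit")
    }
  }
  if (!length(rows))
    stop("no (patient, time point) cell had data", call. = FALSE)
  out <- do.call(rbind, lapply(rows, function(x) as.data.frame(x)))
  class(out) <- c("tia_estimates", "data.frame")
  attr(out, "log") <- do.call(rbind, logs)
  attr(out, "ref_fit") <- ref_fit
  out
}

#' Cell counts of the STP evaluation grid
#'
#' Number of patients with an observation at each requested time point --
#' the cells [run_stp_grid()] would evaluate. Patients lacking a time
#' point (e.g. the late-time subgroup split) are simply absent from that
#' column.
#'
#' @param records Cohort records.
#' @param time_points Time points (h).
#' @return Named integer vector of patient counts per time point.
#' @export
stp_grid_counts <- function(records, time_points) {
  vapply(time_points, function(tp)
    length(unique(records$patient_id[records$time_h == tp])),
    integer(1)) |> stats::setNames(as.character(time_points))
}

#' No-time-point (population) TIA
#'
#' The TIA a centre would assign with no measurements on the patient:
#' evaluated analytically at the mean of the individual parameters of the
#' all-time-point population fit (arithmetic mean across patients of the
#' empirical-Bayes estimates); the same value applies to every patient.
#' When individual estimates are unavailable the population typical values
#' are used.
#'
#' @param fit A [fit_population()] result (the all-time-point reference
#'   fit).
#' @param patient_ids Patients to which the value is assigned (default: all
#'   patients in the fit).
#' @return A [tia_estimates()] table (method `nTIA`, one row per patient,
#'   identical values).
#' @export
ntp_tia <- function(fit, patient_ids = NULL) {
  stopifnot(inherits(fit, "population_fit"))
  ind <- individual_estimates(fit)
  theta <- if (nrow(ind)) {
    colMeans(as.matrix(ind[, c("lambda1", "lambda2", "lambda3", "a1")]))
  } else {
    with(fit$fixed_effects, c(lambda1, lambda2, lambda3, a1))
  }
  tia <- .soef_tia_theta(unname(theta))
  if (is.null(patient_ids)) patient_ids <- ind$patient_id
  tia_estimates(patient_ids, "nTIA", NA_real_, rep(tia, length(patient_ids)))
}

#' Jackknife robustness report for STP fits
#'
#' For each (target patient, time point) cell this reports two things:
#' the exclusion audit (the likelihood dataset must contain exactly one
#' observation for the target patient -- the non-selected observations are
#' excluded), and a leave-one-out perturbation of the population set: each
#' other patient is removed in turn, the STP estimate is recomputed, and
#' the spread (SD) of the target's TIA across the replicates is reported.
#'
#' @param records Full cohort records (>= 3 patients).
#' @param model `"a4c"` or `"a3b"`.
#' @param time_points Time points (h) to evaluate.
#' @param config A [fit_config()].
#' @param patients Optional subset of target patients (default: all with
#'   data at a requested time point).
#' @return Data frame with one row per evaluated cell: `patient_id`,
#'   `time_point_h`, `tia_h` (full-population STP estimate),
#'   `n_target_obs`, `n_replicates`, `tia_sd` (SD over leave-one-out
#'   replicates) and `tia_range`.
#' @export
jackknife_validate <- function(records, model = c("a4c", "a3b"),
                               time_points, config = fit_config(),
                               patients = NULL) {
  model <- match.arg(model)
  ids <- unique(as.character(records$patient_id))
  if (length(ids) < 3)
    stop("jackknife validation needs at least 3 patients", call. = FALSE)
  if (is.null(patients)) patients <- ids
  patients <- as.character(patients)
  ref_fit <- fit_population(records, model = model, config = config)
  warm <- with(ref_fit$fixed_effects,
               c(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 a1 = a1))
  out <- list()
  for (tp in time_points) {
    for (pid in patients) {
      if (!any(as.character(records$patient_id) == pid &
                 records$time_h == tp)) next
      full <- stp_fit(records, pid, tp, model = model, config = config,
                      warm_start = warm)
      audit <- attr(full, "audit")
      reps <- vapply(setdiff(ids, pid), function(drop_id) {
        sub <- records[as.character(records$patient_id) != drop_id, ,
                       drop = FALSE]
        est <- stp_fit(sub, pid, tp, model = model, config = config,
                       warm_start = warm)
        est$tia_h
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        patient_id = pid, time_point_h = tp, tia_h = full$tia_h,
        n_target_obs = audit$n_target_obs, n_replicates = length(reps),
        tia_sd = stats::sd(reps), tia_range = diff(range(reps)))
    }
  }
  if (!length(out))
    stop("no (patient, time point) cell had data", call. = FALSE)
  do.call(rbind, out)
}
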