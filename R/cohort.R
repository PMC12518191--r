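#' Population truth for synthetic cohort generation
#'
#' Describes the data-generating population used by [generate_cohort()]:
#' typical SOEF parameter values, log-normal inter-individual variability
#' (IIV), a residual measurement-noise model, and the sampling schedule
#' (common early times plus a late time point of 96 h or 120 h assigned by
#' subgroup). Individual parameters are drawn log-normally around the
#' typical values (median = typical), which enforces the non-negativity
#' constraint on all rates and on the blood-pool amplitude.
#'
#' @param typical_params A [soef_params()] object with the population
#'   typical values.
#' @param iiv_cv Coefficient of variation of the log-normal IIV, either a
#'   single value applied to all four parameters or a named vector
#'   (`lambda1`, `lambda2`, `lambda3`, `a1`). Use 0 for no variability.
#' @param residual_model List with elements `type` (one of
#'   `"proportional"`, `"additive"`, `"combined"`), `prop` (proportional SD,
#'   fraction), `add` (additive SD, retention units).
#' @param common_times Measurement times (h) shared by every patient.
#' @param late_times Candidate late measurement times (h).
#' @param late_n Number of patients assigned to each late time; must sum to
#'   `n`.
#' @param n Cohort size.
#' @param seed Integer seed making cohort generation reproducible.
#' @param miss_6h_patient If `TRUE`, the first patient lacks the 6 h
#'   measurement (the one-record-short feature of the emulated design).
#' @return An object of class `population_truth`.
#' @export
population_truth <- function(typical_params,
                             iiv_cv = 0.30,
                             residual_model = list(type = "combined",
                                                   prop = 0.10, add = 0.002),
                             common_times = c(2, 6, 24, 48),
                             late_times = c(96, 120),
                             late_n = c(53, 20),
                             n = sum(late_n),
                             seed = 20251L,
                             miss_6h_patient = FALSE) {
  stopifnot(inherits(typical_params, "soef_params"))
  if (length(iiv_cv) == 1)
    iiv_cv <- stats::setNames(rep(iiv_cv, 4),
                              c("lambda1", "lambda2", "lambda3", "a1"))
  iiv_cv <- iiv_cv[c("lambda1", "lambda2", "lambda3", "a1")]
  if (any(is.na(iiv_cv)) || any(iiv_cv < 0))
    stop("iiv_cv must be named, complete and >= 0", call. = FALSE)
  residual_model$type <- match.arg(residual_model$type,
                                   c("proportional", "additive", "combined"))
  if (is.null(residual_model$prop)) residual_model$prop <- 0
  if (is.null(residual_model$add)) residual_model$add <- 0
  if (residual_model$prop < 0 || residual_model$add < 0)
    stop("residual error magnitudes must be >= 0", call. = FALSE)
  if (length(common_times) + length(late_times) == 0)
    stop("schedule must contain at least one measurement time", call. = FALSE)
  if (any(c(common_times, late_times) <= 0))
    stop("measurement times must be > 0 h", call. = FALSE)
  if (length(late_times) != length(late_n))
    stop("late_times and late_n must have equal length", call. = FALSE)
  if (length(late_n) && sum(late_n) != n)
    stop("late-time subgroup sizes must sum to n", call. = FALSE)
  structure(list(typical_params = typical_params,
                 iiv_cv = iiv_cv,
                 residual_model = residual_model,
                 common_times = sort(common_times),
                 late_times = late_times,
                 late_n = as.integer(late_n),
                 n = as.integer(n),
                 seed = as.integer(seed),
                 miss_6h_patient = isTRUE(miss_6h_patient)),
            class = "population_truth")
}

#' Default synthetic study population
#'
#' A fixed, documented population emulating the sampling design of a
#' 73-patient thyroid ^131I uptake study: measurements at 2, 6, 24 and
#' 48 h for everyone plus 96 h (53 patients) or 120 h (20 patients), 30%
#' log-normal inter-individual variability on all four parameters, and
#' combined residual error (10% proportional with a 0.002 additive floor).
#' The typical parameter values (`lambda1 = lambda2 = 0.04` /h,
#' `lambda3 = 0.0015` /h, `a1 = 0.05`) are invented defaults, chosen so the
#' noise-free curve peaks near 34 h at a retention of about 0.40 with a
#' terminal biological half-life of roughly 2.8 weeks -- qualitatively
#' realistic for thyroidal radioiodine uptake. They are configuration, not
#' estimates of any clinical population.
#'
#' @param seed Integer seed stored in the population object.
#' @return A [population_truth()] object.
#' @examples
#' pop <- default_population()
#' soef_tia(pop$typical_params)
#' @export
default_population <- function(seed = 20251L) {
  population_truth(
    typical_params = soef_params(0.04, 0.04, 0.0015, a1 = 0.05),
    iiv_cv = 0.30,
    residual_model = list(type = "combined", prop = 0.10, add = 0.002),
    common_times = c(2, 6, 24, 48),
    late_times = c(96, 120),
    late_n = c(53, 20),
    n = 73L,
    seed = seed)
}

# Split n patients over the late times in the same proportions as late_n,
# keeping the exact configured split when n matches.
.late_assignment <- function(population, n) {
  if (!length(population$late_times)) return(rep(NA_real_, n))
  if (n == population$n) {
    counts <- population$late_n
  } else {
    counts <- floor(n * population$late_n / sum(population$late_n))
    i <- 1L
    while (sum(counts) < n) {  # distribute the rounding remainder in order
      counts[i] <- counts[i] + 1L
      i <- i %% length(counts) + 1L
    }
  }
  rep(population$late_times, counts)
}

#' Generate a synthetic biokinetic cohort
#'
#' Draws `n_patients` individual parameter sets log-normally around the
#' population typical values, evaluates the retention model at each
#' patient's schedule, applies the residual noise model, and records the
#' per-patient ground truth (parameters and analytic TIA). Negative noisy
#' observations are truncated at 0 and flagged. Generation is fully
#' reproducible from the seed; the caller's RNG state is left untouched.
#'
#' @param population A [population_truth()] object.
#' @param n_patients Number of patients (default: the population's `n`).
#' @param seed Optional seed overriding `population$seed`.
#' @return An object of class `synthetic_cohort`: a list with
#'   \describe{
#'     \item{records}{data frame `patient_id`, `time_h`, `retention`,
#'       `truncated`.}
#'     \item{truth}{data frame of true individual parameters and the true
#'       analytic `tia_h` per patient.}
#'     \item{population}{the generating [population_truth()].}
#'   }
#' @export
generate_cohort <- function(population, n_patients = population$n,
                            seed = population$seed) {
  stopifnot(inherits(population, "population_truth"))
  if (n_patients < 2)
    stop("a cohort needs at least 2 patients", call. = FALSE)
  typ <- with(population$typical_params,
              c(lambda1 = lambda1, lambda2 = lambda2,
                lambda3 = lambda3, a1 = a1))
  sdlog <- sqrt(log(1 + population$iiv_cv^2))
  late <- .late_assignment(population, n_patients)
  rm_ <- population$residual_model
  ids <- sprintf("P%03d", seq_len(n_patients))

  records <- vector("list", n_patients)
  truth <- vector("list", n_patients)
  with_preserved_seed(seed, {
    for (i in seq_len(n_patients)) {
      eta <- stats::rnorm(4, 0, sdlog)
      th <- ifelse(typ > 0, typ * exp(eta), 0)  # zero typicals stay zero
      tt <- population$common_times
      if (population$miss_6h_patient && i == 1L) tt <- setdiff(tt, 6)
      if (!is.na(late[i])) tt <- c(tt, late[i])
      p <- soef_params(th[1], th[2], th[3], a1 = th[4],
                       model = population$typical_params$model)
      mu <- soef_retention(p, tt)
      y <- switch(rm_$type,
        proportional = mu * (1 + stats::rnorm(length(tt), 0, rm_$prop)),
        additive     = mu + stats::rnorm(length(tt), 0, rm_$add),
        combined     = mu * (1 + stats::rnorm(length(tt), 0, rm_$prop)) +
                       stats::rnorm(length(tt), 0, rm_$add))
      truncated <- y < 0
      y[truncated] <- 0
      records[[i]] <- data.frame(patient_id = ids[i], time_h = tt,
                                 retention = y, truncated = truncated)
      truth[[i]] <- data.frame(patient_id = ids[i], lambda1 = th[1],
                               lambda2 = th[2], lambda3 = th[3], a1 = th[4],
                               tia_h = soef_tia(p))
    }
  })
  structure(list(records = do.call(rbind, records),
                 truth = do.call(rbind, truth),
                 population = population),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d patients, %d records, seed %d\n",
              nrow(x$truth), nrow(x$records), x$population$seed))
  invisible(x)
}

#' The emulated 73-patient study-design cohort
#'
#' Convenience wrapper around [generate_cohort()] with the
#' [default_population()] and the one-patient-missing-6-h feature switched
#' on, which reproduces the bookkeeping of the emulated design: 73
#' patients, 364 retention records, late-time split 53 patients at 96 h and
#' 20 at 120 h.
#'
#' @param seed Integer seed.
#' @return A `synthetic_cohort`.
#' @export
study_design_cohort <- function(seed = 20251L) {
  pop <- default_population(seed = seed)
  pop$miss_6h_patient <- TRUE
  generate_cohort(pop)
}

# Evaluate a block of code with a temporary RNG seed, restoring the
# caller's RNG state afterwards.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
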