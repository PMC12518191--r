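#' Configuration for population biokinetic fitting
#'
#' Collects the tunables of [fit_population()] and the STP machinery.
#'
#' The residual error models are:
#' \describe{
#'   \item{`"proportional"`}{(default) additive normal error on
#'     log-retention, the exponential-error form of a proportional model;
#'     `sigma` is then approximately the residual CV. Zero-retention
#'     records cannot enter this likelihood and are dropped with a count
#'     kept in the fit object.}
#'   \item{`"additive"`}{homoscedastic normal error on the natural scale.}
#'   \item{`"combined"`}{natural-scale error with SD proportional to
#'     `const + |prediction|`, the additive-plus-proportional form.}
#' }
#'
#' @param error_model Residual error model, see Details.
#' @param n_starts Number of log-uniform random starting vectors screened.
#' @param n_refine Number of best-screened starts refined by the full
#'   mixed-effects fit.
#' @param start_bounds 4 x 2 matrix (rows `lambda1`, `lambda2`, `lambda3`,
#'   `a1`; columns lower, upper) bounding the random starts.
#' @param tolerance Relative convergence tolerance of the outer
#'   optimisation.
#' @param max_iter Maximum outer iterations of the mixed-effects algorithm.
#' @param pnls_max_iter Maximum iterations of the inner penalised
#'   nonlinear least-squares step. Truncating the inner step too early
#'   (small values) makes the outer alternation cycle on this model
#'   class.
#' @param seed Integer seed for start generation (and any derived RNG).
#' @param stp_mode `"joint_refit"` re-estimates the population jointly with
#'   the target's single observation (the default, literal workflow);
#'   `"frozen_prior"` keeps the population estimate fixed and computes only
#'   the target's empirical-Bayes estimate (a fast approximation).
#' @param sigma_floor Lower bound applied to the residual SD estimate.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(error_model = c("proportional", "additive", "combined"),
                       n_starts = 1000L,
                       n_refine = 5L,
                       start_bounds = default_start_bounds(),
                       tolerance = 1e-5,
                       max_iter = 60L,
                       pnls_max_iter = 20L,
                       seed = 1L,
                       stp_mode = c("joint_refit", "frozen_prior"),
                       sigma_floor = 1e-6) {
  error_model <- match.arg(error_model)
  stp_mode <- match.arg(stp_mode)
  if (n_starts < 1) stop("n_starts must be >= 1", call. = FALSE)
  if (n_refine < 1) stop("n_refine must be >= 1", call. = FALSE)
  structure(list(error_model = error_model,
                 n_starts = as.integer(n_starts),
                 n_refine = as.integer(n_refine),
                 start_bounds = .check_bounds(start_bounds),
                 tolerance = tolerance,
                 max_iter = as.integer(max_iter),
                 pnls_max_iter = as.integer(pnls_max_iter),
                 seed = as.integer(seed),
                 stp_mode = stp_mode,
                 sigma_floor = sigma_floor),
            class = "fit_config")
}

#' Default start bounds for multi-start initialisation
#'
#' Rates span 1e-5 to 1 per hour (physiologic uptake/washout scales for
#' thyroidal iodine); the blood-pool amplitude spans 1e-4 to 0.5.
#'
#' @return A 4 x 2 numeric matrix with parameter rownames.
#' @export
default_start_bounds <- function() {
  matrix(c(1e-5, 1, 1e-5, 1, 1e-5, 1, 1e-4, 0.5), ncol = 2, byrow = TRUE,
         dimnames = list(c("lambda1", "lambda2", "lambda3", "a1"),
                         c("lower", "upper")))
}

.check_bounds <- function(b) {
  if (!is.matrix(b) || nrow(b) != 4 || ncol(b) != 2)
    stop("start_bounds must be a 4 x 2 matrix", call. = FALSE)
  if (any(!is.finite(b)) || any(b <= 0))
    stop("start bounds must be finite and positive", call. = FALSE)
  if (any(b[, 1] >= b[, 2]))
    stop("start bounds are inverted (lower >= upper)", call. = FALSE)
  rownames(b) <- c("lambda1", "lambda2", "lambda3", "a1")
  colnames(b) <- c("lower", "upper")
  b
}

#' Log-uniform random starting vectors
#'
#' Draws `n_starts` parameter vectors log-uniformly within the given
#' bounds, reproducibly from the seed. The screening stage of
#' [fit_population()] evaluates a cheap pooled least-squares objective at
#' every start and refines only the best few.
#'
#' @param n_starts Number of starting vectors (>= 1).
#' @param bounds 4 x 2 bounds matrix as in [default_start_bounds()].
#' @param seed Integer seed.
#' @return An `n_starts` x 4 matrix of natural-scale parameter vectors.
#' @export
random_starts <- function(n_starts, bounds = default_start_bounds(), seed = 1L) {
  if (n_starts < 1) stop("n_starts must be >= 1", call. = FALSE)
  bounds <- .check_bounds(bounds)
  with_preserved_seed(seed, {
    u <- matrix(stats::runif(n_starts * 4), ncol = 4)
  })
  lo <- log(bounds[, 1]); hi <- log(bounds[, 2])
  out <- exp(sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`))
  colnames(out) <- rownames(bounds)
  out
}

# ---- record validation -----------------------------------------------------

.validate_records <- function(records, min_patients = 2L) {
  req <- c("patient_id", "time_h", "retention")
  if (!is.data.frame(records) || !all(req %in% names(records)))
    stop("records must be a data frame with columns patient_id, time_h, retention",
         call. = FALSE)
  if (!nrow(records)) stop("records is empty", call. = FALSE)
  if (any(!is.finite(records$time_h)) || any(records$time_h <= 0))
    stop("time_h must be finite and > 0", call. = FALSE)
  if (any(!is.finite(records$retention)) || any(records$retention < 0))
    stop("retention must be finite and >= 0", call. = FALSE)
  npat <- length(unique(records$patient_id))
  if (npat < min_patients)
    stop(sprintf("at least %d patients are required (got %d)",
                 min_patients, npat), call. = FALSE)
  if (all(records$retention == 0))
    stop("all observations are zero; the retention model cannot be estimated",
         call. = FALSE)
  invisible(records)
}

# ---- model prediction functions used inside nlme formulas ------------------

.pred4 <- function(ll1, ll2, ll3, lla1, time_h) {
  lp <- log(2) / (8.022 * 24)
  l1 <- exp(ll1); l2 <- exp(ll2); l3 <- exp(ll3)
  l1 / (l2 + l1 - l3) * (exp(-(l3 + lp) * time_h) -
                         exp(-(l1 + l2 + lp) * time_h)) +
    exp(lla1) * exp(-(l1 + l2 + lp) * time_h)
}

# The floor keeps the log defined when an optimizer step wanders into a
# parameter region with non-positive predictions; observed retentions are
# orders of magnitude above it.
.lpred4 <- function(ll1, ll2, ll3, lla1, time_h)
  log(pmax(.pred4(ll1, ll2, ll3, lla1, time_h), 1e-12))

.pred3 <- function(ll1, ll2, ll3, time_h) {
  lp <- log(2) / (8.022 * 24)
  l1 <- exp(ll1); l2 <- exp(ll2); l3 <- exp(ll3)
  l1 / (l2 + l1 - l3) * (exp(-(l3 + lp) * time_h) -
                         exp(-(l1 + l2 + lp) * time_h))
}

.lpred3 <- function(ll1, ll2, ll3, time_h)
  log(pmax(.pred3(ll1, ll2, ll3, time_h), 1e-12))

.log_par_names <- function(model)
  if (model == "a4c") c("ll1", "ll2", "ll3", "lla1") else c("ll1", "ll2", "ll3")

# Name-based so that a 4-parameter fit whose blood-pool amplitude sits on
# the a1 = 0 boundary (estimated without the lla1 coordinate) maps cleanly
# to the full parameter vector.
.theta_from_log <- function(model, lpar) {
  th <- c(exp(unname(lpar["ll1"])), exp(unname(lpar["ll2"])),
          exp(unname(lpar["ll3"])),
          if ("lla1" %in% names(lpar)) exp(unname(lpar["lla1"])) else 0)
  names(th) <- c("lambda1", "lambda2", "lambda3", "a1")
  th
}

# ---- multi-start screening -------------------------------------------------

# Cheap pooled fixed-effects objective used to rank random starts:
# log-scale RSS for the proportional error model, natural-scale RSS
# otherwise.
.screen_objective <- function(records, model, starts, error_model) {
  t_h <- records$time_h
  y <- records$retention
  use_log <- error_model == "proportional"
  if (use_log) {
    keep <- y > 0
    t_h <- t_h[keep]; y <- log(y[keep])
  }
  apply(starts, 1, function(th) {
    mu <- .soef_eval(c(th[1:3], if (model == "a4c") th[4] else 0), t_h)
    r <- if (use_log) y - log(pmax(mu, 1e-12)) else y - mu
    sum(r * r)
  })
}

# ---- nlme backends ---------------------------------------------------------

# The model functions are namespace-qualified because nlme evaluates the
# model expression outside the formula environment.
.nlme_formula <- function(model, error_model) {
  if (model == "a4c") {
    if (error_model == "proportional")
      log(retention) ~ stpdosim:::.lpred4(ll1, ll2, ll3, lla1, time_h)
    else retention ~ stpdosim:::.pred4(ll1, ll2, ll3, lla1, time_h)
  } else {
    if (error_model == "proportional")
      log(retention) ~ stpdosim:::.lpred3(ll1, ll2, ll3, time_h)
    else retention ~ stpdosim:::.pred3(ll1, ll2, ll3, time_h)
  }
}

# One attempt at a full mixed-effects fit. re_names selects which log
# parameters carry a random effect; returns NULL on any failure.
.try_nlme <- function(data, model, start_log, re_names, config) {
  pnames <- .log_par_names(model)
  fixed <- stats::as.formula(paste(paste(pnames, collapse = "+"), "~ 1"))
  random <- nlme::pdDiag(stats::as.formula(
    paste(paste(re_names, collapse = "+"), "~ 1")))
  form <- .nlme_formula(model, config$error_model)
  environment(form) <- environment()
  args <- list(form,
               fixed = fixed, random = random, groups = ~patient_id,
               data = data, start = start_log[pnames], method = "ML",
               control = nlme::nlmeControl(maxIter = config$max_iter,
                                           msMaxIter = 150,
                                           pnlsMaxIter = config$pnls_max_iter,
                                           tolerance = config$tolerance,
                                           returnObject = FALSE))
  if (config$error_model == "combined")
    args$weights <- nlme::varConstPower(fixed = list(power = 1))
  fit <- suppressWarnings(try(do.call(nlme::nlme, args), silent = TRUE))
  if (inherits(fit, "try-error")) {
    options(stpdosim.last_nlme_error = attr(fit, "condition")$message)
    return(NULL)
  }
  fit
}

# Pooled fixed-effects-only fit (omega = 0): the exact maximum-likelihood
# model for a homogeneous cohort and the last rung of the fallback ladder.
# Uses the raw Levenberg-Marquardt interface with an explicit residual
# function, which is robust to weakly acting parameters (e.g. a1 on data
# without a blood-pool signal).
.fit_pooled <- function(data, model, start_log, config) {
  pnames <- .log_par_names(model)
  use_log <- config$error_model == "proportional"
  t_h <- data$time_h
  y <- if (use_log) log(data$retention) else data$retention
  res_fn <- function(lpar) {
    theta <- .theta_from_log(model, stats::setNames(lpar, pnames))
    mu <- .soef_eval(theta, t_h)
    if (use_log) y - log(pmax(mu, 1e-12)) else y - mu
  }
  fit <- try(minpack.lm::nls.lm(par = unname(start_log[pnames]), fn = res_fn,
                                lower = rep(-25, length(pnames)),
                                upper = rep(5, length(pnames)),
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 500)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  lpar <- stats::setNames(fit$par, pnames)
  n <- nrow(data)
  rss <- sum(res_fn(fit$par)^2)
  sigma <- max(sqrt(rss / n), config$sigma_floor)
  objective <- n * log(2 * pi * sigma^2) + rss / sigma^2
  list(lpar = lpar, sigma = sigma, objective = objective)
}

# ---- population fit --------------------------------------------------------

#' Fit a population retention model by nonlinear mixed effects
#'
#' Estimates population typical values (fixed effects on the log scale),
#' diagonal between-patient variances (log scale), and a residual error
#' parameter for the chosen retention model, from multi-patient biokinetic
#' records. Starting values are screened by a pooled least-squares
#' objective over `n_starts` log-uniform random vectors and the best
#' `n_refine` are refined by the full mixed-effects fit (maximum
#' likelihood, Lindstrom-Bates approximation); the best converged
#' refinement is returned.
#'
#' If no refinement converges with random effects on all parameters, the
#' blood-pool random effect is dropped, and as a last resort a pooled
#' fixed-effects-only fit (all between-patient variances 0) is returned and
#' flagged via `engine = "pooled"`. The pooled rung is exact for
#' homogeneous (zero-variability) cohorts. The result is deterministic
#' given the records, the configuration and its seed.
#'
#' @param records Data frame with `patient_id`, `time_h`, `retention`
#'   (>= 2 patients, >= 1 observation each).
#' @param model `"a4c"` or `"a3b"`.
#' @param config A [fit_config()].
#' @param starts Optional matrix of natural-scale starting vectors
#'   (columns `lambda1`, `lambda2`, `lambda3`, `a1`) replacing the random
#'   screen; the first `n_refine` rows (after screening-ranking) are
#'   refined.
#' @param screen Logical; rank `starts` by the screening objective before
#'   refining (default `TRUE`).
#' @param first_success Stop refining at the first converged fit instead of
#'   taking the best of all refinements (used by the STP grid's warm
#'   starts).
#' @return An object of class `population_fit` with elements
#'   `fixed_effects` ([soef_params()]), `log_fixef`, `omega` (named
#'   log-scale variances), `sigma`, `sigma_const`, `objective` (-2 log
#'   likelihood, approximate), `converged`, `engine`, `n_starts_used`,
#'   `individual` (per-patient empirical-Bayes parameters and analytic
#'   TIAs), and bookkeeping fields.
#' @export
fit_population <- function(records, model = c("a4c", "a3b"),
                           config = fit_config(), starts = NULL,
                           screen = TRUE, first_success = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(config, "fit_config"))
  .validate_records(records, min_patients = 2L)
  data <- records
  data$patient_id <- factor(data$patient_id)
  n_dropped <- 0L
  if (config$error_model == "proportional") {
    drop <- data$retention <= 0
    n_dropped <- sum(drop)
    data <- data[!drop, , drop = FALSE]
    bad <- setdiff(levels(data$patient_id), unique(as.character(data$patient_id)))
    if (length(bad))
      stop("patients with no positive retention cannot enter the ",
           "proportional-error likelihood: ", paste(bad, collapse = ", "),
           call. = FALSE)
    data$patient_id <- droplevels(data$patient_id)
  }

  if (is.null(starts))
    starts <- random_starts(config$n_starts, config$start_bounds, config$seed)
  n_starts_used <- nrow(starts)
  ord <- if (screen && nrow(starts) > 1)
    order(.screen_objective(data, model, starts, config$error_model))
  else seq_len(nrow(starts))
  cand <- starts[utils::head(ord, config$n_refine), , drop = FALSE]

  pnames <- .log_par_names(model)
  start_log_of <- function(row) stats::setNames(
    log(pmax(row[c("lambda1", "lambda2", "lambda3",
                   "a1")][seq_along(pnames)], 1e-12)), pnames)

  # A pooled fit that is exact (residual SD at the floor) means the cohort
  # is homogeneous and noise-free: the fixed-effects-only model IS the
  # maximum-likelihood solution and the mixed-effects approximation has
  # nothing to estimate. Detect this first; it also short-circuits the
  # degenerate cohorts for which the iterative algorithm is unstable.
  pooled0 <- .fit_pooled(data, model, start_log_of(cand[1, ]), config)
  if (!is.null(pooled0) && pooled0$sigma <= config$sigma_floor) {
    res <- .pack_pooled_fit(pooled0, data, model, config,
                            n_starts_used, n_dropped)
    res$seed <- config$seed
    return(res)
  }

  re_full <- pnames
  fits <- list()
  for (i in seq_len(nrow(cand))) {
    sl <- start_log_of(cand[i, ])
    f <- .try_nlme(data, model, sl, re_full, config)
    if (!is.null(f)) {
      fits[[length(fits) + 1L]] <- list(fit = f, engine = "nlme",
                                        re_names = re_full, start = sl)
      if (first_success) break
    }
  }
  n_ladder <- min(2L, nrow(cand))  # fallback rungs retry the best starts only
  if (!length(fits) && model == "a4c") {
    # drop the blood-pool random effect, keep rates random
    for (i in seq_len(n_ladder)) {
      f <- .try_nlme(data, model, start_log_of(cand[i, ]),
                     c("ll1", "ll2", "ll3"), config)
      if (!is.null(f)) {
        fits[[1L]] <- list(fit = f, engine = "nlme_reduced",
                           re_names = c("ll1", "ll2", "ll3"),
                           start = start_log_of(cand[i, ]))
        break
      }
    }
  }
  if (!length(fits) && model == "a4c") {
    # a1 on its boundary: when the data carry no blood-pool signal the
    # log-scale amplitude runs to -Inf and the 4-parameter fit is
    # structurally degenerate; the maximum-likelihood solution is the
    # nested 3-parameter model with a1 = 0.
    for (i in seq_len(n_ladder)) {
      sl3 <- start_log_of(cand[i, ])[c("ll1", "ll2", "ll3")]
      f <- .try_nlme(data, "a3b", sl3, c("ll1", "ll2", "ll3"), config)
      if (!is.null(f)) {
        fits[[1L]] <- list(fit = f, engine = "nlme_a1_boundary",
                           re_names = c("ll1", "ll2", "ll3"), start = sl3)
        break
      }
    }
  }

  if (length(fits)) {
    objs <- vapply(fits, function(z) -2 * as.numeric(stats::logLik(z$fit)),
                   numeric(1))
    best <- fits[[which.min(objs)]]
    res <- .pack_nlme_fit(best, data, model, config,
                          n_starts_used, n_dropped, min(objs))
  } else {
    pooled <- pooled0
    for (i in seq_len(nrow(cand))) {
      if (!is.null(pooled)) break
      pooled <- .fit_pooled(data, model, start_log_of(cand[i, ]), config)
    }
    if (is.null(pooled))
      stop("population fit failed: no start converged, pooled fallback failed",
           call. = FALSE)
    res <- .pack_pooled_fit(pooled, data, model, config,
                            n_starts_used, n_dropped)
  }
  res$seed <- config$seed
  res
}

.omega_template <- function() stats::setNames(numeric(4),
  c("lambda1", "lambda2", "lambda3", "a1"))

.pack_nlme_fit <- function(best, data, model, config,
                           n_starts_used, n_dropped, objective) {
  fit <- best$fit
  lfix <- nlme::fixef(fit)
  theta <- .theta_from_log(model, lfix)
  omega <- .omega_template()
  sd_re <- suppressWarnings(
    as.numeric(nlme::VarCorr(fit)[best$re_names, "StdDev"]))
  map <- c(ll1 = "lambda1", ll2 = "lambda2", ll3 = "lambda3", lla1 = "a1")
  omega[map[best$re_names]] <- sd_re^2
  sigma <- max(fit$sigma, config$sigma_floor)
  sigma_const <- 0
  if (config$error_model == "combined") {
    vs <- fit$modelStruct$varStruct
    sigma_const <- exp(as.numeric(stats::coef(vs, unconstrained = TRUE)[1]))
  }
  cf <- stats::coef(fit)  # per-patient log-scale EB parameters
  ind <- data.frame(patient_id = rownames(cf), stringsAsFactors = FALSE)
  thm <- t(apply(as.matrix(cf), 1, function(r)
    .theta_from_log(model, stats::setNames(r, colnames(cf)))))
  ind <- cbind(ind, as.data.frame(thm))
  ind$tia_h <- apply(thm, 1, .soef_tia_theta)
  structure(list(model = model, error_model = config$error_model,
                 log_fixef = lfix,
                 fixed_effects = soef_params(theta[1], theta[2], theta[3],
                                             a1 = theta[4], model = model),
                 omega = omega, sigma = sigma, sigma_const = sigma_const,
                 objective = objective, converged = TRUE,
                 engine = best$engine, n_starts_used = n_starts_used,
                 n_records_dropped = n_dropped,
                 n_patients = length(unique(data$patient_id)),
                 individual = ind, data = data, nlme_fit = fit),
            class = "population_fit")
}

.pack_pooled_fit <- function(pooled, data, model, config,
                             n_starts_used, n_dropped) {
  theta <- .theta_from_log(model, pooled$lpar)
  ids <- unique(as.character(data$patient_id))
  thm <- matrix(theta, nrow = length(ids), ncol = 4, byrow = TRUE,
                dimnames = list(ids, names(theta)))
  ind <- data.frame(patient_id = ids, as.data.frame(thm),
                    stringsAsFactors = FALSE)
  ind$tia_h <- .soef_tia_theta(theta)
  structure(list(model = model, error_model = config$error_model,
                 log_fixef = pooled$lpar,
                 fixed_effects = soef_params(theta[1], theta[2], theta[3],
                                             a1 = theta[4], model = model),
                 omega = .omega_template(), sigma = pooled$sigma,
                 sigma_const = 0, objective = pooled$objective,
                 converged = TRUE, engine = "pooled",
                 n_starts_used = n_starts_used,
                 n_records_dropped = n_dropped,
                 n_patients = length(ids),
                 individual = ind, data = data, nlme_fit = NULL),
            class = "population_fit")
}

#' @export
print.population_fit <- function(x, ...) {
  cat(sprintf("population fit (%s, %s error, engine %s)\n",
              x$model, x$error_model, x$engine))
  p <- x$fixed_effects
  cat(sprintf("  fixed effects: lambda1=%.4g lambda2=%.4g lambda3=%.4g a1=%.4g\n",
              p$lambda1, p$lambda2, p$lambda3, p$a1))
  cat(sprintf("  omega (log-scale var): %s\n",
              paste(sprintf("%s=%.3g", names(x$omega), x$omega),
                    collapse = " ")))
  cat(sprintf("  sigma=%.4g  -2LL=%.2f  patients=%d\n",
              x$sigma, x$objective, x$n_patients))
  invisible(x)
}

#' Per-patient empirical-Bayes estimates of a population fit
#'
#' @param fit A [fit_population()] result.
#' @return Data frame with `patient_id`, the four natural-scale parameters
#'   and the analytic `tia_h`.
#' @export
individual_estimates <- function(fit) {
  stopifnot(inherits(fit, "population_fit"))
  fit$individual
}

# ---- empirical Bayes / MAP -------------------------------------------------

# Residual SD per observation under the fit's error model.
.resid_sd <- function(fit, mu) {
  switch(fit$error_model,
         proportional = rep(fit$sigma, length(mu)),
         additive = rep(fit$sigma, length(mu)),
         combined = fit$sigma * (fit$sigma_const + abs(mu)))
}

# -2 log of (likelihood x prior) for one patient's random-effect vector
# eta, restricted to components with omega > 0.
.map_objective <- function(eta_free, free, fit, t_h, y) {
  eta <- numeric(length(fit$log_fixef))
  eta[free] <- eta_free
  lpar <- fit$log_fixef + eta
  theta <- .theta_from_log(fit$model, stats::setNames(lpar,
                                                      names(fit$log_fixef)))
  mu <- .soef_eval(theta, t_h)
  if (fit$error_model == "proportional") {
    r <- log(y) - log(pmax(mu, 1e-300))
    sd_ <- rep(fit$sigma, length(mu))
  } else {
    r <- y - mu
    sd_ <- pmax(.resid_sd(fit, mu), fit$sigma * 1e-3 + 1e-12)
  }
  omega_free <- .omega_map(fit)[free]
  sum(r^2 / sd_^2 + log(2 * pi * sd_^2)) + sum(eta_free^2 / omega_free) +
    sum(log(2 * pi * omega_free))
}

.omega_map <- function(fit) {
  m <- c(ll1 = "lambda1", ll2 = "lambda2", ll3 = "lambda3", lla1 = "a1")
  unname(fit$omega[m[names(fit$log_fixef)]])
}

#' Empirical-Bayes (MAP) individual estimate under a population fit
#'
#' Returns the mode of a patient's conditional parameter distribution given
#' their observations and the fitted population distribution (maximum a
#' posteriori on the log scale), together with the analytic TIA. Components
#' whose between-patient variance is zero are pinned at the population
#' typical value. Works for patients that were not part of the fit, which
#' is what the frozen-prior STP mode uses.
#'
#' @param fit A [fit_population()] result.
#' @param patient_records Data frame of the patient's records (`time_h`,
#'   `retention`; `patient_id` optional, must be a single patient).
#' @return A list with `patient_id`, `params` ([soef_params()]), `eta`
#'   (log-scale deviations), and `tia_h`.
#' @export
empirical_bayes <- function(fit, patient_records) {
  stopifnot(inherits(fit, "population_fit"))
  if (!nrow(patient_records))
    stop("patient has no observations", call. = FALSE)
  if ("patient_id" %in% names(patient_records) &&
      length(unique(patient_records$patient_id)) > 1)
    stop("patient_records must belong to a single patient", call. = FALSE)
  t_h <- patient_records$time_h
  y <- patient_records$retention
  if (fit$error_model == "proportional") {
    keep <- y > 0
    t_h <- t_h[keep]; y <- y[keep]
    if (!length(y))
      stop("no positive observations for MAP under proportional error",
           call. = FALSE)
  }
  omega <- .omega_map(fit)
  free <- which(omega > 0)
  if (length(free)) {
    opt <- stats::nlminb(numeric(length(free)), .map_objective,
                         free = free, fit = fit, t_h = t_h, y = y,
                         control = list(iter.max = 500))
    eta <- numeric(length(fit$log_fixef))
    eta[free] <- opt$par
  } else {
    eta <- numeric(length(fit$log_fixef))
  }
  lpar <- stats::setNames(fit$log_fixef + eta, names(fit$log_fixef))
  theta <- .theta_from_log(fit$model, lpar)
  pid <- if ("patient_id" %in% names(patient_records))
    as.character(patient_records$patient_id[1]) else NA_character_
  list(patient_id = pid,
       params = soef_params(theta[1], theta[2], theta[3], a1 = theta[4],
                            model = fit$model),
       eta = stats::setNames(eta, names(fit$log_fixef)),
       tia_h = .soef_tia_theta(theta))
}

# ---- Laplace objective evaluator ------------------------------------------

#' Approximate -2 log marginal likelihood at given population parameters
#'
#' Evaluates the Laplace approximation of the marginal likelihood of a
#' record set at an arbitrary population parameter vector (log fixed
#' effects, diagonal log-scale variances, residual SD). Used to compare the
#' returned estimate against multi-start initial points; it is independent
#' of the estimation path.
#'
#' @param records Records data frame.
#' @param model `"a4c"` or `"a3b"`.
#' @param log_fixef Named log-scale fixed effects (`ll1`, `ll2`, `ll3`, and
#'   `lla1` for `"a4c"`).
#' @param omega Named log-scale variances (`lambda1` ... `a1`).
#' @param sigma Residual SD.
#' @param error_model As in [fit_config()].
#' @param sigma_const Constant of the combined error model.
#' @return The approximate -2 log marginal likelihood (scalar).
#' @export
laplace_m2ll <- function(records, model, log_fixef, omega, sigma,
                         error_model = "proportional", sigma_const = 0) {
  fitlike <- structure(list(model = model, error_model = error_model,
                            log_fixef = log_fixef, omega = omega,
                            sigma = sigma, sigma_const = sigma_const),
                       class = "population_fit")
  ids <- unique(as.character(records$patient_id))
  omega_v <- .omega_map(fitlike)
  free <- which(omega_v > 0)
  total <- 0
  for (pid in ids) {
    pr <- records[records$patient_id == pid, , drop = FALSE]
    t_h <- pr$time_h; y <- pr$retention
    if (error_model == "proportional") {
      keep <- y > 0; t_h <- t_h[keep]; y <- y[keep]
      if (!length(y)) next
    }
    if (!length(free)) {
      total <- total + .map_objective(numeric(0), integer(0), fitlike, t_h, y)
      next
    }
    opt <- stats::nlminb(numeric(length(free)), .map_objective,
                         free = free, fit = fitlike, t_h = t_h, y = y,
                         control = list(iter.max = 500))
    h <- stats::optimHess(opt$par, function(e)
      .map_objective(e, free, fitlike, t_h, y) / 2)
    ld <- determinant(h, logarithm = TRUE)
    ldet <- if (ld$sign > 0) as.numeric(ld$modulus) else 0  # guard: PSD in practice
    total <- total + opt$objective - length(free) * log(2 * pi) + ldet
  }
  total
}
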