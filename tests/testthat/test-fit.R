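# Population fitting: multi-start machinery, recovery, empirical Bayes.

test_that("random starts are log-uniform within bounds and seeded", {
  b <- default_start_bounds()
  s <- random_starts(1000, b, seed = 3L)
  expect_equal(dim(s), c(1000L, 4L))
  for (j in 1:4) {
    expect_true(all(s[, j] >= b[j, 1] & s[, j] <= b[j, 2]))
  }
  expect_identical(s, random_starts(1000, b, seed = 3L))
  expect_false(identical(s, random_starts(1000, b, seed = 4L)))
  expect_equal(nrow(random_starts(1, b, seed = 1L)), 1L)
  bad <- b; bad[1, ] <- rev(bad[1, ])
  expect_error(random_starts(10, bad), "inverted")
  expect_error(random_starts(10, -b), "positive")
})

test_that("a homogeneous noise-free cohort is recovered almost exactly", {
  pop <- small_population(n = 20, iiv_cv = 0, prop = 0, add = 0)
  pop$residual_model$type <- "proportional"
  coh <- generate_cohort(pop)
  fit <- fit_population(coh$records, "a4c", quick_config())
  est <- with(fit$fixed_effects, c(lambda1, lambda2, lambda3, a1))
  expect_true(all(relerr(est, typical_vector(pop)) < 1e-2))
  expect_true(fit$converged)
})

test_that("degenerate inputs are rejected", {
  coh <- generate_cohort(small_population(n = 4))
  one <- coh$records[coh$records$patient_id == "P001", ]
  expect_error(fit_population(one, "a4c", quick_config()), "at least 2")
  zero <- coh$records; zero$retention <- 0
  expect_error(fit_population(zero, "a4c", quick_config()), "zero")
})

test_that("the fit is deterministic given records, config and seed", {
  coh <- generate_cohort(small_population(n = 10, seed = 77L))
  cfg <- quick_config(seed = 5L)
  f1 <- fit_population(coh$records, "a4c", cfg)
  f2 <- fit_population(coh$records, "a4c", cfg)
  expect_identical(f1$log_fixef, f2$log_fixef)
  expect_identical(f1$objective, f2$objective)
  expect_identical(f1$omega, f2$omega)
  expect_identical(f1$individual, f2$individual)
})

test_that("individual estimates carry analytic TIAs of their parameters", {
  coh <- generate_cohort(small_population(n = 10, seed = 78L))
  fit <- fit_population(coh$records, "a4c", quick_config())
  ind <- individual_estimates(fit)
  tia_re <- mapply(function(l1, l2, l3, a1)
    soef_tia(soef_params(l1, l2, l3, a1 = a1)),
    ind$lambda1, ind$lambda2, ind$lambda3, ind$a1)
  expect_equal(ind$tia_h, unname(tia_re), tolerance = 1e-12)
})

test_that("empirical Bayes collapses to the typical values when omega is zero", {
  coh <- degenerate_cohort(n = 6)
  fit <- fit_population(coh$records, "a4c", quick_config())
  expect_equal(fit$engine, "pooled")       # zero-variance cohort
  eb <- empirical_bayes(fit, coh$records[coh$records$patient_id == "P002", ])
  expect_equal(with(eb$params, c(lambda1, lambda2, lambda3, a1)),
               with(fit$fixed_effects, c(lambda1, lambda2, lambda3, a1)),
               tolerance = 1e-12)
  expect_error(empirical_bayes(fit, coh$records[0, ]), "no observations")
})

test_that("with a diffuse prior the MAP estimate approaches the patient's own fit", {
  # rich noise-free data for one patient, population prior centred elsewhere
  truth <- c(lambda1 = 0.06, lambda2 = 0.03, lambda3 = 0.002, a1 = 0.08)
  times <- c(1, 2, 4, 6, 12, 24, 48, 72, 96, 120, 168)
  y <- stpdosim:::.soef_eval(unname(truth), times)
  pr <- data.frame(patient_id = "X", time_h = times, retention = y)

  base <- list(model = "a4c", error_model = "proportional",
               log_fixef = stats::setNames(log(c(0.04, 0.04, 0.0015, 0.05)),
                                           c("ll1", "ll2", "ll3", "lla1")),
               sigma = 0.1, sigma_const = 0)
  omega_wide <- stats::setNames(rep(25, 4),
                                c("lambda1", "lambda2", "lambda3", "a1"))
  fit_wide <- structure(c(base, list(omega = omega_wide)),
                        class = "population_fit")
  eb <- empirical_bayes(fit_wide, pr)
  est <- with(eb$params, c(lambda1, lambda2, lambda3, a1))
  expect_true(all(relerr(est, unname(truth)) < 2e-2))

  # tightening the prior monotonically shrinks the deviation from the
  # population mode (the parameters move from the individual fit towards
  # the prior as omega decreases)
  eta_norm <- function(w) {
    om <- stats::setNames(rep(w, 4), c("lambda1", "lambda2", "lambda3", "a1"))
    f <- structure(c(base, list(omega = om)), class = "population_fit")
    sqrt(sum(empirical_bayes(f, pr)$eta^2))
  }
  norms <- vapply(c(25, 0.5, 0.02, 1e-5), eta_norm, numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[4], 0.2 * norms[1])
})

test_that("a single observation shrinks the prediction towards the data", {
  coh <- generate_cohort(small_population(n = 10, seed = 30L))
  fit <- fit_population(coh$records, "a4c", quick_config())
  expect_true(fit$engine != "pooled")  # informative fit, not the degenerate rung
  obs_t <- 48
  prior_pred <- soef_retention(fit$fixed_effects, obs_t)
  y <- prior_pred * 1.6                      # observation above the prior
  eb <- empirical_bayes(fit, data.frame(patient_id = "new", time_h = obs_t,
                                        retention = y))
  post_pred <- soef_retention(eb$params, obs_t)
  expect_gt(post_pred, prior_pred)           # moved towards the observation
  expect_lt(post_pred, y)                    # but not beyond it
})

test_that("the returned objective beats every refined multi-start point", {
  coh <- generate_cohort(small_population(n = 10, seed = 91L))
  cfg <- quick_config(seed = 8L)
  fit <- fit_population(coh$records, "a4c", cfg)
  expect_true(fit$engine != "pooled")  # informative fit, not the degenerate rung
  m2ll_at <- function(lf) laplace_m2ll(
    coh$records[coh$records$retention > 0, ], "a4c", lf,
    fit$omega, fit$sigma, error_model = "proportional")
  final <- m2ll_at(fit$log_fixef)
  starts <- random_starts(cfg$n_starts, cfg$start_bounds, cfg$seed)
  ord <- order(stpdosim:::.screen_objective(coh$records, "a4c", starts,
                                            "proportional"))
  for (i in utils::head(ord, cfg$n_refine)) {
    lf <- stats::setNames(log(starts[i, ]), c("ll1", "ll2", "ll3", "lla1"))
    expect_lt(final, m2ll_at(lf))
  }
})

test_that("fitting the 4-parameter model on data without blood pool is honest", {
  pop <- small_population(n = 15, iiv_cv = 0.25, prop = 0.08, add = 0,
                          seed = 400L)
  pop$residual_model$type <- "proportional"
  pop$typical_params <- soef_params(0.04, 0.04, 0.0015, a1 = 0)
  coh <- generate_cohort(pop)
  cfg <- quick_config(seed = 12L)
  f4 <- fit_population(coh$records, "a4c", cfg)
  f3 <- fit_population(coh$records, "a3b", cfg)
  expect_lt(f4$fixed_effects$a1, 0.02)
  # nested models: the richer model cannot be substantially worse, and on
  # a1-free data it should not be substantially better either
  expect_lt(abs(f4$objective - f3$objective), 10)
})
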