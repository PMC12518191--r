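# Shared fixtures: small study populations built in code.

# A scaled-down version of the default study population.
small_population <- function(n = 12L, late_n = NULL, iiv_cv = 0.30,
                             prop = 0.10, add = 0.002, seed = 101L,
                             common_times = c(2, 6, 24, 48),
                             late_times = c(96, 120)) {
  if (is.null(late_n)) {
    n96 <- round(n * 53 / 73)
    late_n <- c(n96, n - n96)
  }
  type <- if (prop > 0 && add > 0) "combined"
          else if (add > 0 && prop == 0) "additive" else "proportional"
  population_truth(
    typical_params = soef_params(0.04, 0.04, 0.0015, a1 = 0.05),
    iiv_cv = iiv_cv,
    residual_model = list(type = type, prop = prop, add = add),
    common_times = common_times, late_times = late_times,
    late_n = as.integer(late_n), n = as.integer(n), seed = seed)
}

# Homogeneous, noise-free cohort: every patient is the typical patient.
degenerate_cohort <- function(n = 8L, seed = 55L, late_n = NULL) {
  pop <- small_population(n = n, late_n = late_n, iiv_cv = 0,
                          prop = 0, add = 0, seed = seed)
  pop$residual_model <- list(type = "proportional", prop = 0, add = 0)
  generate_cohort(pop)
}

# Fast fitting configuration for unit tests.
quick_config <- function(seed = 42L, ...) {
  fit_config(n_starts = 200L, n_refine = 3L, seed = seed, ...)
}

# Natural-scale typical parameter vector of a population.
typical_vector <- function(pop) {
  with(pop$typical_params,
       c(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3, a1 = a1))
}

relerr <- function(est, truth) abs(est - truth) / abs(truth)
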