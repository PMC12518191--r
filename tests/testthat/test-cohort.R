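# Synthetic cohort generator: design bookkeeping, noise model, truth.

test_that("record counts follow the schedule and cohort split", {
  pop <- population_truth(soef_params(0.04, 0.04, 0.0015, a1 = 0.05),
                          common_times = c(2, 6, 24, 48),
                          late_times = 120, late_n = 4L, n = 4L, seed = 9L)
  coh <- generate_cohort(pop)
  expect_equal(nrow(coh$records), 20L)   # 4 patients x 5 times
  expect_equal(nrow(coh$truth), 4L)

  expect_error(generate_cohort(pop, n_patients = 1), "at least 2")
  expect_error(population_truth(soef_params(0.1, 0.1, 0.001),
                                common_times = numeric(0),
                                late_times = numeric(0),
                                late_n = integer(0), n = 5L),
               "at least one measurement time")
  expect_error(population_truth(soef_params(0.1, 0.1, 0.001),
                                late_times = c(96, 120), late_n = c(3L, 3L),
                                n = 5L),
               "sum to n")
})

test_that("zero variability and zero noise reproduce the typical curve", {
  pop <- small_population(n = 5, iiv_cv = 0, prop = 0, add = 0)
  pop$residual_model$type <- "proportional"
  coh <- generate_cohort(pop)
  expected <- soef_retention(pop$typical_params, coh$records$time_h)
  expect_equal(coh$records$retention, expected, tolerance = 1e-15)
  expect_equal(coh$truth$tia_h, rep(soef_tia(pop$typical_params), 5),
               tolerance = 1e-15)
})

test_that("the emulated study design yields 364 records with the printed split", {
  coh <- study_design_cohort(seed = 1L)
  expect_equal(nrow(coh$records), 364L)
  counts <- table(coh$records$time_h)
  expect_equal(as.integer(counts[c("2", "6", "24", "48", "96", "120")]),
               c(73L, 72L, 73L, 73L, 53L, 20L))
  # truth is internally consistent: stored TIA equals the analytic TIA
  tia_re <- mapply(function(l1, l2, l3, a1)
    soef_tia(soef_params(l1, l2, l3, a1 = a1)),
    coh$truth$lambda1, coh$truth$lambda2, coh$truth$lambda3, coh$truth$a1)
  expect_equal(coh$truth$tia_h, unname(tia_re), tolerance = 1e-14)
})

test_that("generation is reproducible from the seed and leaves the RNG alone", {
  pop <- small_population(n = 6)
  a <- generate_cohort(pop)
  set.seed(777); before <- runif(3)
  set.seed(777)
  b <- generate_cohort(pop)            # must not disturb the RNG stream
  after <- runif(3)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  expect_identical(before, after)
  c2 <- generate_cohort(pop, seed = pop$seed + 1L)
  expect_false(identical(a$records$retention, c2$records$retention))
})

test_that("sampled parameter variability matches the configured CV", {
  pop <- small_population(n = 2000, late_n = c(1452L, 548L), iiv_cv = 0.30,
                          prop = 0, add = 0, seed = 2024L)
  pop$residual_model$type <- "proportional"
  coh <- generate_cohort(pop)
  for (par in c("lambda1", "lambda2", "lambda3", "a1")) {
    x <- coh$truth[[par]]
    cv <- sd(x) / mean(x)
    expect_lt(abs(cv - 0.30) / 0.30, 0.10)
  }
})

test_that("proportional noise magnitude is recovered from replicates", {
  pop <- population_truth(soef_params(0.04, 0.04, 0.0015, a1 = 0.05),
                          iiv_cv = 0,
                          residual_model = list(type = "proportional",
                                                prop = 0.10, add = 0),
                          common_times = 24, late_times = numeric(0),
                          late_n = integer(0), n = 2000L, seed = 31L)
  coh <- generate_cohort(pop)
  true24 <- soef_retention(pop$typical_params, 24)
  rel <- (coh$records$retention - true24) / true24
  expect_lt(abs(sd(rel) - 0.10) / 0.10, 0.10)
})

test_that("negative noisy observations are truncated at zero and flagged", {
  pop <- population_truth(soef_params(0.04, 0.04, 0.0015, a1 = 0.0),
                          iiv_cv = 0,
                          residual_model = list(type = "additive",
                                                prop = 0, add = 0.5),
                          common_times = c(2, 24), late_times = numeric(0),
                          late_n = integer(0), n = 50L, seed = 5L)
  coh <- generate_cohort(pop)
  expect_true(any(coh$records$truncated))
  expect_true(all(coh$records$retention >= 0))
  expect_true(all(coh$records$retention[coh$records$truncated] == 0))
})

test_that("the default population's noise-free curve peaks between 6 h and 96 h", {
  pop <- default_population()
  grid <- seq(0.1, 300, by = 0.1)
  vals <- soef_retention(pop$typical_params, grid)
  tmax <- grid[which.max(vals)]
  expect_gt(tmax, 6); expect_lt(tmax, 96)
  expect_gt(max(vals), 0.3); expect_lt(max(vals), 0.6)
})

test_that("the default population round-trips through config serialization", {
  cfg <- run_config(seed = 17L)
  back <- yaml::yaml.load(yaml::as.yaml(stpdosim:::.serialize_config(cfg)))
  pop <- cfg$population
  expect_equal(back$population$typical$lambda1, pop$typical_params$lambda1)
  expect_equal(back$population$typical$lambda3, pop$typical_params$lambda3)
  expect_equal(unlist(back$population$iiv_cv), pop$iiv_cv)
  expect_equal(back$population$residual$prop, pop$residual_model$prop)
  expect_equal(back$population$common_times, pop$common_times)
  expect_equal(back$population$late_n, pop$late_n)
  expect_equal(back$seed, 17L)
})
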