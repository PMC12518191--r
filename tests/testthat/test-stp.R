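# STP dosimetry workflow: reference, single-time-point and population TIAs.

test_that("TIA estimate tables enforce method/time-point consistency", {
  expect_error(tia_estimates("P1", "s1TIA", NA, 50), "must record")
  expect_error(tia_estimates("P1", "rTIA", 24, 50), "must not carry")
  expect_error(tia_estimates("P1", "rTIA", NA, -1), "> 0")
  expect_error(tia_estimates("P1", "xTIA", NA, 50), "unknown")
  ok <- tia_estimates(c("P1", "P2"), "hTIA", c(24, 48), c(90, 95))
  expect_s3_class(ok, "tia_estimates")
})

test_that("a homogeneous noise-free cohort gives rTIA = sTIA = nTIA = truth", {
  coh <- degenerate_cohort(n = 8, late_n = c(5L, 3L))
  truth_tia <- coh$truth$tia_h[1]
  cfg <- quick_config()

  refs <- compute_reference_tias(coh$records, cfg)
  expect_true(all(relerr(refs$tia_h, truth_tia) < 1e-3))
  fit <- attr(refs, "fit")

  grid <- run_stp_grid(coh$records, "a4c", time_points = c(2, 24, 120),
                       config = cfg, ref_fit = fit)
  expect_true(all(relerr(grid$tia_h, truth_tia) < 1e-3))

  ntias <- ntp_tia(fit)
  expect_equal(nrow(ntias), 8L)
  expect_true(all(relerr(ntias$tia_h, truth_tia) < 1e-3))
})

test_that("the STP dataset keeps exactly one observation of the target", {
  coh <- generate_cohort(small_population(n = 6, seed = 202L))
  cfg <- quick_config()
  fit <- fit_population(coh$records, "a4c", cfg)
  warm <- with(fit$fixed_effects, c(lambda1, lambda2, lambda3, a1))
  est <- stp_fit(coh$records, "P004", 48, "a4c", cfg, warm_start = warm)
  audit <- attr(est, "audit")
  expect_identical(audit$n_target_obs, 1L)
  n_other <- sum(coh$records$patient_id != "P004")
  expect_identical(audit$n_obs_total, n_other + 1L)
  expect_identical(est$method, "s1TIA")
  expect_identical(est$time_point_h, 48)

  s2 <- stp_fit(coh$records, "P004", 48, "a3b", cfg, warm_start = warm)
  expect_identical(s2$method, "s2TIA")

  expect_error(stp_fit(coh$records, "P004", 37, "a4c", cfg),
               "no observation at")
  expect_error(stp_fit(coh$records, "nobody", 48, "a4c", cfg),
               "unknown target")
})

test_that("the grid skips patients lacking a time point and audits each cell", {
  coh <- generate_cohort(small_population(n = 6, late_n = c(4L, 2L),
                                          seed = 203L))
  cfg <- quick_config()
  grid <- run_stp_grid(coh$records, "a4c", time_points = c(48, 120),
                       config = cfg)
  log <- attr(grid, "log")
  expect_equal(sum(grid$time_point_h == 48), 6L)
  expect_equal(sum(grid$time_point_h == 120), 2L)   # late subgroup only
  expect_true(all(log$n_target_obs == 1L))
  expect_error(run_stp_grid(coh$records, "a4c", time_points = 72,
                            config = cfg), "never observed")
  expect_error(run_stp_grid(coh$records, "a4c", time_points = numeric(0),
                            config = cfg), "empty")
})

test_that("grid cell counts reproduce the emulated design bookkeeping", {
  coh <- study_design_cohort(seed = 2L)
  counts <- stp_grid_counts(coh$records, c(2, 6, 24, 48, 96, 120))
  expect_equal(unname(counts), c(73L, 72L, 73L, 73L, 53L, 20L))
})

test_that("frozen-prior mode approximates the joint refit", {
  coh <- generate_cohort(small_population(n = 10, seed = 204L))
  cfg <- quick_config()
  fit_all <- fit_population(coh$records, "a4c", cfg)
  warm <- with(fit_all$fixed_effects, c(lambda1, lambda2, lambda3, a1))
  joint <- stp_fit(coh$records, "P003", 48, "a4c", cfg, warm_start = warm)
  others <- coh$records[coh$records$patient_id != "P003", ]
  ref_others <- fit_population(others, "a4c", cfg)
  frozen <- stp_fit(coh$records, "P003", 48, "a4c", cfg,
                    mode = "frozen_prior", ref_fit = ref_others)
  expect_lt(abs(joint$tia_h - frozen$tia_h) / joint$tia_h, 0.25)
})

test_that("nTIA is the analytic TIA of the mean individual parameters", {
  coh <- generate_cohort(small_population(n = 8, seed = 205L))
  fit <- fit_population(coh$records, "a4c", quick_config())
  ind <- individual_estimates(fit)
  mean_theta <- colMeans(as.matrix(ind[, c("lambda1", "lambda2",
                                           "lambda3", "a1")]))
  expected <- soef_tia(soef_params(mean_theta[["lambda1"]],
                                   mean_theta[["lambda2"]],
                                   mean_theta[["lambda3"]],
                                   a1 = mean_theta[["a1"]]))
  ntias <- ntp_tia(fit)
  expect_equal(unique(ntias$tia_h), expected, tolerance = 1e-12)
})

test_that("s1TIA and s2TIA agree when there is no blood-pool signal", {
  # Monte-Carlo noise on the two population fits shrinks with cohort size;
  # the late time point is the one that pins the TIA in both models.
  pop <- small_population(n = 16, late_n = c(8L, 8L), iiv_cv = 0.25,
                          prop = 0.08, add = 0, seed = 206L)
  pop$residual_model$type <- "proportional"
  pop$typical_params <- soef_params(0.04, 0.04, 0.0015, a1 = 0)
  coh <- generate_cohort(pop)
  cfg <- quick_config()
  g1 <- run_stp_grid(coh$records, "a4c", time_points = 120, config = cfg)
  g2 <- run_stp_grid(coh$records, "a3b", time_points = 120, config = cfg)
  m <- merge(as.data.frame(g1), as.data.frame(g2), by = "patient_id")
  expect_lt(median(abs(m$tia_h.x - m$tia_h.y) / m$tia_h.x), 0.05)
})

test_that("jackknife spread is zero for identical patients and counts are right", {
  coh <- degenerate_cohort(n = 5, late_n = c(3L, 2L))
  cfg <- quick_config()
  rep120 <- jackknife_validate(coh$records, "a4c", time_points = 48,
                               config = cfg)
  expect_equal(nrow(rep120), 5L)
  expect_true(all(rep120$n_replicates == 4L))
  expect_true(all(rep120$n_target_obs == 1L))
  expect_true(all(rep120$tia_sd / rep120$tia_h < 1e-6))

  two <- coh$records[coh$records$patient_id %in% c("P001", "P002"), ]
  expect_error(jackknife_validate(two, "a4c", time_points = 48,
                                  config = cfg), "at least 3")
})
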