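# Strain arithmetic --------------------------------------------------------

test_that("strain and repeat-baseline difference follow their definitions", {
  expect_equal(compute_strain(2.0, 2.0), 0)
  expect_equal(compute_strain(2.0, 1.9), -5)
  expect_equal(compute_strain(2.0, 2.1), 5) # swelling is not clamped
  expect_error(compute_strain(0, 1), "positive")
  expect_equal(thickness_difference(2.00, 2.00), 0)
  expect_equal(thickness_difference(2.00, 2.01), 0.5)
  expect_error(thickness_difference(-1, 1), "positive")
  # mean over repeats = mean of pairwise differences
  reps <- c(2.01, 1.99, 2.02)
  expect_equal(mean(thickness_difference(2, reps)),
               mean(sapply(reps, function(h) thickness_difference(2, h))))
})

test_that("strain trajectories validate their time axis", {
  expect_error(strain_trajectory(c(10, 10, 20), c(-4, -3, -2)),
               "strictly increasing")
  expect_error(strain_trajectory(c(0, 10, 20), c(-4, -3, -2)), "> 0")
  expect_error(strain_trajectory(c(10, 20), c(-4, NA)), "finite")
})

# Kelvin-Voigt fit ----------------------------------------------------------

test_that("noiseless Kelvin-Voigt data are recovered exactly", {
  t <- c(10, 20, 30, 40, 50)
  fit <- fit_kelvin_voigt(strain_trajectory(t, -5 * exp(-0.04 * t)))
  expect_true(fit$converged)
  expect_equal(fit$A, -5, tolerance = 1e-6)
  expect_equal(fit$B, 0.04, tolerance = 1e-6)
  expect_equal(fit$characteristic_recovery_time, 25, tolerance = 1e-6)
  expect_identical(fit$characteristic_recovery_time, 1 / fit$B)
  expect_lt(fit$rmse, 1e-8)
})

test_that("noiseless fits recover a whole (A, B) parameter grid", {
  t <- c(10, 20, 30, 40, 50)
  for (A in c(-8, -4.5, -1)) {
    for (B in c(0.01, 0.05, 0.2)) {
      fit <- fit_kelvin_voigt(strain_trajectory(t, A * exp(-B * t)))
      expect_lt(abs(fit$A - A) / abs(A), 1e-6)
      expect_lt(abs(fit$B - B) / B, 1e-6)
    }
  }
})

test_that("measurement-scale noise perturbs 1/B only moderately", {
  # Monte-Carlo oracle: 0.2%-scale Gaussian noise (the repeatability of
  # the thickness technique) on a 25-min trajectory
  t <- c(10, 20, 30, 40, 50)
  truth <- -5 * exp(-0.04 * t)
  set.seed(42)
  rec <- replicate(1000, {
    fit <- fit_kelvin_voigt(strain_trajectory(t, truth + rnorm(5, 0, 0.2)))
    fit$characteristic_recovery_time
  })
  expect_lt(abs(median(rec) - 25) / 25, 0.15)
})

test_that("degenerate trajectories are flagged, not fatal", {
  t <- c(10, 20, 30, 40, 50)
  expect_error(fit_kelvin_voigt(strain_trajectory(t[1:2], c(-4, -3))),
               "at least 3")
  expect_error(fit_kelvin_voigt(strain_trajectory(t, rep(0, 5))), "zero")
  # constant nonzero strain: B driven to its lower bound
  fit <- suppressWarnings(
    fit_kelvin_voigt(strain_trajectory(t, rep(-3, 5))))
  expect_false(fit$converged)
})

test_that("offset variant reduces to the default when the offset is zero", {
  t <- c(10, 20, 30, 40, 50)
  traj <- strain_trajectory(t, -5 * exp(-0.04 * t))
  fit <- fit_kelvin_voigt(traj, offset = TRUE)
  expect_equal(fit$offset, 0, tolerance = 1e-4)
  expect_equal(fit$B, 0.04, tolerance = 1e-3)
})

# Cohort aggregation --------------------------------------------------------

test_that("cohort mean handles shared grids and missing scans", {
  t <- c(10, 20, 30, 40, 50)
  tr1 <- strain_trajectory(t, -5 * exp(-0.04 * t))
  expect_equal(cohort_mean_trajectory(list(tr1, tr1))$strains, tr1$strains)
  # subject 2 misses the 40-min point (motion artifact case)
  tr2 <- strain_trajectory(t[-4], -4 * exp(-0.05 * t[-4]))
  cm <- cohort_mean_trajectory(list(tr1, tr2))
  expect_equal(cm$n, c(2L, 2L, 2L, 1L, 2L))
  expect_equal(cm$strains[4], tr1$strains[4])
  expect_equal(cm$strains[1], mean(c(tr1$strains[1], tr2$strains[1])))
  # simple two-value mean
  a <- strain_trajectory(10, -4); b <- strain_trajectory(10, -2)
  expect_equal(cohort_mean_trajectory(list(a, b))$strains, -3)
})

# Froude-normalised walking speed -------------------------------------------

test_that("walking speed follows the Froude relation", {
  expect_equal(froude_walk_speed(0.25, 0.9), sqrt(0.25 * 0.9 * 9.81))
  expect_equal(froude_walk_speed(0.25, 0.9), 1.486, tolerance = 1e-3)
  expect_error(froude_walk_speed(0, 0.9), "positive")
  expect_error(froude_walk_speed(0.25, -1), "positive")
  # v ~ sqrt(L) at fixed Fr
  expect_equal(froude_walk_speed(0.25, 4 * 0.9),
               2 * froude_walk_speed(0.25, 0.9), tolerance = 1e-12)
})

# Biphasic model -------------------------------------------------------------

test_that("biphasic creep series is normalised, bounded and monotone", {
  p <- biphasic_parameters(2.27, 0.65, 2.00e-15, sigma0 = 0.1,
                           units = "mm_MPa")
  expect_lt(abs(biphasic_strain(p, 0)), 1e-10)
  eq <- -p$sigma0 / p$H_A
  expect_equal(biphasic_strain(p, 50 * time_constant(p)), eq,
               tolerance = 1e-9)
  tt <- seq(0, 5 * time_constant(p), length.out = 400)
  eps <- biphasic_strain(p, tt)
  expect_true(all(diff(eps) <= 1e-15))
  expect_true(all(eps >= eq - 1e-12))
})

test_that("time constant and characteristic time follow the h^2/(H_A k) law", {
  p <- biphasic_parameters(2.27e-3, 0.65e6, 2.00e-15)
  expect_equal(time_constant(p), 2.27e-3^2 / (0.65e6 * 2.00e-15))
  expect_equal(time_constant(p), 3964, tolerance = 1e-3)
  # doubling h quadruples tau
  p2 <- biphasic_parameters(2 * 2.27e-3, 0.65e6, 2.00e-15)
  expect_equal(time_constant(p2), 4 * time_constant(p), tolerance = 1e-12)
  # tau0 / tau = 4 / pi^2, and the mm/MPa constructor agrees with SI
  for (h in c(1e-3, 2.27e-3, 3.12e-3)) {
    pp <- biphasic_parameters(h, 0.79e6, 4.7e-15)
    expect_equal(characteristic_time(pp) * 60 / time_constant(pp),
                 4 / pi^2, tolerance = 1e-12)
  }
  p_mm <- biphasic_parameters(2.27, 0.65, 2.00e-15, units = "mm_MPa")
  expect_equal(time_constant(p_mm), time_constant(p), tolerance = 1e-12)
  expect_error(biphasic_parameters(-1, 1, 1), "positive")
})

test_that("Kelvin-Voigt is the one-term truncation of the biphasic series", {
  p <- biphasic_parameters(2.27, 0.65, 2.00e-15, sigma0 = 0.1,
                           units = "mm_MPa")
  tau <- time_constant(p)
  M0 <- pi^2 * 0.25
  B <- M0 / tau
  A <- (p$sigma0 / p$H_A) * (2 / M0)
  const <- -p$sigma0 / p$H_A
  tt <- seq(0.01 * tau, 3 * tau, length.out = 50) # t > 0: truncation regime
  one_term <- biphasic_strain(p, tt, n_terms = 1)
  expect_equal(one_term, A * exp(-B * tt) + const, tolerance = 1e-12)
})
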