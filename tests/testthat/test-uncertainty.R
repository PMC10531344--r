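make_quick_fit <- function(seed = 41) {
  cs <- generate_curve_set(small_design(reps = 2, duration = 1200),
                           seed = seed)
  fit_kinetics(cs, "no_ligation",
               settings = fit_settings(seed = 1, joint_maxiter = 15,
                                       ess = ess_settings(n_sample = 16,
                                                          n_recombine = 6,
                                                          n_polish = 1)))
}

test_that("residual resampling preserves the design and the residual scale", {
  fit <- make_quick_fit()
  bs1 <- residual_resample(fit, seed = 5)
  bs2 <- residual_resample(fit, seed = 5)
  expect_identical(bs1$observations, bs2$observations)  # seeded determinism
  expect_identical(bs1$meta, fit$curves$meta)
  expect_identical(bs1$observations$time_s, fit$curves$observations$time_s)
  # across many draws the resampled residual variance matches the original
  set.seed(9)
  v <- replicate(100, {
    b <- residual_resample(fit)
    var(b$observations$conc_nm - fit$residuals$fitted)
  })
  expect_rel_equal(mean(v), var(fit$residuals$residual), 0.1)
})

test_that("zero residuals reproduce the fitted curves exactly", {
  fit <- make_quick_fit()
  fit$residuals$residual <- 0
  fit$curves$observations$conc_nm <- fit$residuals$fitted
  bs <- residual_resample(fit, seed = 1)
  expect_equal(bs$observations$conc_nm, fit$residuals$fitted)
})

test_that("bootstrap intervals are reproducible, ordered, and tighten on
           near-noiseless data", {
  fit <- make_quick_fit()
  boot <- bootstrap_ci(fit, n_boot = 8, seed = 11)
  expect_true(all(boot$ci$lower <= boot$ci$upper))
  expect_equal(unname(diag(boot$correlation)), rep(1, ncol(boot$draws)))
  expect_equal(boot$correlation, t(boot$correlation))
  boot2 <- bootstrap_ci(fit, n_boot = 8, seed = 11)
  expect_identical(boot$draws, boot2$draws)

  # percentile CIs are equivariant under monotone reparameterization:
  # the CI of the log-parameter is the log of the CI
  for (p in colnames(boot$draws)) {
    q_nat <- quantile(boot$draws[, p], c(0.025, 0.975), type = 1)
    q_log <- quantile(log(boot$draws[, p]), c(0.025, 0.975), type = 1)
    expect_equal(unname(log(q_nat)), unname(q_log), tolerance = 1e-10)
    expect_equal(unname(q_nat),
                 c(boot$ci$lower[boot$ci$parameter == p],
                   boot$ci$upper[boot$ci$parameter == p]), tolerance = 1e-12)
  }
})

test_that("Monte Carlo band collapses for degenerate errors and normalizes
           its densities", {
  r <- reference_rates()
  times <- seq(30, 900, 30)
  band <- monte_carlo_predict(r, err_s_pool = 1, err_e_pool = 1,
                              s0 = 400, e0 = 10, times = times,
                              n_draws = 50, seed = 3)
  expect_lt(max(band$band$upper - band$band$lower), 1e-9)
  # per-time frequencies sum to one (density contract)
  expect_equal(rowSums(band$density$freq), rep(1, length(times)))
  expect_true(all(band$density$freq >= 0))

  # spread errors widen the band monotonically with the pool spread
  set.seed(4)
  band2 <- monte_carlo_predict(r, err_s_pool = c(0.9, 1, 1.1),
                               err_e_pool = c(0.7, 1, 1.4),
                               s0 = 400, e0 = 10, times = times,
                               n_draws = 200, seed = 3)
  expect_gt(mean(band2$band$upper - band2$band$lower), 1)
  expect_identical(
    monte_carlo_predict(r, c(0.9, 1.1), c(0.8, 1.2), 400, 10, times,
                        n_draws = 20, seed = 6)$draws,
    monte_carlo_predict(r, c(0.9, 1.1), c(0.8, 1.2), 400, 10, times,
                        n_draws = 20, seed = 6)$draws)
})

test_that("band coverage counts points inside the envelope", {
  r <- reference_rates()
  times <- seq(30, 600, 30)
  band <- monte_carlo_predict(r, c(0.9, 1, 1.1), c(0.8, 1, 1.2),
                              s0 = 400, e0 = 10, times = times,
                              n_draws = 200, seed = 2)
  centre <- simulate_reaction(r, 400, 10, times)$observable
  expect_equal(band_coverage(band, times, centre), 1)
  expect_equal(band_coverage(band, times, centre + 1e6), 0)
})
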