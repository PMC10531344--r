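env_truth <- function() {
  environment_params(
    arrhenius = list(k_off = list(e_a = 9e4), k_clv = list(e_a = 8e4),
                     k_rls = list(e_a = 6e4)),
    mg = list(k_on = list(a = 5e-4, b = 8e-3, c = 0.02),
              k_clv = list(a = 0, b = 0.35, c = 0.04),
              k_rls = list(a = 4, b = 34, c = 0.30)),
    map = dependency_map(), t_ref = 328.15)
}

test_that("single-temperature data leave the activation energy
           unidentifiable", {
  cs <- exact_curve_set(levels = c(250, 1000), times = seq(30, 600, 30))
  expect_error(fit_arrhenius(cs, reference_rates()), "3 temperatures")
})

test_that("activation energies are recovered from a multi-temperature
           series", {
  set.seed(51)
  cs <- generate_condition_series(
    temperatures_c = c(50, 55, 60),
    design = experiment_design(substrate_nm = c(250, 1000), replicates = 1,
                               duration_s = 1200),
    env = env_truth(),
    noise = noise_model(err_s_sdlog = 0.01, err_e_sdlog = 0.01,
                        err_e_sdlog_low = 0.01, read_noise_frac = 0.01),
    seed = 51)
  fit <- fit_arrhenius(cs, reference_rates(),
                       settings = fit_settings(
                         seed = 5, ess = ess_settings(n_sample = 16,
                                                      n_recombine = 6,
                                                      n_polish = 1)))
  truth_ea <- c(k_off = 9e4, k_clv = 8e4, k_rls = 6e4)
  # cleavage dominates the output, so its activation energy is the one a
  # small design pins down; the weakly influential steps must at least be
  # statistically consistent with the truth
  expect_lt(abs(fit$e_a[["k_clv"]] / truth_ea[["k_clv"]] - 1), 0.25)
  for (nm in c("k_off", "k_rls"))
    expect_lt(abs(fit$e_a[[nm]] - truth_ea[[nm]]), 4 * fit$e_a_sd[[nm]])
  # the staged objective decreases through the stages
  expect_true(all(diff(fit$stage_rmse) <= 1e-8))
  # temperatures outside the calibrated window warn
  cs2 <- cs
  cs2$meta$temperature_c[cs2$meta$temperature_c == 50] <- 40
  cs2$observations$curve_id <- cs2$observations$curve_id  # unchanged
  expect_warning(
    fit_arrhenius(cs2, reference_rates(),
                  settings = fit_settings(
                    seed = 5, ess = ess_settings(n_sample = 8,
                                                 n_recombine = 2,
                                                 n_polish = 0),
                    lm_maxiter = 4)),
    "extrapolation")
})

test_that("magnesium laws are recovered with the saturation ordering
           preserved", {
  set.seed(61)
  cs <- generate_condition_series(
    mg_mm = c(2, 10, 20, 60, 100),
    design = experiment_design(substrate_nm = c(100, 500, 1000),
                               replicates = 1, duration_s = 1200),
    env = env_truth(),
    noise = noise_model(err_s_sdlog = 0.01, err_e_sdlog = 0.01,
                        err_e_sdlog_low = 0.01, read_noise_frac = 0.01),
    seed = 61)
  fit <- fit_mg(cs, reference_rates(),
                settings = fit_settings(
                  seed = 6, ess = ess_settings(n_sample = 16,
                                               n_recombine = 6,
                                               n_polish = 1)))
  # release saturates at much lower Mg2+ than association and cleavage
  expect_gt(fit$mg_laws$k_rls$c, fit$mg_laws$k_on$c)
  expect_gt(fit$mg_laws$k_rls$c, fit$mg_laws$k_clv$c)
  expect_equal(fit$mg_laws$k_clv$a, 0)  # no cleavage without the cofactor
  # fitted cleavage law reproduces the generating law where the data are
  # informative (mid-to-high Mg; the 2 mmol/L value is hypersensitive to c)
  for (mg in c(20, 60, 100)) {
    want <- mg_rate(mg, 0, 0.35, 0.04, "increasing")
    got <- mg_rate(mg, fit$mg_laws$k_clv$a, fit$mg_laws$k_clv$b,
                   fit$mg_laws$k_clv$c, "increasing")
    expect_lt(abs(got / want - 1), 0.25)
  }
})

test_that("degenerate magnesium designs are rejected", {
  cs <- exact_curve_set(levels = c(250, 1000), times = seq(30, 600, 30))
  expect_error(fit_mg(cs, reference_rates()), "3 concentrations")
})

test_that("without Mg2+ no product is generated", {
  base <- reference_rates()
  env <- env_truth()
  r0 <- resolve_rates(base, env, mg_mm = 0)
  expect_equal(r0[["k_clv"]], 0)
  tr <- simulate_reaction(r0, 500, 10, seq(0, 900, 30))
  expect_lt(max(tr$observable), 1e-8)
})
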