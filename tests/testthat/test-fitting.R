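test_that("pooled RMSE objective behaves like a proper loss", {
  cs <- exact_curve_set(levels = c(250, 1000), times = seq(30, 900, 30))
  # evaluated at the generating parameters the misfit is solver noise only
  expect_lt(objective_rmse(cs, reference_rates()), 1e-5)
  # a constant offset delta shows up as RMSE = delta
  cs2 <- cs
  cs2$observations$conc_nm <- cs2$observations$conc_nm + 5
  expect_equal(objective_rmse(cs2, reference_rates()), 5, tolerance = 1e-4)
  # invariance to curve order / replicate relabeling
  perm <- sample(nrow(cs$observations))
  cs3 <- curve_set(cs$observations[perm, ], cs$meta[rev(seq_len(nrow(cs$meta))), ])
  expect_equal(objective_rmse(cs3, reference_rates()),
               objective_rmse(cs, reference_rates()), tolerance = 1e-12)
})

test_that("scatter search improves on the incumbent, is deterministic, and
           finds a displaced minimum", {
  # 3-parameter quadratic in log space with minimum one decade from init
  target <- c(a = 10, b = 0.1, c = 1)
  obj <- function(p) sum((log10(p) - log10(target))^2)
  init <- c(a = 1, b = 1, c = 1)
  s1 <- scatter_search(obj, init, settings = ess_settings(n_sample = 60),
                       seed = 7)
  s2 <- scatter_search(obj, init, settings = ess_settings(n_sample = 60),
                       seed = 7)
  expect_identical(s1$candidates, s2$candidates)
  expect_lte(s1$best_objective, obj(init))
  # dense-grid oracle over the box confirms the found minimum
  grid <- as.matrix(expand.grid(a = 10^seq(-2, 2, 0.1),
                                b = 10^seq(-2, 2, 0.1),
                                c = 10^seq(-2, 2, 0.1)))
  best_grid <- grid[which.min(apply(grid, 1, obj)), ]
  expect_lt(max(abs(log10(s1$best_par) - log10(best_grid))), 0.15)
  # different seed gives a different candidate set
  s3 <- scatter_search(obj, init, settings = ess_settings(n_sample = 60),
                       seed = 8)
  expect_false(identical(s1$candidates, s3$candidates))
})

test_that("least-squares refinement solves a linear model exactly", {
  x <- seq(0, 10, 0.5)
  y <- 3.7 * x
  ref <- refine_least_squares(function(b) y - b * x, init = c(beta = 1))
  expect_equal(unname(ref$par), 3.7, tolerance = 1e-8)
  expect_lt(ref$rss, 1e-12)
  expect_true(ref$converged)
})

test_that("error terms are recovered from curves with known mislabeling", {
  # curves generated with ErrS = 0.9, ErrE = 1.5 plus 2% read noise
  truth <- reference_rates()
  cs <- exact_curve_set(levels = c(500, 1000), err_s = 0.9, err_e = 1.5,
                        times = seq(30, 1200, 30))
  set.seed(21)
  cs$observations$conc_nm <- cs$observations$conc_nm +
    rnorm(nrow(cs$observations), 0,
          0.02 * cs$meta$substrate_nm[match(cs$observations$curve_id,
                                            cs$meta$curve_id)])
  err <- estimate_error_terms(cs, truth)
  expect_true(all(abs(err$err_s - 0.9) / 0.9 < 0.1))
  expect_true(all(abs(err$err_e - 1.5) / 1.5 < 0.1))
  # exact data with unit errors give estimates at 1
  cs0 <- exact_curve_set(levels = c(500,  1000), times = seq(30, 900, 30))
  err0 <- estimate_error_terms(cs0, truth)
  expect_equal(err0$err_s, rep(1, 2), tolerance = 1e-4)
  expect_equal(err0$err_e, rep(1, 2), tolerance = 1e-4)
})

test_that("short curves are skipped with a warning in error estimation", {
  cs <- exact_curve_set(levels = 500, times = seq(30, 120, 30))
  expect_warning(err <- estimate_error_terms(cs, reference_rates()),
                 "fewer than 5")
  expect_equal(err$err_s, 1)
})

test_that("the staged workflow never increases the objective between stages", {
  cs <- generate_curve_set(small_design(reps = 2, duration = 1200), seed = 31)
  fit <- fit_kinetics(cs, "no_ligation",
                      settings = fit_settings(seed = 2,
                                              ess = ess_settings(n_sample = 24,
                                                                 n_recombine = 8,
                                                                 n_polish = 1)))
  expect_true(all(diff(fit$stage_rmse) <= 1e-8))
  expect_equal(unname(fit$stage_rmse["joint"]), fit$rmse, tolerance = 1e-10)
  expect_gte(min(fit$errors$err_s), fit$settings$err_bounds[1])
  expect_lte(max(fit$errors$err_e), fit$settings$err_bounds[2])
})

test_that("AIC follows the least-squares form and its parameter penalty", {
  expect_equal(aic_ls(100, 100, 3), 8)
  # an extra parameter that leaves RSS unchanged costs exactly 2
  expect_equal(aic_ls(57.3, 400, 7) - aic_ls(57.3, 400, 6), 2)
  expect_warning(a0 <- aic_ls(0, 10, 2), "zero")
  expect_identical(a0, -Inf)
})

test_that("variant comparison prefers the parsimonious model on
           ligation-free data", {
  cs <- generate_curve_set(experiment_design(substrate_nm = c(250, 1000),
                                             replicates = 2), seed = 17)
  st <- fit_settings(seed = 3, joint_maxiter = 20,
                     ess = ess_settings(n_sample = 24, n_recombine = 8,
                                        n_polish = 1))
  cmp <- compare_variants(cs, c("full_equilibrium", "no_ligation"),
                          settings = st)
  expect_s3_class(cmp, "dz_variant_comparison")
  expect_true(all(c("full_equilibrium", "no_ligation") %in% cmp$table$variant))
  # truth has k_lig = 0: the extra ligation parameter cannot be significant
  # and No Ligation must be selected
  expect_identical(cmp$selected, "no_ligation")
  # a single-variant comparison returns that variant
  one <- compare_variants(cs, "no_ligation", settings = st)
  expect_identical(one$selected, "no_ligation")
})
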