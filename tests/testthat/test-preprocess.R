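test_that("baseline subtraction removes the substrate-only signal", {
  raw <- generate_curves(small_design(), noise = no_noise(), seed = 1)
  bsub <- subtract_baseline(raw)
  truth <- attr(raw, "truth")
  slope <- truth$noise$slope_au_per_nm
  # with noise off the subtracted signal equals slope * observable exactly
  for (id in bsub$meta$curve_id) {
    got <- bsub$curves$value_au[bsub$curves$curve_id == id]
    want <- slope * truth$noiseless$observable_nm[truth$noiseless$curve_id == id]
    expect_equal(got, want, tolerance = 1e-10)
  }
  expect_true(all(bsub$meta$role == "reaction"))
})

test_that("a curve identical to its control subtracts to zero", {
  times <- seq(30, 600, 30)
  mk_meta <- function(id, role) data.frame(
    curve_id = id, substrate_nm = 500, enzyme_nm = if (role == "control") 0 else 10,
    temperature_c = 55, mg_mm = 20, replicate = 1, start_delay_s = 0,
    role = role)
  trace <- data.frame(curve_id = "a", time_s = times, value_au = 100)
  ctl <- data.frame(curve_id = "c", time_s = times, value_au = 100)
  raw <- raw_curves(rbind(trace, ctl),
                    rbind(mk_meta("a", "reaction"), mk_meta("c", "control")))
  bsub <- subtract_baseline(raw)
  expect_equal(bsub$curves$value_au, rep(0, length(times)))
})

test_that("calibration line recovers slope from plateaus", {
  # two-point line through the origin region
  cal <- fit_calibration(c(100, 1000), c(5000, 50000))
  expect_equal(cal$slope, 50)
  # noiseless generator: exact slope, r2 = 1
  raw <- generate_curves(experiment_design(substrate_nm = c(100, 500, 1000),
                                           replicates = 1),
                         noise = no_noise(), seed = 1)
  cal2 <- calibrate_curves(subtract_baseline(raw))
  expect_rel_equal(cal2$slope, 40, 0.01)
  expect_gt(cal2$r_squared, 0.9999)
  # 2% read noise: slope within 5% of the generating value
  nm <- noise_model(err_s_sdlog = 0, err_e_sdlog = 0, err_e_sdlog_low = 0,
                    read_noise_frac = 0.02)
  raw3 <- generate_curves(experiment_design(replicates = 2), noise = nm,
                          seed = 3)
  cal3 <- calibrate_curves(subtract_baseline(raw3))
  expect_rel_equal(cal3$slope, 40, 0.05)
  expect_error(fit_calibration(c(100, 100), c(1, 2)), "distinct")
  expect_error(fit_calibration(500, 2), "distinct")
})

test_that("normalization converts AU to nmol/L and shifts the time axis", {
  cal <- structure(list(slope = 50, intercept = 0, r_squared = 1),
                   class = "calibration_model")
  times <- seq(30, 300, 30)
  raw <- raw_curves(
    data.frame(curve_id = "a", time_s = times, value_au = 500),
    data.frame(curve_id = "a", substrate_nm = 100, enzyme_nm = 10,
               temperature_c = 55, mg_mm = 20, replicate = 1,
               start_delay_s = 45, role = "reaction"))
  cs <- normalize_curves(raw, cal)
  expect_equal(cs$observations$conc_nm, rep(10, length(times)))
  expect_equal(cs$observations$time_s, times + 45)
  # linearity: scaling fluorescence by lambda scales concentration by lambda
  raw2 <- raw
  raw2$curves$value_au <- raw$curves$value_au * 3
  expect_equal(normalize_curves(raw2, cal)$observations$conc_nm,
               3 * cs$observations$conc_nm)
})

test_that("full preprocessing round-trip recovers the noiseless observable", {
  # complete curves (plateau reached) so the calibration is unbiased
  raw <- generate_curves(small_design(levels = c(100, 250, 500), reps = 2,
                                      duration = 1800),
                         noise = no_noise(), seed = 2)
  pp <- preprocess_curves(raw)
  truth <- attr(raw, "truth")
  for (id in pp$curves$meta$curve_id) {
    got <- pp$curves$observations$conc_nm[pp$curves$observations$curve_id == id]
    want <- truth$noiseless$observable_nm[truth$noiseless$curve_id == id]
    # bias below 1% of the plateau
    expect_lt(max(abs(got - want)), 0.01 * max(want))
  }
})

test_that("incomplete curves trigger a plateau warning", {
  tr <- simulate_reaction(reference_rates(), 1000, 10, seq(30, 240, 30))
  expect_warning(estimate_plateau(tr$time_s, tr$observable), "plateau")
})
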