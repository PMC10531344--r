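# Shared fixtures: small designs and exact (solver-generated) curve sets.

small_design <- function(levels = c(250, 1000), reps = 2, duration = 900) {
  experiment_design(substrate_nm = levels, replicates = reps,
                    duration_s = duration)
}

# noise model with everything switched off (for round-trip tests)
no_noise <- function() {
  noise_model(err_s_sdlog = 0, err_e_sdlog = 0, err_e_sdlog_low = 0,
              read_noise_frac = 0)
}

# Exact concentration curve set straight from the solver (no AU layer, no
# calibration round trip); errors are per-level vectors recycled per curve.
exact_curve_set <- function(rates = reference_rates(),
                            levels = c(100, 500, 1000), e0 = 10,
                            times = seq(30, 1500, 30), err_s = 1,
                            err_e = 1, reps = 1) {
  err_s <- rep_len(err_s, length(levels) * reps)
  err_e <- rep_len(err_e, length(levels) * reps)
  i <- 0
  obs <- list(); meta <- list()
  for (s0 in levels) for (r in seq_len(reps)) {
    i <- i + 1
    id <- sprintf("S%04d_r%d", s0, r)
    tr <- simulate_reaction(rates, s0, e0, times, err_s = err_s[i],
                            err_e = err_e[i])
    obs[[i]] <- data.frame(curve_id = id, time_s = times,
                           conc_nm = tr$observable)
    meta[[i]] <- data.frame(curve_id = id, substrate_nm = s0, enzyme_nm = e0,
                            temperature_c = 55, mg_mm = 20, replicate = r)
  }
  out <- curve_set(do.call(rbind, obs), do.call(rbind, meta))
  attr(out, "err") <- data.frame(curve_id = vapply(meta, `[[`, "", "curve_id"),
                                 err_s = err_s, err_e = err_e)
  out
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x / y - 1)), tol)
}
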