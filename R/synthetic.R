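#' Experiment design for synthetic kinetic curves
#'
#' Mirrors the plate-reader study design: a fixed DNAzyme concentration
#' (10 nmol/L), a ladder of substrate concentrations, readings every 30 s
#' for 25 min, and replicated wells per concentration (8 replicates at the
#' 55 degree C / 20 mmol/L Mg2+ reference condition, 3 in the
#' condition-series experiments).
#'
#' @param substrate_nm substrate levels, nmol/L
#' @param enzyme_nm DNAzyme concentration, nmol/L
#' @param replicates wells per substrate level
#' @param interval_s sampling interval, s
#' @param duration_s total measured time, s (>= 10 intervals)
#' @param temperature_c working temperature, degrees C
#' @param mg_mm Mg2+ concentration, mmol/L
#' @param start_delay_s delay between substrate addition and first read, s
#' @param stagger_s extra delay per successive replicate (wells are started
#'   one after another), s
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(substrate_nm = c(100, 250, 500, 750, 1000),
                              enzyme_nm = 10, replicates = 8,
                              interval_s = 30, duration_s = 1500,
                              temperature_c = 55, mg_mm = 20,
                              start_delay_s = 0, stagger_s = 0) {
  stopifnot(all(substrate_nm > 0), enzyme_nm > 0, replicates >= 1,
            interval_s > 0, duration_s >= 10 * interval_s,
            mg_mm >= 0, start_delay_s >= 0, stagger_s >= 0)
  structure(list(substrate_nm = substrate_nm, enzyme_nm = enzyme_nm,
                 replicates = replicates, interval_s = interval_s,
                 duration_s = duration_s, temperature_c = temperature_c,
                 mg_mm = mg_mm, start_delay_s = start_delay_s,
                 stagger_s = stagger_s),
            class = "experiment_design")
}

#' Noise model for synthetic kinetic curves
#'
#' Statistical structure of the emulated measurement process:
#' multiplicative log-normal pipetting errors on both concentrations
#' (`err_s` tight, about +/-6% at 95%; `err_e` wider with a heavy right
#' tail at the lowest substrate level, where the data carry little
#' information on the enzyme amount), additive Gaussian read noise
#' proportional to the plateau signal, a residual substrate-only baseline
#' proportional to the substrate input, and a linear fluorescence
#' calibration slope.
#'
#' @param err_s_sdlog log-sd of the substrate pipetting error (median 1)
#' @param err_e_sdlog log-sd of the enzyme pipetting error (median 1)
#' @param err_e_sdlog_low log-sd of the enzyme error at the lowest
#'   substrate level (heavy tail, up to roughly 5-fold); set equal to
#'   `err_e_sdlog` to disable
#' @param low_substrate_nm threshold at or below which the heavy tail applies
#' @param read_noise_frac additive read-noise SD as a fraction of the
#'   plateau signal
#' @param slope_au_per_nm calibration slope, AU per nmol/L
#' @param baseline_rel substrate-only baseline as a fraction of the
#'   would-be plateau signal (imperfect quenching)
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(err_s_sdlog = 0.058, err_e_sdlog = 0.10,
                        err_e_sdlog_low = 0.80, low_substrate_nm = 100,
                        read_noise_frac = 0.02, slope_au_per_nm = 40,
                        baseline_rel = 0.08) {
  stopifnot(err_s_sdlog >= 0, err_e_sdlog >= 0, err_e_sdlog_low >= 0,
            read_noise_frac >= 0, slope_au_per_nm > 0, baseline_rel >= 0)
  structure(list(err_s_sdlog = err_s_sdlog, err_e_sdlog = err_e_sdlog,
                 err_e_sdlog_low = err_e_sdlog_low,
                 low_substrate_nm = low_substrate_nm,
                 read_noise_frac = read_noise_frac,
                 slope_au_per_nm = slope_au_per_nm,
                 baseline_rel = baseline_rel),
            class = "noise_model")
}

#' Generate synthetic raw plate-reader curves
#'
#' Emulates the fluorescence measurement process: for each well a pair of
#' pipetting errors (ErrS, ErrE) is drawn, the mass-action system is
#' integrated from the realized concentrations, the observable EP + P is
#' mapped to fluorescence through the calibration slope plus a
#' substrate-proportional baseline, and i.i.d. Gaussian read noise is
#' added.  One substrate-only control trace per substrate level is
#' emitted alongside.  The ground truth (rates, per-curve errors,
#' noiseless observables, the noise model itself) is attached as
#' `attr(x, "truth")`; all noise magnitudes there are assumptions of the
#' generator, not fitted quantities.
#'
#' @param design an [experiment_design()]
#' @param truth ground-truth [rate_constants()] at the reference condition
#' @param noise a [noise_model()]
#' @param env optional [environment_params()]; when supplied, `truth` is
#'   resolved to the design's temperature and/or Mg2+ condition before
#'   simulating
#' @param resolve which environment layers to apply when `env` is given:
#'   `"temperature"`, `"mg"` or both names
#' @param seed integer seed for reproducibility
#' @return A [raw_curves()] set with a `truth` attribute.
#' @examples
#' raw <- generate_curves(experiment_design(replicates = 2), seed = 1)
#' raw
#' @export
generate_curves <- function(design = experiment_design(),
                            truth = reference_rates(),
                            noise = noise_model(), env = NULL,
                            resolve = c("temperature", "mg"),
                            seed = NULL) {
  stopifnot(inherits(design, "experiment_design"), inherits(noise, "noise_model"))
  truth <- as_rates(truth)
  if (!is.null(seed)) set.seed(seed)
  rates <- if (!is.null(env)) {
    resolve_rates(truth, env,
                  temp_c = if ("temperature" %in% resolve) design$temperature_c else NULL,
                  mg_mm = if ("mg" %in% resolve) design$mg_mm else NULL)
  } else truth
  .generate_raw(design, rates, noise, truth_base = truth, env = env)
}

#' Generate curves with a substrate-saturation misfit
#'
#' Above roughly 1000 nmol/L substrate the real reaction slows down
#' relative to the mass-action model (saturation of the DNAzyme by excess
#' substrate).  This generator deliberately mis-specifies the data
#' relative to the model by scaling the cleavage rate down by
#' `1 / (1 + inhibition * max(0, s0/threshold - 1))` per well, so that
#' model-misfit detection can be exercised.  With `inhibition = 0` or
#' below-threshold substrate it reduces exactly to [generate_curves()].
#'
#' @inheritParams generate_curves
#' @param inhibition dimensionless slowdown factor (0 disables)
#' @param threshold_nm substrate concentration where saturation sets in
#' @return A [raw_curves()] set with a `truth` attribute.
#' @export
generate_saturating <- function(design, truth = reference_rates(),
                                noise = noise_model(), inhibition = 1,
                                threshold_nm = 1000, seed = NULL) {
  stopifnot(inhibition >= 0, threshold_nm > 0)
  truth <- as_rates(truth)
  if (!is.null(seed)) set.seed(seed)
  .generate_raw(design, truth, noise, truth_base = truth, env = NULL,
                clv_scale = function(s0)
                  1 / (1 + inhibition * max(0, s0 / threshold_nm - 1)))
}

# shared generator core; assumes RNG state already seeded
.generate_raw <- function(design, rates, noise, truth_base, env,
                          clv_scale = NULL) {
  times <- seq(design$interval_s, design$duration_s, by = design$interval_s)
  slope <- noise$slope_au_per_nm
  curves <- list(); meta <- list(); truth_err <- list(); noiseless <- list()
  ii <- 0L
  for (s0 in design$substrate_nm) {
    sdlog_e <- if (s0 <= noise$low_substrate_nm) noise$err_e_sdlog_low
               else noise$err_e_sdlog
    plateau_au <- slope * s0
    read_sd <- noise$read_noise_frac * plateau_au
    for (rep in seq_len(design$replicates)) {
      ii <- ii + 1L
      id <- sprintf("S%04d_r%02d_T%02g_Mg%03g", s0, rep,
                    design$temperature_c, design$mg_mm)
      err_s <- rlnorm(1, 0, noise$err_s_sdlog)
      err_e <- rlnorm(1, 0, sdlog_e)
      r_i <- unclass(rates)
      if (!is.null(clv_scale)) r_i["k_clv"] <- r_i["k_clv"] * clv_scale(s0)
      obs <- sim_observable(unname(r_i[.RATE_NAMES]), s0, design$enzyme_nm,
                            times, err_s = err_s, err_e = err_e)
      au <- noise$baseline_rel * plateau_au + slope * obs +
        rnorm(length(obs), 0, read_sd)
      curves[[ii]] <- data.frame(curve_id = id, time_s = times, value_au = au)
      meta[[ii]] <- data.frame(
        curve_id = id, substrate_nm = s0, enzyme_nm = design$enzyme_nm,
        temperature_c = design$temperature_c, mg_mm = design$mg_mm,
        replicate = rep,
        start_delay_s = design$start_delay_s + (rep - 1) * design$stagger_s,
        role = "reaction")
      truth_err[[ii]] <- data.frame(curve_id = id, err_s = err_s, err_e = err_e)
      noiseless[[ii]] <- data.frame(curve_id = id, time_s = times,
                                    observable_nm = obs)
    }
    # substrate-only control well for this level
    ii <- ii + 1L
    id <- sprintf("ctrl_S%04d_T%02g_Mg%03g", s0,
                  design$temperature_c, design$mg_mm)
    au <- noise$baseline_rel * plateau_au + rnorm(length(times), 0, read_sd)
    curves[[ii]] <- data.frame(curve_id = id, time_s = times, value_au = au)
    meta[[ii]] <- data.frame(
      curve_id = id, substrate_nm = s0, enzyme_nm = 0,
      temperature_c = design$temperature_c, mg_mm = design$mg_mm,
      replicate = 1, start_delay_s = design$start_delay_s, role = "control")
  }
  out <- raw_curves(do.call(rbind, curves), do.call(rbind, meta))
  attr(out, "truth") <- list(
    rates = truth_base, rates_at_condition = structure(unclass(rates),
                                                       class = "rate_constants"),
    env = env, errors = do.call(rbind, truth_err),
    noiseless = do.call(rbind, noiseless), noise = noise, design = design)
  out
}

#' Generate a preprocessed synthetic curve set
#'
#' Convenience wrapper: [generate_curves()] followed by
#' [preprocess_curves()], returning fit-ready concentration curves with
#' the ground truth attached.
#'
#' @inheritParams generate_curves
#' @param cal optional [calibration_model()]; when the simulated reaction
#'   does not run to completion (so plateaus under-determine the slope),
#'   pass `calibration_model(noise$slope_au_per_nm)` to normalize with the
#'   generator's known slope instead of the data-driven plateau fit
#' @return A [curve_set()] with attributes `truth` and `calibration`.
#' @export
generate_curve_set <- function(design = experiment_design(),
                               truth = reference_rates(),
                               noise = noise_model(), env = NULL,
                               resolve = c("temperature", "mg"),
                               seed = NULL, cal = NULL) {
  raw <- generate_curves(design, truth, noise, env = env,
                         resolve = resolve, seed = seed)
  pp <- preprocess_curves(raw, cal = cal)
  out <- pp$curves
  attr(out, "truth") <- attr(raw, "truth")
  attr(out, "calibration") <- pp$calibration
  out
}

#' Generate a multi-condition curve series
#'
#' Builds one design per condition (varying temperature or Mg2+), resolves
#' the ground-truth rates through the environment layers, and returns the
#' combined preprocessed curve set.
#'
#' @param temperatures_c,mg_mm vectors of conditions; vary exactly one
#' @param design base [experiment_design()] for the per-condition wells
#' @param truth reference-condition [rate_constants()]
#' @param env [environment_params()] ground truth for the varied layer
#' @param noise a [noise_model()]
#' @param seed integer seed
#' @return A combined [curve_set()]; per-condition truths in
#'   `attr(x, "truth_by_condition")`.
#' @export
generate_condition_series <- function(temperatures_c = NULL, mg_mm = NULL,
                                      design = experiment_design(replicates = 3),
                                      truth = reference_rates(), env,
                                      noise = noise_model(), seed = NULL) {
  if (is.null(temperatures_c) == is.null(mg_mm))
    stop("vary exactly one of temperatures_c or mg_mm")
  if (!is.null(seed)) set.seed(seed)
  conds <- if (!is.null(temperatures_c)) temperatures_c else mg_mm
  layer <- if (!is.null(temperatures_c)) "temperature" else "mg"
  sets <- vector("list", length(conds))
  truths <- vector("list", length(conds))
  # slow conditions need not plateau within the run, so normalization uses
  # the generator's known slope (a dedicated calibration experiment) rather
  # than per-condition plateaus
  cal <- calibration_model(noise$slope_au_per_nm)
  for (i in seq_along(conds)) {
    d <- design
    if (layer == "temperature") d$temperature_c <- conds[i] else d$mg_mm <- conds[i]
    raw <- generate_curves(d, truth, noise, env = env, resolve = layer,
                           seed = NULL)
    pp <- preprocess_curves(raw, cal = cal)
    sets[[i]] <- pp$curves
    truths[[i]] <- attr(raw, "truth")
  }
  out <- do.call(combine_curves, sets)
  attr(out, "truth_by_condition") <- truths
  attr(out, "truth") <- list(rates = truth, env = env, noise = noise)
  out
}
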