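#' Subtract the substrate-only baseline from reaction curves
#'
#' The dually labeled substrate fluoresces residually even before cleavage,
#' in proportion to its concentration.  For every reaction curve the
#' matching substrate-only control (same nominal substrate concentration)
#' is located, its time-averaged signal is taken as the baseline for that
#' concentration, and subtracted.  Control curves are dropped from the
#' returned set.
#'
#' @param raw a [raw_curves()] set containing `"reaction"` and `"control"`
#'   curves, or a reaction-only set with `controls` supplied separately
#' @param controls optional [raw_curves()] set of substrate-only controls
#' @return A `raw_curves` set of baseline-subtracted reaction curves.
#' @export
subtract_baseline <- function(raw, controls = NULL) {
  stopifnot(inherits(raw, "raw_curves"))
  if (is.null(controls)) {
    ctl_meta <- raw$meta[raw$meta$role == "control", , drop = FALSE]
    rx_meta  <- raw$meta[raw$meta$role == "reaction", , drop = FALSE]
    ctl_curves <- raw$curves[raw$curves$curve_id %in% ctl_meta$curve_id, ]
  } else {
    stopifnot(inherits(controls, "raw_curves"))
    ctl_meta <- controls$meta
    ctl_curves <- controls$curves
    rx_meta <- raw$meta[raw$meta$role == "reaction", , drop = FALSE]
  }
  if (nrow(ctl_meta) == 0) stop("no substrate-only control curves found")
  if (nrow(rx_meta) == 0) stop("no reaction curves found")

  # per-concentration baseline: time-average of the control trace(s)
  base_by_s <- tapply(ctl_curves$value_au,
                      ctl_meta$substrate_nm[match(ctl_curves$curve_id,
                                                  ctl_meta$curve_id)],
                      mean)
  rx <- raw$curves[raw$curves$curve_id %in% rx_meta$curve_id, , drop = FALSE]
  s0 <- rx_meta$substrate_nm[match(rx$curve_id, rx_meta$curve_id)]
  key <- as.character(s0)
  if (!all(key %in% names(base_by_s)))
    stop("no control at substrate concentration(s): ",
         paste(unique(s0[!key %in% names(base_by_s)]), collapse = ", "))
  rx$value_au <- as.numeric(rx$value_au - base_by_s[key])
  raw_curves(rx, rx_meta)
}

#' Fit the fluorescence calibration line
#'
#' Ordinary least-squares regression of plateau fluorescence on substrate
#' concentration.  When the full amount of substrate is eventually cleaved,
#' the plateau signal is proportional to the substrate input, and the slope
#' of this line converts arbitrary fluorescence units to nmol/L.
#'
#' @param concentration_nm substrate concentrations, nmol/L (>= 2 distinct)
#' @param plateau_au plateau fluorescence at each concentration, AU
#' @return An object of class `calibration_model` with `slope`
#'   (AU per nmol/L), `intercept` (AU) and `r_squared`.
#' @examples
#' fit_calibration(c(100, 500, 1000), c(4000, 20000, 40000))
#' @export
fit_calibration <- function(concentration_nm, plateau_au) {
  if (length(concentration_nm) < 2 || length(unique(concentration_nm)) < 2)
    stop("calibration needs at least 2 distinct concentrations")
  if (length(concentration_nm) != length(plateau_au))
    stop("concentration and plateau vectors must have equal length")
  fit <- lm(plateau_au ~ concentration_nm)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration slope must be positive; got ", signif(slope, 4))
  r2 <- if (length(concentration_nm) > 2 && sd(plateau_au) > 0)
    summary(fit)$r.squared else 1
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 r_squared = r2),
            class = "calibration_model")
}

#' Construct a calibration model from known coefficients
#'
#' For use when the fluorescence-to-concentration slope comes from a
#' dedicated calibration experiment rather than from the plateaus of the
#' curves being preprocessed (e.g. condition series whose slow curves
#' never reach their plateau within the run).
#'
#' @param slope AU per nmol/L, positive
#' @param intercept AU
#' @param r_squared coefficient of determination of the source regression
#' @return A `calibration_model`.
#' @export
calibration_model <- function(slope, intercept = 0, r_squared = NA_real_) {
  stopifnot(is.finite(slope), slope > 0)
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Calibration: slope %.4g AU/(nmol/L), intercept %.4g AU, r2 %.4f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Estimate the plateau of a progress curve
#'
#' Mean of the final fraction (`frac`, default 10%) of readings.  A curve
#' is judged complete when the relative slope over that window is below
#' `max_rel_slope` per 30 s of its plateau value; incomplete curves give a
#' warning since their plateau under-estimates the end point.
#'
#' @param times reading times, s
#' @param values signal values
#' @param frac final fraction of readings averaged
#' @param max_rel_slope completeness threshold, relative change per 30 s
#' @return The plateau estimate (scalar).
#' @export
estimate_plateau <- function(times, values, frac = 0.1, max_rel_slope = 1e-4) {
  n <- length(values)
  stopifnot(n >= 3, length(times) == n)
  w <- max(3L, as.integer(ceiling(frac * n)))
  idx <- seq.int(max(1L, n - w + 1L), n)
  plateau <- mean(values[idx])
  if (length(idx) >= 2 && plateau > 0) {
    sl <- coef(lm(values[idx] ~ times[idx]))[2]
    if (is.finite(sl) && abs(sl) * 30 / abs(plateau) > max_rel_slope)
      warning("curve may not have reached its plateau; estimate is biased low")
  }
  plateau
}

#' Calibrate a baseline-subtracted curve set
#'
#' Estimates a plateau per reaction curve with [estimate_plateau()] and
#' regresses plateaus on nominal substrate concentration to obtain the
#' fluorescence calibration.
#'
#' @param bsub a baseline-subtracted [raw_curves()] set
#' @param ... passed to [estimate_plateau()]
#' @return A `calibration_model`.
#' @export
calibrate_curves <- function(bsub, ...) {
  stopifnot(inherits(bsub, "raw_curves"))
  obs <- split(bsub$curves, bsub$curves$curve_id)
  plateaus <- vapply(obs, function(o)
    suppressWarnings(estimate_plateau(o$time_s, o$value_au, ...)), numeric(1))
  s0 <- bsub$meta$substrate_nm[match(names(plateaus), bsub$meta$curve_id)]
  fit_calibration(s0, unname(plateaus))
}

#' Convert fluorescence to product concentration
#'
#' Divides baseline-subtracted fluorescence by the calibration slope and
#' shifts each time axis by the curve's `start_delay_s`, so that t = 0 is
#' the moment of substrate addition rather than the first plate read.
#'
#' @param bsub a baseline-subtracted [raw_curves()] set
#' @param cal a `calibration_model`
#' @return A [curve_set()] in nmol/L.
#' @export
normalize_curves <- function(bsub, cal) {
  stopifnot(inherits(bsub, "raw_curves"), inherits(cal, "calibration_model"))
  if (cal$slope <= 0) stop("calibration slope must be positive")
  cc <- bsub$curves
  delay <- bsub$meta$start_delay_s[match(cc$curve_id, bsub$meta$curve_id)]
  obs <- data.frame(curve_id = cc$curve_id,
                    time_s = cc$time_s + delay,
                    conc_nm = cc$value_au / cal$slope)
  meta <- bsub$meta[, c("curve_id", "substrate_nm", "enzyme_nm",
                        "temperature_c", "mg_mm", "replicate")]
  curve_set(obs, meta)
}

#' Full preprocessing chain: baseline, calibration, normalization
#'
#' @param raw a [raw_curves()] set with reaction and control curves
#' @param cal optional pre-fitted `calibration_model`; fitted from the
#'   data's own plateaus when `NULL`
#' @return A list with `curves` (the [curve_set()]) and `calibration`.
#' @export
preprocess_curves <- function(raw, cal = NULL) {
  bsub <- subtract_baseline(raw)
  if (is.null(cal)) cal <- calibrate_curves(bsub)
  list(curves = normalize_curves(bsub, cal), calibration = cal)
}
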