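#' Residual-resampled bootstrap data set
#'
#' Builds one surrogate curve set by adding residuals resampled with
#' replacement (pooled within each curve) to the fitted curves, keeping
#' the original design and metadata.  This is the error-based resampling
#' underlying the bootstrap confidence intervals.
#'
#' @param fit a `dz_fit`
#' @param seed integer seed
#' @return A [curve_set()] with the same design as the fitted data.
#' @export
residual_resample <- function(fit, seed = NULL) {
  stopifnot(inherits(fit, "dz_fit"))
  if (!is.null(seed)) set.seed(seed)
  res <- fit$residuals
  new_val <- unlist(lapply(split(res, res$curve_id), function(d) {
    d$fitted + sample(d$residual, nrow(d), replace = TRUE)
  }), use.names = FALSE)
  # split() orders by curve_id; observations are sorted the same way
  obs <- fit$curves$observations
  obs$conc_nm <- new_val
  curve_set(obs, fit$curves$meta)
}

#' Bootstrap confidence intervals for the rate constants
#'
#' Creates `n_boot` residual-resampled data sets, refits each one jointly
#' (rates + error terms) starting from the base-fit estimates, and
#' summarizes the resulting parameter distribution by percentile
#' confidence intervals and pairwise correlations.  Individual refit
#' failures are logged and excluded; more than 20% failures is an error.
#'
#' @param fit a converged `dz_fit`
#' @param n_boot number of bootstrap data sets (default 100)
#' @param level confidence level (default 0.95)
#' @param seed integer seed
#' @return An object of class `dz_boot` with `draws` (matrix, draw x
#'   parameter), `ci` (data frame with lower/upper per parameter),
#'   `correlation`, `n_failed`.
#' @export
bootstrap_ci <- function(fit, n_boot = 100, level = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "dz_fit"), n_boot >= 2, level > 0, level < 1)
  if (!is.null(seed)) set.seed(seed)
  free <- fit$free
  draws <- matrix(NA_real_, n_boot, length(free),
                  dimnames = list(NULL, free))
  failed <- character(0)
  for (b in seq_len(n_boot)) {
    bs <- residual_resample(fit)
    rf <- tryCatch(
      joint_refit(bs, fit$rates, fit$errors, variant = fit$variant,
                  settings = fit$settings),
      error = function(e) e)
    if (inherits(rf, "error")) {
      failed <- c(failed, sprintf("draw %d: %s", b, conditionMessage(rf)))
    } else {
      draws[b, ] <- unclass(rf$rates)[free]
    }
  }
  ok <- stats::complete.cases(draws)
  if (mean(!ok) > 0.2)
    stop("more than 20% of bootstrap refits failed (",
         sum(!ok), "/", n_boot, ")")
  d <- draws[ok, , drop = FALSE]
  alpha <- (1 - level) / 2
  # order-statistic percentiles (type 1): equivariant under monotone
  # reparameterization of the constants
  ci <- data.frame(
    parameter = free,
    estimate = unclass(fit$rates)[free],
    lower = apply(d, 2, quantile, alpha, type = 1),
    upper = apply(d, 2, quantile, 1 - alpha, type = 1))
  rownames(ci) <- NULL
  corr <- if (nrow(d) > 2 && all(apply(d, 2, sd) > 0)) cor(d) else
    diag(ncol(d))
  structure(list(draws = d, ci = ci, correlation = corr, level = level,
                 n_boot = n_boot, n_failed = sum(!ok),
                 failures = failed),
            class = "dz_boot")
}

#' @export
print.dz_boot <- function(x, ...) {
  cat(sprintf("Bootstrap: %d draws (%d failed), %.0f%% percentile CIs\n",
              nrow(x$draws), x$n_failed, 100 * x$level))
  print(transform(x$ci, estimate = signif(estimate, 4),
                  lower = signif(lower, 4), upper = signif(upper, 4)))
  invisible(x)
}

#' Monte Carlo forward prediction of the observable
#'
#' Propagates the pipetting-error variability into the model output: the
#' per-curve (ErrS, ErrE) estimates of a fit are pooled into empirical
#' distributions, `n_draws` independent (ErrS, ErrE) combinations are
#' drawn, the reaction is simulated for each draw at the requested
#' condition, and the spread is summarized as per-time-point probability
#' densities (frequencies summing to 1 at every time point) and a central
#' prediction band.
#'
#' @param rates [rate_constants()] to simulate with (e.g. `fit$rates`)
#' @param err_s_pool,err_e_pool empirical pools of error terms; typically
#'   `fit$errors$err_s` and `fit$errors$err_e`
#' @param s0,e0 nominal condition, nmol/L
#' @param times output grid, s
#' @param n_draws Monte Carlo draws (default 1000)
#' @param level band level (default 0.95)
#' @param n_bins histogram bins for the densities
#' @param obs_noise_sd optional measurement-noise SD (nmol/L): when
#'   positive, i.i.d. Gaussian read noise is added to every draw so the
#'   band is predictive for observed points rather than for the noise-free
#'   model output (use when overlaying experimental curves)
#' @param seed integer seed
#' @return An object of class `dz_prediction_band` with `band` (data
#'   frame `time_s`, `lower`, `median`, `upper`), `density` (`breaks`,
#'   `freq` time x bin matrix), and `draws` (draw x time matrix).
#' @export
monte_carlo_predict <- function(rates, err_s_pool, err_e_pool, s0, e0,
                                times, n_draws = 1000, level = 0.95,
                                n_bins = 50, obs_noise_sd = 0,
                                seed = NULL) {
  stopifnot(length(err_s_pool) >= 1, length(err_e_pool) >= 1,
            n_draws >= 1, level > 0, level < 1, obs_noise_sd >= 0)
  rates <- as_rates(rates)
  if (!is.null(seed)) set.seed(seed)
  es <- sample(err_s_pool, n_draws, replace = TRUE)
  ee <- sample(err_e_pool, n_draws, replace = TRUE)
  rv <- unname(unclass(rates)[.RATE_NAMES])
  draws <- t(vapply(seq_len(n_draws), function(i)
    sim_observable(rv, s0, e0, times, err_s = es[i], err_e = ee[i]),
    numeric(length(times))))
  if (obs_noise_sd > 0)
    draws <- draws + rnorm(length(draws), 0, obs_noise_sd)
  alpha <- (1 - level) / 2
  qs <- apply(draws, 2, quantile, c(alpha, 0.5, 1 - alpha))
  band <- data.frame(time_s = times, lower = qs[1, ], median = qs[2, ],
                     upper = qs[3, ])
  rng <- range(draws)
  breaks <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = n_bins + 1)
  freq <- t(apply(draws, 2, function(v) {
    h <- hist(v, breaks = breaks, plot = FALSE)
    h$counts / sum(h$counts)
  }))
  structure(list(band = band, density = list(breaks = breaks, freq = freq),
                 draws = draws, level = level, s0 = s0, e0 = e0,
                 err_draws = data.frame(err_s = es, err_e = ee)),
            class = "dz_prediction_band")
}

#' @importFrom graphics hist
#' @export
print.dz_prediction_band <- function(x, ...) {
  cat(sprintf(paste0("Monte Carlo prediction band: %d draws, %.0f%% band, ",
                     "S0 = %g, E0 = %g nmol/L\n"),
              nrow(x$draws), 100 * x$level, x$s0, x$e0))
  invisible(x)
}

#' Fraction of observed points inside a prediction band
#'
#' Overlays a held-out curve on a Monte Carlo band and reports the
#' fraction of its points lying inside the band (band limits linearly
#' interpolated at the observation times).
#'
#' @param band a `dz_prediction_band`
#' @param times,values the held-out observations
#' @return Fraction in [0, 1].
#' @export
band_coverage <- function(band, times, values) {
  stopifnot(inherits(band, "dz_prediction_band"),
            length(times) == length(values))
  lo <- approx(band$band$time_s, band$band$lower, xout = times, rule = 2)$y
  hi <- approx(band$band$time_s, band$band$upper, xout = times, rule = 2)$y
  mean(values >= lo & values <= hi)
}
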