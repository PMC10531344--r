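#' Staged Arrhenius calibration from a multi-temperature curve series
#'
#' Estimates activation energies for the temperature-dependent rate
#' constants and re-estimates the reference rates from data spanning
#' several temperatures.  Stages mirror the base workflow:
#' \enumerate{
#'   \item scatter search (two orders of magnitude) plus
#'     Levenberg-Marquardt on the activation energies with the reference
#'     rates frozen at the base fit;
#'   \item joint re-estimation of the reference rates together with the
#'     activation energies;
#'   \item per-curve concentration error terms with everything else fixed.
#' }
#'
#' @param curves a multi-temperature [curve_set()] (>= 3 distinct
#'   temperatures); temperatures outside 50--60 degrees C trigger an
#'   extrapolation warning
#' @param base_rates reference-condition [rate_constants()], typically
#'   from [fit_kinetics()] at the reference temperature
#' @param dep names of the temperature-dependent constants (default
#'   `k_off`, `k_clv`, `k_rls`; association and product binding show
#'   minimal temperature dependence)
#' @param variant a [model_variant()] or its name
#' @param t_ref reference temperature, K
#' @param e_a_init initial activation energy, J/mol (applied to each
#'   dependent constant)
#' @param settings a [fit_settings()]
#' @return An object of class `dz_env_fit` with elements `k_ref`, `e_a`,
#'   `e_a_sd`, `env` (an [environment_params()]), `errors`, `rmse`, `aic`.
#' @export
fit_arrhenius <- function(curves, base_rates,
                          dep = c("k_off", "k_clv", "k_rls"),
                          variant = "no_ligation", t_ref = 328.15,
                          e_a_init = 5e4, settings = fit_settings()) {
  stopifnot(inherits(curves, "curve_set"))
  variant <- as_variant(variant)
  temps <- unique(curves$meta$temperature_c)
  if (length(temps) < 3)
    stop("activation energies are not identifiable from fewer than 3 ",
         "temperatures (got ", length(temps), ")")
  if (any(temps < 50 | temps > 60))
    warning("temperature(s) outside the calibrated 50-60 degree C range: ",
            paste(sort(temps[temps < 50 | temps > 60]), collapse = ", "),
            " (extrapolation)")
  base_rates <- as_rates(base_rates)
  factory <- .factory_arrhenius(variant, dep, t_ref)
  dep <- factory$dep
  clist <- curve_list(curves)
  resid <- .make_resid(clist, factory, settings$rtol, settings$atol)
  n_curve <- length(clist)
  ones <- rep(1, n_curve)
  nk <- factory$nk

  ea0 <- setNames(rep(e_a_init, length(dep)), dep)
  par <- factory$to_par(unclass(base_rates), ea0)
  names(par) <- factory$par_names
  kref_idx <- seq_len(nk)
  ea_idx <- nk + seq_along(dep)
  stage_rmse <- c()

  # stage 1: E_a only, k_ref frozen (ESS over two decades, then LM)
  obj_ea <- function(ea) {
    p <- par; p[ea_idx] <- ea / 1e4
    sqrt(mean(resid$all(p, ones, ones)^2))
  }
  ess <- scatter_search(obj_ea, ea0, settings = settings$ess,
                        seed = settings$seed)
  par[ea_idx] <- ess$best_par / 1e4
  ref1 <- refine_least_squares(
    function(ea4) { p <- par; p[ea_idx] <- ea4; resid$all(p, ones, ones) },
    par[ea_idx], maxiter = settings$lm_maxiter)
  par[ea_idx] <- ref1$par
  stage_rmse["e_a"] <- sqrt(ref1$rss / resid$n_obs)

  # stage 2: joint re-estimation of k_ref and E_a
  lo <- c(rep(settings$rate_bounds_log10[1], nk), rep(-100, length(dep)))
  hi <- c(rep(settings$rate_bounds_log10[2], nk), rep(100, length(dep)))
  ref2 <- refine_least_squares(function(p) resid$all(p, ones, ones),
                               par, lower = lo, upper = hi,
                               maxiter = settings$lm_maxiter)
  par <- ref2$par
  stage_rmse["joint_kref_ea"] <- sqrt(ref2$rss / resid$n_obs)

  # stage 3: per-curve error terms
  rep_par <- factory$report(par)
  env <- environment_params(
    arrhenius = setNames(lapply(dep, function(nm)
      list(e_a = rep_par$e_a[[nm]])), dep),
    map = dependency_map(temperature = dep, mg = character(0)),
    t_ref = t_ref)
  errors <- estimate_error_terms(curves, rep_par$k_ref, settings,
                                 env = env, resolve = "temperature")
  res_vec <- resid$all(par, errors$err_s, errors$err_e)
  rss <- sum(res_vec^2)
  stage_rmse["error_terms"] <- sqrt(rss / resid$n_obs)
  n_params <- length(par) + 2 * n_curve

  e_a <- rep_par$e_a
  e_a_sd <- setNames(ref2$sd[ea_idx] * 1e4, dep)
  structure(list(
    k_ref = rep_par$k_ref, e_a = e_a, e_a_sd = e_a_sd, t_ref = t_ref,
    env = env, errors = errors, dep = dep, variant = variant,
    rmse = sqrt(rss / resid$n_obs), rss = rss, n_obs = resid$n_obs,
    n_params = n_params, aic = aic_ls(rss, resid$n_obs, n_params),
    stage_rmse = stage_rmse, curves = curves, kind = "arrhenius"),
    class = "dz_env_fit")
}

#' Staged Mg2+-law calibration from a multi-concentration curve series
#'
#' Fits the exponential magnesium laws of the dependent rate constants
#' (increasing for association and cleavage, decreasing for release; the
#' cleavage intercept is forced to zero since there is no cleavage without
#' Mg2+).  The law parameters (a, b, c) are fitted in log10 space by a
#' one-decade scatter search followed by Levenberg-Marquardt, then the
#' per-curve error terms are estimated.
#'
#' @param curves a multi-Mg [curve_set()] (>= 3 distinct non-zero
#'   concentrations)
#' @param base_rates reference-condition [rate_constants()] supplying the
#'   Mg-independent constants (k_off, k_bin) and the initialization of the
#'   laws at the calibration concentration
#' @param dep named character vector mapping dependent constants to their
#'   law direction
#' @param mg_ref Mg2+ concentration at which `base_rates` were calibrated,
#'   mmol/L (informational)
#' @param c_init initial saturation coefficient for the increasing laws,
#'   (mmol/L)^-1; the decreasing (release) law starts at ten times this,
#'   reflecting its saturation at much lower cofactor concentrations
#' @param settings a [fit_settings()]; the scatter-search span is forced
#'   to one decade
#' @return An object of class `dz_env_fit` with elements `mg_laws` (named
#'   list of `a`, `b`, `c`, `form`), `env`, `errors`, `rmse`, `aic`.
#' @export
fit_mg <- function(curves, base_rates,
                   dep = c(k_on = "increasing", k_clv = "increasing",
                           k_rls = "decreasing"),
                   mg_ref = 20, c_init = 0.05,
                   settings = fit_settings()) {
  stopifnot(inherits(curves, "curve_set"))
  mgs <- unique(curves$meta$mg_mm)
  if (length(mgs) < 3)
    stop("Mg2+ laws are not identifiable from fewer than 3 concentrations")
  if (all(mgs == 0))
    stop("all curves at 0 mmol/L Mg2+: the cleavage law is degenerate")
  base_rates <- as_rates(base_rates)

  # initialize each law at the scale of the base rate: amplitudes of the
  # order of the rate itself, slow saturation for the increasing laws and
  # fast decay for the decreasing (release) law
  k_base <- unclass(base_rates)
  laws0 <- lapply(names(dep), function(nm) {
    k <- max(k_base[nm], 1e-6)
    if (dep[[nm]] == "increasing") {
      list(a = if (nm == "k_clv") 0 else 0.05 * k, b = k, c = c_init,
           form = dep[[nm]])
    } else {
      list(a = 0.5 * k, b = k, c = 10 * c_init, form = dep[[nm]])
    }
  })
  names(laws0) <- names(dep)

  factory <- .factory_mg(dep, base_rates)
  clist <- curve_list(curves)
  resid <- .make_resid(clist, factory, settings$rtol, settings$atol)
  n_curve <- length(clist)
  ones <- rep(1, n_curve)
  par <- factory$to_par(laws0)
  names(par) <- factory$par_names
  stage_rmse <- c()

  # stage 1: one-decade scatter search + LM on the law parameters
  ess_set <- settings$ess
  ess_set$span <- 1
  obj <- function(v) sqrt(mean(resid$all(log10(v), ones, ones)^2))
  ess <- scatter_search(obj, setNames(10^par, factory$par_names),
                        settings = ess_set, seed = settings$seed)
  par <- setNames(log10(ess$best_par), factory$par_names)
  ref <- refine_least_squares(function(p) resid$all(p, ones, ones), par,
                              lower = rep(-10, length(par)),
                              upper = rep(6, length(par)),
                              maxiter = settings$lm_maxiter)
  par <- ref$par
  stage_rmse["laws_lm"] <- sqrt(ref$rss / resid$n_obs)

  # stage 2: per-curve error terms
  mg_laws <- factory$report(par)
  env <- environment_params(
    mg = lapply(mg_laws, function(p) list(a = p$a, b = p$b, c = p$c)),
    map = dependency_map(temperature = character(0),
                         mg = vapply(mg_laws, `[[`, character(1), "form")))
  errors <- estimate_error_terms(curves, base_rates, settings, env = env,
                                 resolve = "mg")
  res_vec <- resid$all(par, errors$err_s, errors$err_e)
  rss <- sum(res_vec^2)
  stage_rmse["error_terms"] <- sqrt(rss / resid$n_obs)
  n_params <- length(par) + 2 * n_curve

  sd_nat <- setNames(log(10) * (10^par) * ref$sd, factory$par_names)
  structure(list(
    mg_laws = mg_laws, mg_law_sd = sd_nat, base_rates = base_rates,
    env = env, errors = errors, dep = names(dep),
    rmse = sqrt(rss / resid$n_obs), rss = rss, n_obs = resid$n_obs,
    n_params = n_params, aic = aic_ls(rss, resid$n_obs, n_params),
    stage_rmse = stage_rmse, curves = curves, kind = "mg"),
    class = "dz_env_fit")
}

#' @export
print.dz_env_fit <- function(x, ...) {
  if (x$kind == "arrhenius") {
    cat("Arrhenius calibration (T_ref ", x$t_ref, " K)\n", sep = "")
    cat("  reference rates:\n")
    print(format(unclass(x$k_ref), digits = 4), quote = FALSE)
    cat("  activation energies (J/mol):\n")
    print(data.frame(e_a = signif(x$e_a, 4), sd = signif(x$e_a_sd, 3)))
  } else {
    cat("Mg2+ law calibration\n")
    for (nm in names(x$mg_laws)) {
      p <- x$mg_laws[[nm]]
      cat(sprintf("  %s (%s): a=%.4g b=%.4g c=%.4g\n", nm, p$form,
                  p$a, p$b, p$c))
    }
  }
  cat(sprintf("RMSE %.4g nmol/L | AIC %.2f | %d obs\n", x$rmse, x$aic, x$n_obs))
  invisible(x)
}
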