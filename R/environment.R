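#' Arrhenius temperature scaling of a rate constant
#'
#' `k = k_ref * exp((E_a / R) * (1 / T_ref - 1 / T))`, the Arrhenius law
#' written relative to a reference temperature so that `k(T_ref) = k_ref`.
#' Negative activation energies are allowed: DNA strand association is
#' known to slow down with temperature (anti-Arrhenius behavior).
#'
#' @param k_ref rate constant at the reference temperature
#' @param e_a activation energy, J/mol (any sign)
#' @param temp_k temperature of interest, K
#' @param t_ref reference temperature, K (default 328.15 K = 55 degrees C,
#'   the central working temperature of the assay)
#' @return The rate constant at `temp_k`, same units as `k_ref`.
#' @examples
#' arrhenius_rate(k_ref = 0.222, e_a = 5e4, temp_k = 333.15)
#' @export
arrhenius_rate <- function(k_ref, e_a, temp_k, t_ref = 328.15) {
  stopifnot(k_ref >= 0, t_ref > 0)
  if (any(temp_k <= 0)) stop("temperature must be positive (kelvin)")
  k_ref * exp((e_a / .GAS_R) * (1 / t_ref - 1 / temp_k))
}

#' Exponential magnesium dependence of a rate constant
#'
#' The catalytic cofactor Mg2+ modulates the rate constants exponentially,
#' either decreasingly, `k = a + b * exp(-c * mg)`, or increasingly
#' (saturating), `k = a + b * (1 - exp(-c * mg))`.  For the cleavage
#' constant the intercept is forced to `a = 0` because the DNAzyme is
#' catalytically inactive without Mg2+.
#'
#' @param mg Mg2+ concentration, mmol/L (non-negative)
#' @param a asymptote term, rate units
#' @param b amplitude, rate units
#' @param c saturation coefficient, (mmol/L)^-1
#' @param form `"increasing"` or `"decreasing"`
#' @return The rate constant at `mg`.
#' @examples
#' mg_rate(20, a = 0, b = 0.3, c = 0.03, form = "increasing")
#' @export
mg_rate <- function(mg, a, b, c, form = c("increasing", "decreasing")) {
  form <- match.arg(form)
  stopifnot(a >= 0, b >= 0, c >= 0)
  if (any(mg < 0)) stop("Mg2+ concentration must be non-negative")
  if (form == "decreasing") a + b * exp(-c * mg)
  else a + b * (1 - exp(-c * mg))
}

#' Condition dependence map of the rate constants
#'
#' Declares which rate constants respond to temperature (Arrhenius law)
#' and which respond to Mg2+ (exponential laws, with their direction).
#' The defaults reflect the retained model structure: temperature acts on
#' dissociation, cleavage and release (`k_on` and `k_bin` show minimal
#' temperature dependence), and Mg2+ acts increasingly on association and
#' cleavage and decreasingly on release (`k_off` and `k_bin` show little
#' Mg2+ dependence).
#'
#' @param temperature character vector of temperature-dependent constants
#' @param mg named character vector mapping Mg-dependent constants to
#'   `"increasing"` or `"decreasing"`
#' @return An object of class `dependency_map`.
#' @export
dependency_map <- function(temperature = c("k_off", "k_clv", "k_rls"),
                           mg = c(k_on = "increasing", k_clv = "increasing",
                                  k_rls = "decreasing")) {
  bad <- setdiff(c(temperature, names(mg)), .RATE_NAMES)
  if (length(bad)) stop("unknown rate constant(s): ", paste(bad, collapse = ", "))
  if (length(mg) && !all(mg %in% c("increasing", "decreasing")))
    stop("mg forms must be 'increasing' or 'decreasing'")
  structure(list(temperature = temperature, mg = mg),
            class = "dependency_map")
}

#' Environment parameter set
#'
#' Bundles per-constant Arrhenius parameters and Mg2+ law parameters with
#' the dependence map.  `arrhenius` is a named list of
#' `list(e_a = <J/mol>)` entries (the `k_ref` values are the base rate
#' constants themselves); `mg` is a named list of `list(a, b, c)` entries
#' whose direction comes from the map.
#'
#' @param arrhenius named list of Arrhenius entries, e.g.
#'   `list(k_clv = list(e_a = 8e4))`
#' @param mg named list of Mg-law entries, e.g.
#'   `list(k_clv = list(a = 0, b = 0.3, c = 0.03))`
#' @param map a [dependency_map()]
#' @param t_ref reference temperature, K
#' @return An object of class `environment_params`.
#' @export
environment_params <- function(arrhenius = list(), mg = list(),
                               map = dependency_map(names(arrhenius),
                                                    vapply(mg, function(z) z$form %||% "increasing",
                                                           character(1))),
                               t_ref = 328.15) {
  stopifnot(t_ref > 0)
  for (nm in names(mg)) {
    p <- mg[[nm]]
    stopifnot(all(c("a", "b", "c") %in% names(p)))
    if (nm == "k_clv" && p$a != 0)
      stop("the Mg2+ law of k_clv must have a = 0 (no cleavage without Mg2+)")
  }
  structure(list(arrhenius = arrhenius, mg = mg, map = map, t_ref = t_ref),
            class = "environment_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve rate constants at an environmental condition
#'
#' Maps a base set of rate constants (calibrated at the reference
#' condition) to the rate constants holding at temperature `temp_c` and/or
#' Mg2+ concentration `mg_mm`.  Constants in the temperature set are
#' transformed by the Arrhenius law with the base value as `k_ref`;
#' constants in the Mg set are evaluated from their exponential law
#' (which replaces the base value); constants in neither set pass through
#' unchanged.  A constant may not be subject to both layers at once: the
#' two dependences are calibrated on separate data sets and no joint
#' temperature-by-Mg model is defined.
#'
#' @param base a [rate_constants()] vector at the reference condition
#' @param env an [environment_params()] object
#' @param temp_c temperature, degrees C, or `NULL` to skip the layer
#' @param mg_mm Mg2+ concentration, mmol/L, or `NULL` to skip the layer
#' @return A `rate_constants` vector at the requested condition.
#' @export
resolve_rates <- function(base, env, temp_c = NULL, mg_mm = NULL) {
  base <- as_rates(base)
  if (is.null(env) || (is.null(temp_c) && is.null(mg_mm))) return(base)
  t_set <- if (!is.null(temp_c)) intersect(env$map$temperature, names(env$arrhenius)) else character(0)
  m_set <- if (!is.null(mg_mm)) intersect(names(env$map$mg), names(env$mg)) else character(0)
  both <- intersect(t_set, m_set)
  if (length(both))
    stop("rate constant(s) subject to both temperature and Mg2+ layers in ",
         "one resolution: ", paste(both, collapse = ", "),
         " (combined T x Mg fitting is not supported)")
  r <- unclass(base)
  for (nm in t_set) {
    r[nm] <- arrhenius_rate(r[nm], env$arrhenius[[nm]]$e_a,
                            temp_k = temp_c + 273.15, t_ref = env$t_ref)
  }
  for (nm in m_set) {
    p <- env$mg[[nm]]
    r[nm] <- mg_rate(mg_mm, p$a, p$b, p$c, form = env$map$mg[[nm]])
  }
  structure(r, class = "rate_constants")
}
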