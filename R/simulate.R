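#' Mass-action derivatives of the cleavage network
#'
#' Evaluates the right-hand side of the five-species reaction system.  The
#' observable of the assay is the cleaved fraction `EP + P`; the product
#' balance uses the release/binding pair `k_rls * EP - k_bin * E * P`, the
#' only closure of the reaction scheme that conserves both total substrate
#' (`S + ES + EP + P`) and total enzyme (`E + ES + EP`).
#'
#' @param state named numeric vector with components `S`, `E`, `ES`, `EP`,
#'   `P` (nmol/L)
#' @param rates a [rate_constants()] vector
#' @return Named numeric vector of time derivatives, nmol/L/s.
#' @examples
#' mass_action_rhs(c(S = 100, E = 10, ES = 0, EP = 0, P = 0),
#'                 reference_rates())
#' @export
mass_action_rhs <- function(state, rates) {
  rates <- as_rates(rates)
  if (!all(.SPECIES %in% names(state)))
    stop("state must name all of: ", paste(.SPECIES, collapse = ", "))
  s <- state[.SPECIES]
  if (!all(is.finite(s))) stop("state must be finite")
  v_on  <- rates[["k_on"]]  * s[["S"]] * s[["E"]]
  v_off <- rates[["k_off"]] * s[["ES"]]
  v_clv <- rates[["k_clv"]] * s[["ES"]]
  v_lig <- rates[["k_lig"]] * s[["EP"]]
  v_rls <- rates[["k_rls"]] * s[["EP"]]
  v_bin <- rates[["k_bin"]] * s[["E"]] * s[["P"]]
  c(S  = -v_on + v_off,
    E  = -v_on + v_off + v_rls - v_bin,
    ES =  v_on - v_off - v_clv + v_lig,
    EP =  v_clv - v_lig - v_rls + v_bin,
    P  =  v_rls - v_bin)
}

#' Observable signal of the assay
#'
#' The fluorescence readout tracks every cleaved substrate molecule whether
#' the product is still enzyme-bound or released, so the model observable is
#' the sum of the `EP` and `P` concentrations.
#'
#' @param state a named vector or data frame with `EP` and `P` components
#' @return `EP + P`, nmol/L.
#' @export
observable <- function(state) {
  if (is.data.frame(state)) state$EP + state$P
  else state[["EP"]] + state[["P"]]
}

#' Simulate a cleavage progress curve
#'
#' Integrates the mass-action system from `S(0) = err_s * s0`,
#' `E(0) = err_e * e0`, `ES(0) = EP(0) = P(0) = 0` over the requested time
#' grid with a stiff-capable adaptive solver ([deSolve::lsoda] driving the
#' package's compiled derivative function).  Tight default tolerances
#' (rtol 1e-10, atol 1e-10 nmol/L) are chosen because the rate constants
#' of this reaction span four orders of magnitude; fitting uses a slightly
#' looser relative tolerance (see [fit_settings()]) since solver error is
#' then far below measurement noise.
#'
#' @param rates a [rate_constants()] vector
#' @param s0 nominal substrate concentration, nmol/L
#' @param e0 nominal DNAzyme concentration, nmol/L
#' @param times output time grid in seconds, non-negative and strictly
#'   increasing; a leading 0 is added internally if absent
#' @param err_s,err_e multiplicative concentration errors applied to the
#'   nominal values (pipetting-inaccuracy terms), default 1
#' @param rtol,atol relative / absolute solver tolerances
#' @param method integration method passed to [deSolve::ode]
#' @param compiled use the compiled derivative function (fast path); set to
#'   `FALSE` to integrate the plain-R [mass_action_rhs()] instead
#' @return A data frame of class `dz_trajectory` with columns `time_s`,
#'   `S`, `E`, `ES`, `EP`, `P`, `observable`.
#' @examples
#' tr <- simulate_reaction(reference_rates(), s0 = 1000, e0 = 10,
#'                         times = seq(0, 1500, 30))
#' head(tr)
#' @export
simulate_reaction <- function(rates, s0, e0, times, err_s = 1, err_e = 1,
                              rtol = 1e-10, atol = 1e-10, method = "lsoda",
                              compiled = TRUE) {
  rates <- as_rates(rates)
  stopifnot(s0 >= 0, e0 >= 0, err_s > 0, err_e > 0, rtol > 0, atol > 0)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(times < 0)) stop("times must be non-negative")

  grid <- times
  prepend <- length(grid) == 0L || grid[1] > 0
  if (prepend) grid <- c(0, grid)

  y0 <- c(S = err_s * s0, E = err_e * e0, ES = 0, EP = 0, P = 0)
  if (compiled) {
    out <- deSolve::ode(y = y0, times = grid, func = "dzkin_derivs",
                        parms = unname(unclass(rates)[.RATE_NAMES]),
                        dllname = "dzkin", initfunc = "dzkin_initmod",
                        rtol = rtol, atol = atol, method = method)
  } else {
    out <- deSolve::ode(y = y0, times = grid,
                        func = function(t, y, p) list(mass_action_rhs(y, p)),
                        parms = rates, rtol = rtol, atol = atol,
                        method = method)
  }
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed (istate = ", attr(out, "istate")[1],
         ") at rates: ", paste(signif(rates, 4), collapse = ", "))
  out <- as.data.frame(out)
  names(out)[1] <- "time_s"
  if (prepend) out <- out[-1, , drop = FALSE]
  rownames(out) <- NULL
  out$observable <- out$EP + out$P
  class(out) <- c("dz_trajectory", "data.frame")
  out
}

#' Fixed-step reference integration of a progress curve
#'
#' Brute-force classical 4th-order Runge-Kutta at a small fixed step
#' (default 1 ms), used as an independent reference for the adaptive
#' solver.  Slower but free of step-size control.
#'
#' @inheritParams simulate_reaction
#' @param dt fixed step size, seconds
#' @return A `dz_trajectory` data frame.
#' @export
simulate_reaction_rk4 <- function(rates, s0, e0, times, err_s = 1,
                                  err_e = 1, dt = 1e-3) {
  rates <- as_rates(rates)
  stopifnot(s0 >= 0, e0 >= 0, err_s > 0, err_e > 0, dt > 0)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  grid <- times
  prepend <- grid[1] > 0
  if (prepend) grid <- c(0, grid)
  y0 <- c(err_s * s0, err_e * e0, 0, 0, 0)
  out <- .Call("dzkin_rk4", as.numeric(y0),
               as.numeric(unclass(rates)[.RATE_NAMES]), as.numeric(grid),
               as.numeric(dt), PACKAGE = "dzkin")
  out <- as.data.frame(out)
  if (prepend) out <- out[-1, , drop = FALSE]
  rownames(out) <- NULL
  out$observable <- out$EP + out$P
  class(out) <- c("dz_trajectory", "data.frame")
  out
}

# Fast path used by the fitting code: observable only, no validation
# beyond the solver's own.  `rates_vec` is an unnamed numeric of length 6
# in canonical order.
sim_observable <- function(rates_vec, s0, e0, times, err_s = 1, err_e = 1,
                           rtol = 1e-8, atol = 1e-10) {
  grid <- times
  prepend <- grid[1] > 0
  if (prepend) grid <- c(0, grid)
  y0 <- c(S = err_s * s0, E = err_e * e0, ES = 0, EP = 0, P = 0)
  # lsoda occasionally refuses a tolerance as too tight for the local
  # scale; retry with progressively relaxed tolerances before giving up
  out <- NULL
  for (relax in c(1, 10, 100)) {
    out <- suppressWarnings(
      deSolve::ode(y = y0, times = grid, func = "dzkin_derivs",
                   parms = rates_vec, dllname = "dzkin",
                   initfunc = "dzkin_initmod",
                   rtol = rtol * relax, atol = atol * relax,
                   method = "lsoda"))
    if (attr(out, "istate")[1] >= 0 && nrow(out) == length(grid)) break
  }
  if (attr(out, "istate")[1] < 0 || nrow(out) < length(grid))
    stop("ODE integration failed at rates: ",
         paste(signif(rates_vec, 4), collapse = ", "))
  obs <- out[, "EP"] + out[, "P"]
  if (prepend) obs <- obs[-1]
  obs
}
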