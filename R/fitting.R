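#' Optimizer settings for the staged fit
#'
#' @param ess settings for the scatter-search stage, see [ess_settings()]
#' @param rtol,atol ODE solver tolerances used during fitting
#' @param err_bounds lower/upper bounds for the per-curve error terms
#' @param lm_maxiter maximum Levenberg-Marquardt iterations per stage
#' @param joint_maxiter maximum iterations of the final joint refit
#' @param rate_bounds_log10 box for the rate constants in log10 space
#' @param seed integer seed used by the stochastic stages
#' @return A list of class `fit_settings`.
#' @export
fit_settings <- function(ess = ess_settings(), rtol = 1e-8, atol = 1e-10,
                         err_bounds = c(0.2, 10), lm_maxiter = 60,
                         joint_maxiter = 40, rate_bounds_log10 = c(-8, 4),
                         seed = NULL) {
  stopifnot(rtol > 0, atol > 0, err_bounds[1] > 0,
            err_bounds[1] < err_bounds[2])
  structure(list(ess = ess, rtol = rtol, atol = atol,
                 err_bounds = err_bounds, lm_maxiter = lm_maxiter,
                 joint_maxiter = joint_maxiter,
                 rate_bounds_log10 = rate_bounds_log10, seed = seed),
            class = "fit_settings")
}

#' Scatter-search settings
#'
#' @param span half-width of the search box, in orders of magnitude around
#'   the initial values (2 for the base fit, 1 for the Mg2+ layer)
#' @param n_sample space-filling candidates drawn in the box
#' @param n_elite size of the elite reference set
#' @param n_recombine children generated by recombining elite pairs
#' @param n_polish top candidates refined by a short local search
#' @param polish_maxit Nelder-Mead iterations per polish
#' @return A list of class `ess_settings`.
#' @export
ess_settings <- function(span = 2, n_sample = 48, n_elite = 6,
                         n_recombine = 12, n_polish = 2, polish_maxit = 40) {
  stopifnot(span > 0, n_sample >= 1, n_elite >= 2, n_polish >= 0)
  structure(list(span = span, n_sample = n_sample, n_elite = n_elite,
                 n_recombine = n_recombine, n_polish = n_polish,
                 polish_maxit = polish_maxit),
            class = "ess_settings")
}

#' Default initial rate constants for the staged fit
#'
#' Order-of-magnitude starting guesses used when no initial values are
#' supplied: they place every constant within the two-decade scatter-search
#' box of plausible values for nucleic-acid hybridization and catalysis at
#' the assay's concentration scale.
#'
#' @return A [rate_constants()] vector.
#' @export
default_init_rates <- function() {
  rate_constants(k_on = 1e-3, k_off = 0.1, k_clv = 0.1, k_lig = 0.01,
                 k_rls = 1, k_bin = 0.01)
}

# ---------------------------------------------------------------------------
# residual machinery

# Predicted observable for one curve entry from curve_list()
.pred_curve <- function(rates_full, cl, err_s, err_e, rtol, atol) {
  sim_observable(unname(rates_full[.RATE_NAMES]), cl$s0, cl$e0, cl$times,
                 err_s = err_s, err_e = err_e, rtol = rtol, atol = atol)
}

# Parameterization: base model.  Optimization parameters are the log10 of
# the variant's free rate constants; clamped constants stay at zero.
.factory_basic <- function(variant) {
  free <- free_rate_names(variant)
  full0 <- setNames(numeric(6), .RATE_NAMES)
  list(
    kind = "basic",
    par_names = paste0("log10_", free),
    to_par = function(rates) log10(pmax(unclass(rates)[free], 1e-8)),
    rates_for_curve = function(par, cl) {
      r <- full0
      r[free] <- 10^par
      r
    },
    report = function(par) {
      r <- full0
      r[free] <- 10^par
      structure(r, class = "rate_constants")
    })
}

# Parameterization: Arrhenius layer.  log10 reference rates for the free
# constants plus activation energies (in 1e4 J/mol) for the dependent set.
.factory_arrhenius <- function(variant, dep, t_ref) {
  free <- free_rate_names(variant)
  dep <- intersect(dep, free)
  full0 <- setNames(numeric(6), .RATE_NAMES)
  nk <- length(free)
  list(
    kind = "arrhenius", free = free, dep = dep, nk = nk, t_ref = t_ref,
    par_names = c(paste0("log10_", free), paste0("ea4_", dep)),
    to_par = function(k_ref, e_a) c(log10(pmax(k_ref[free], 1e-8)),
                                    e_a[dep] / 1e4),
    rates_for_curve = function(par, cl) {
      r <- full0
      r[free] <- 10^par[seq_len(nk)]
      ea <- setNames(par[nk + seq_along(dep)] * 1e4, dep)
      for (nm in dep)
        r[nm] <- arrhenius_rate(r[nm], ea[nm],
                                temp_k = cl$temperature_c + 273.15,
                                t_ref = t_ref)
      r
    },
    report = function(par) {
      k_ref <- full0
      k_ref[free] <- 10^par[seq_len(nk)]
      list(k_ref = structure(k_ref, class = "rate_constants"),
           e_a = setNames(par[nk + seq_along(dep)] * 1e4, dep))
    })
}

# Parameterization: Mg2+ layer.  log10 of the exponential-law parameters
# (a, b, c) per dependent constant -- a is dropped (fixed 0) for k_clv --
# with the non-dependent constants frozen at their base-fit values.
.factory_mg <- function(dep_forms, fixed_rates) {
  dep <- names(dep_forms)
  par_names <- unlist(lapply(dep, function(nm) {
    abc <- if (nm == "k_clv") c("b", "c") else c("a", "b", "c")
    paste0("log10_", abc, "_", nm)
  }))
  full0 <- unclass(fixed_rates)[.RATE_NAMES]
  unpack <- function(par) {
    out <- list(); i <- 0
    for (nm in dep) {
      if (nm == "k_clv") {
        out[[nm]] <- list(a = 0, b = unname(10^par[i + 1]),
                          c = unname(10^par[i + 2]), form = dep_forms[[nm]])
        i <- i + 2
      } else {
        out[[nm]] <- list(a = unname(10^par[i + 1]),
                          b = unname(10^par[i + 2]),
                          c = unname(10^par[i + 3]), form = dep_forms[[nm]])
        i <- i + 3
      }
    }
    out
  }
  list(
    kind = "mg", dep = dep, par_names = par_names, unpack = unpack,
    to_par = function(laws) {
      unlist(lapply(dep, function(nm) {
        p <- laws[[nm]]
        v <- if (nm == "k_clv") c(p$b, p$c) else c(p$a, p$b, p$c)
        log10(pmax(v, 1e-10))
      }))
    },
    rates_for_curve = function(par, cl) {
      r <- full0
      laws <- unpack(par)
      for (nm in dep)
        r[nm] <- mg_rate(cl$mg_mm, laws[[nm]]$a, laws[[nm]]$b,
                         laws[[nm]]$c, form = laws[[nm]]$form)
      r
    },
    report = function(par) unpack(par))
}

# Stacked residuals and curve-local residuals for a factory + curve set.
.make_resid <- function(clist, factory, rtol, atol) {
  n_per <- vapply(clist, function(cl) length(cl$times), integer(1))
  list(
    n_obs = sum(n_per), n_per = n_per,
    curve = function(par, i, err_s, err_e) {
      cl <- clist[[i]]
      r <- factory$rates_for_curve(par, cl)
      cl$values - .pred_curve(r, cl, err_s, err_e, rtol, atol)
    },
    all = function(par, err_s_vec, err_e_vec) {
      unlist(lapply(seq_along(clist), function(i) {
        cl <- clist[[i]]
        r <- factory$rates_for_curve(par, cl)
        cl$values - .pred_curve(r, cl, err_s_vec[i], err_e_vec[i],
                                rtol, atol)
      }), use.names = FALSE)
    })
}

#' Pooled root-mean-square error of the model against a curve set
#'
#' Simulates the observable EP + P for every curve at the supplied rate
#' constants (and optional per-curve error terms) and returns the RMSE
#' pooled over all points of all curves.
#'
#' @param curves a [curve_set()]
#' @param rates a [rate_constants()] vector
#' @param errors optional data frame with `curve_id`, `err_s`, `err_e`;
#'   both default to 1
#' @param env optional [environment_params()]; when given, rates are
#'   resolved to each curve's condition through the layer(s) in `resolve`
#' @param resolve which layers to apply when `env` is given
#' @param settings a [fit_settings()] (solver tolerances)
#' @return RMSE in nmol/L.
#' @export
objective_rmse <- function(curves, rates, errors = NULL, env = NULL,
                           resolve = c("temperature", "mg"),
                           settings = fit_settings()) {
  stopifnot(inherits(curves, "curve_set"))
  rates <- as_rates(rates)
  clist <- curve_list(curves)
  err <- .align_errors(errors, curves)
  res <- unlist(lapply(seq_along(clist), function(i) {
    cl <- clist[[i]]
    r <- if (!is.null(env)) {
      resolve_rates(rates, env,
                    temp_c = if ("temperature" %in% resolve) cl$temperature_c else NULL,
                    mg_mm = if ("mg" %in% resolve) cl$mg_mm else NULL)
    } else rates
    cl$values - .pred_curve(unclass(r), cl, err$err_s[i], err$err_e[i],
                            settings$rtol, settings$atol)
  }), use.names = FALSE)
  sqrt(mean(res^2))
}

.align_errors <- function(errors, curves) {
  ids <- curves$meta$curve_id
  if (is.null(errors))
    return(data.frame(curve_id = ids, err_s = 1, err_e = 1))
  m <- match(ids, errors$curve_id)
  if (anyNA(m)) stop("errors must cover every curve_id")
  data.frame(curve_id = ids, err_s = errors$err_s[m], err_e = errors$err_e[m])
}

# ---------------------------------------------------------------------------
# scatter search

#' Enhanced scatter search over a log-uniform box
#'
#' Global pre-optimization stage: draws space-filling (Latin hypercube)
#' candidates log-uniformly within `span` orders of magnitude around the
#' initial values, recombines elite pairs in log space, polishes the best
#' candidates with a short Nelder-Mead local search, and returns the
#' ranked candidate list.  The incumbent initial point is always included,
#' so the best candidate is never worse than the start.  Fully
#' deterministic under a fixed seed.
#'
#' @param objective function of a positive named parameter vector
#'   returning a scalar to minimize
#' @param init strictly positive named initial parameter vector
#' @param settings an [ess_settings()]
#' @param seed integer seed
#' @param lower_log10,upper_log10 optional explicit box in log10 space,
#'   overriding the span-around-init default
#' @return A list with `best_par`, `best_objective`, `candidates` (data
#'   frame of parameters and objectives, ranked) and `n_eval`.
#' @export
scatter_search <- function(objective, init, settings = ess_settings(),
                           seed = NULL, lower_log10 = NULL,
                           upper_log10 = NULL) {
  stopifnot(all(init > 0), all(is.finite(init)))
  d <- length(init)
  l0 <- log10(init)
  lo <- if (is.null(lower_log10)) l0 - settings$span else lower_log10
  hi <- if (is.null(upper_log10)) l0 + settings$span else upper_log10
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  nm <- names(init) %||% paste0("p", seq_len(d))

  # stratified Latin hypercube in log10 space, plus the incumbent
  n <- settings$n_sample
  U <- vapply(seq_len(d), function(j)
    (sample.int(n) - runif(n)) / n, numeric(n))
  X <- sweep(sweep(U, 2, hi - lo, "*"), 2, lo, "+")
  X <- rbind(l0, X)

  f_log <- function(lx) {
    v <- tryCatch(objective(setNames(10^lx, nm)), error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }
  obj <- apply(X, 1, f_log)

  # recombine elite pairs: extended convex combinations in log space
  ord <- order(obj)
  elite <- X[ord[seq_len(min(settings$n_elite, nrow(X)))], , drop = FALSE]
  if (settings$n_recombine > 0 && nrow(elite) >= 2) {
    kids <- t(vapply(seq_len(settings$n_recombine), function(k) {
      ij <- sample.int(nrow(elite), 2)
      alpha <- runif(d, -0.3, 1.3)
      pmin(pmax(alpha * elite[ij[1], ] + (1 - alpha) * elite[ij[2], ], lo), hi)
    }, numeric(d)))
    X <- rbind(X, kids)
    obj <- c(obj, apply(kids, 1, f_log))
  }

  # local polish of the top candidates
  n_eval <- length(obj)
  if (settings$n_polish > 0) {
    ord <- order(obj)
    for (i in ord[seq_len(min(settings$n_polish, length(ord)))]) {
      op <- optim(X[i, ], f_log, method = "Nelder-Mead",
                  control = list(maxit = settings$polish_maxit))
      n_eval <- n_eval + op$counts[1]
      if (is.finite(op$value) && op$value < obj[i]) {
        X <- rbind(X, pmin(pmax(op$par, lo), hi))
        obj <- c(obj, f_log(X[nrow(X), ]))
      }
    }
  }
  if (!any(is.finite(obj)))
    stop("scatter search exhausted its budget without a finite objective")
  ord <- order(obj)
  cand <- as.data.frame(10^X[ord, , drop = FALSE])
  names(cand) <- nm
  cand$objective <- obj[ord]
  rownames(cand) <- NULL
  list(best_par = setNames(10^X[ord[1], ], nm), best_objective = obj[ord[1]],
       candidates = cand, n_eval = n_eval)
}

# ---------------------------------------------------------------------------
# Levenberg-Marquardt refinement

#' Nonlinear least-squares refinement
#'
#' Thin wrapper around Levenberg-Marquardt ([minpack.lm::nls.lm]) that
#' returns the estimates together with the Jacobian-based covariance and
#' per-parameter standard deviations, and flags rank-deficient problems
#' (condition number of the Jacobian above `cond_tol`).
#'
#' @param resid_fun function of the parameter vector returning the
#'   residual vector
#' @param init initial parameter vector (finite, inside bounds)
#' @param lower,upper parameter bounds
#' @param jac optional analytic/structured Jacobian function
#' @param maxiter maximum iterations
#' @param cond_tol condition-number threshold for the identifiability
#'   warning
#' @return A list with `par`, `sd`, `cov`, `rss`, `residuals`,
#'   `converged`, `message`, `niter`, `jac_cond`.
#' @export
refine_least_squares <- function(resid_fun, init, lower = NULL, upper = NULL,
                                 jac = NULL, maxiter = 60, cond_tol = 1e8) {
  stopifnot(all(is.finite(init)))
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-10,
                                     ptol = 1e-10)
  fit <- minpack.lm::nls.lm(par = init, fn = resid_fun, jac = jac,
                            lower = lower, upper = upper, control = ctrl)
  if (fit$info == 0 || fit$info == 9)
    stop("least-squares refinement failed to converge: ", fit$message)
  par <- fit$par
  res <- fit$fvec
  rss <- sum(res^2)
  J <- if (!is.null(jac)) jac(par) else .fd_jac(resid_fun, par, lower, upper)
  sv <- svd(J, nu = 0, nv = 0)$d
  jac_cond <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  if (jac_cond > cond_tol)
    warning("Jacobian at the optimum is near rank-deficient (condition ",
            format(jac_cond, digits = 3),
            "); some parameters may not be identifiable")
  n <- length(res); p <- length(par)
  sigma2 <- if (n > p) rss / (n - p) else NA_real_
  cov <- tryCatch(sigma2 * solve(crossprod(J)),
                  error = function(e) matrix(NA_real_, p, p))
  sd <- sqrt(pmax(diag(cov), 0))
  names(sd) <- names(par)
  list(par = par, sd = sd, cov = cov, rss = rss, residuals = res,
       converged = fit$info %in% 1:4, message = fit$message,
       niter = fit$niter, jac_cond = jac_cond)
}

.fd_jac <- function(resid_fun, par, lower = NULL, upper = NULL) {
  r0 <- resid_fun(par)
  J <- matrix(0, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- 1e-6 * max(1, abs(par[j]))
    pj <- par; pj[j] <- pj[j] + h
    if (!is.null(upper) && pj[j] > upper[j]) { pj[j] <- par[j] - h; h <- -h }
    J[, j] <- (resid_fun(pj) - r0) / h
  }
  J
}

# Structured finite-difference Jacobian for the joint problem: model
# parameters touch every curve; each error term touches one curve only.
.joint_jac <- function(resid, n_model, n_curve, n_per) {
  offsets <- c(0, cumsum(n_per))
  function(par) {
    pm <- par[seq_len(n_model)]
    es <- par[n_model + seq_len(n_curve)]
    ee <- par[n_model + n_curve + seq_len(n_curve)]
    r0 <- lapply(seq_len(n_curve), function(i)
      resid$curve(pm, i, es[i], ee[i]))
    r0v <- unlist(r0, use.names = FALSE)
    J <- matrix(0, length(r0v), length(par))
    for (j in seq_len(n_model)) {
      h <- 1e-6 * max(1, abs(pm[j]))
      pj <- pm; pj[j] <- pj[j] + h
      rj <- unlist(lapply(seq_len(n_curve), function(i)
        resid$curve(pj, i, es[i], ee[i])), use.names = FALSE)
      J[, j] <- (rj - r0v) / h
    }
    for (i in seq_len(n_curve)) {
      rows <- (offsets[i] + 1):offsets[i + 1]
      h <- 1e-6 * max(1, es[i])
      J[rows, n_model + i] <-
        (resid$curve(pm, i, es[i] + h, ee[i]) - r0[[i]]) / h
      h <- 1e-6 * max(1, ee[i])
      J[rows, n_model + n_curve + i] <-
        (resid$curve(pm, i, es[i], ee[i] + h) - r0[[i]]) / h
    }
    J
  }
}

# ---------------------------------------------------------------------------
# error terms

#' Estimate per-curve concentration error terms
#'
#' With the rate constants held fixed, fits the two multiplicative
#' concentration errors (ErrS, ErrE) of each curve separately by
#' least squares on that curve's residuals, within `err_bounds`
#' (default [0.2, 10]).  Curves with fewer than 5 points are skipped with
#' a warning (errors left at 1).
#'
#' @param curves a [curve_set()]
#' @param rates fixed [rate_constants()] from a prior stage
#' @param settings a [fit_settings()]
#' @param env,resolve optional environment layer(s), as in
#'   [objective_rmse()]
#' @return Data frame with `curve_id`, `err_s`, `err_e`, `converged`.
#' @export
estimate_error_terms <- function(curves, rates, settings = fit_settings(),
                                 env = NULL, resolve = c("temperature", "mg")) {
  stopifnot(inherits(curves, "curve_set"))
  rates <- as_rates(rates)
  clist <- curve_list(curves)
  lo <- settings$err_bounds[1]; hi <- settings$err_bounds[2]
  out <- lapply(clist, function(cl) {
    if (length(cl$times) < 5) {
      warning("curve ", cl$curve_id, " has fewer than 5 points; ",
              "error terms left at 1")
      return(data.frame(curve_id = cl$curve_id, err_s = 1, err_e = 1,
                        converged = FALSE))
    }
    r <- if (!is.null(env)) {
      resolve_rates(rates, env,
                    temp_c = if ("temperature" %in% resolve) cl$temperature_c else NULL,
                    mg_mm = if ("mg" %in% resolve) cl$mg_mm else NULL)
    } else rates
    rv <- unclass(r)
    fn <- function(p) cl$values - .pred_curve(rv, cl, p[1], p[2],
                                              settings$rtol, settings$atol)
    fit <- minpack.lm::nls.lm(par = c(err_s = 1, err_e = 1), fn = fn,
                              lower = c(lo, lo), upper = c(hi, hi),
                              control = minpack.lm::nls.lm.control(maxiter = 30))
    data.frame(curve_id = cl$curve_id, err_s = fit$par[1],
               err_e = fit$par[2], converged = fit$info %in% 1:4)
  })
  do.call(rbind, out)
}

# ---------------------------------------------------------------------------
# staged workflow

#' Staged estimation of the rate constants from progress curves
#'
#' The full calibration workflow, fitting all curves simultaneously:
#' \enumerate{
#'   \item scatter search over two orders of magnitude around the initial
#'     rate constants (error terms at 1);
#'   \item Levenberg-Marquardt refinement of the rate constants in log10
#'     space;
#'   \item per-curve estimation of the concentration error terms with the
#'     rates frozen;
#'   \item joint refinement of rates and all error terms together.
#' }
#' The objective never increases from stage to stage.  The observable
#' compared with the data is the summed concentration of enzyme-bound and
#' free product, EP + P.
#'
#' @param curves a [curve_set()]
#' @param variant a [model_variant()] or its name
#' @param init initial [rate_constants()]; defaults to
#'   [default_init_rates()]
#' @param settings a [fit_settings()]
#' @param stages subset of `1:4` to run (mainly for diagnostics)
#' @return An object of class `dz_fit`; see [print.dz_fit()].
#' @examples
#' \donttest{
#' cs <- generate_curve_set(experiment_design(substrate_nm = c(250, 1000),
#'                                            replicates = 2), seed = 1)
#' fit <- fit_kinetics(cs, "no_ligation",
#'                     settings = fit_settings(seed = 1))
#' fit
#' }
#' @export
fit_kinetics <- function(curves, variant = "no_ligation", init = NULL,
                         settings = fit_settings(), stages = 1:4) {
  stopifnot(inherits(curves, "curve_set"))
  variant <- as_variant(variant)
  factory <- .factory_basic(variant)
  clist <- curve_list(curves)
  resid <- .make_resid(clist, factory, settings$rtol, settings$atol)
  n_curve <- length(clist)
  init <- as_rates(init %||% default_init_rates())
  par <- factory$to_par(init)
  names(par) <- factory$par_names
  lo <- rep(settings$rate_bounds_log10[1], length(par))
  hi <- rep(settings$rate_bounds_log10[2], length(par))
  ones <- rep(1, n_curve)
  stage_rmse <- c()
  rmse_of <- function(p, es, ee) sqrt(mean(resid$all(p, es, ee)^2))

  # stage 1: scatter search on the rates, errors at 1
  if (1 %in% stages) {
    free <- free_rate_names(variant)
    obj <- function(k) {
      p <- log10(k)
      sqrt(mean(resid$all(p, ones, ones)^2))
    }
    ess <- scatter_search(obj, setNames(10^par, free),
                          settings = settings$ess, seed = settings$seed)
    par <- setNames(log10(ess$best_par), factory$par_names)
    stage_rmse["scatter_search"] <- ess$best_objective
  }
  par <- pmin(pmax(par, lo), hi)

  # stage 2: LM on the rates in log10 space, errors at 1
  sd_rates <- NULL; conv <- list(); jac_cond <- NA_real_
  if (2 %in% stages) {
    ref <- refine_least_squares(function(p) resid$all(p, ones, ones),
                                par, lower = lo, upper = hi,
                                maxiter = settings$lm_maxiter)
    par <- ref$par
    stage_rmse["rates_lm"] <- sqrt(ref$rss / resid$n_obs)
    conv$rates <- ref$message
  }

  # stage 3: per-curve error terms with rates frozen
  errors <- data.frame(curve_id = curves$meta$curve_id, err_s = 1,
                       err_e = 1, converged = TRUE)
  if (3 %in% stages) {
    errors <- estimate_error_terms(curves, factory$report(par), settings)
    stage_rmse["error_terms"] <- rmse_of(par, errors$err_s, errors$err_e)
  }

  # stage 4: joint refinement of rates + error terms
  if (4 %in% stages) {
    pj <- c(par, setNames(errors$err_s, paste0("err_s_", errors$curve_id)),
            setNames(errors$err_e, paste0("err_e_", errors$curve_id)))
    n_model <- length(par)
    lo_j <- c(lo, rep(settings$err_bounds[1], 2 * n_curve))
    hi_j <- c(hi, rep(settings$err_bounds[2], 2 * n_curve))
    fn <- function(p) resid$all(p[seq_len(n_model)],
                                p[n_model + seq_len(n_curve)],
                                p[n_model + n_curve + seq_len(n_curve)])
    jac <- .joint_jac(resid, n_model, n_curve, resid$n_per)
    ref <- refine_least_squares(fn, pj, lower = lo_j, upper = hi_j,
                                jac = jac, maxiter = settings$joint_maxiter)
    par <- ref$par[seq_len(n_model)]
    errors$err_s <- unname(ref$par[n_model + seq_len(n_curve)])
    errors$err_e <- unname(ref$par[n_model + n_curve + seq_len(n_curve)])
    stage_rmse["joint"] <- sqrt(ref$rss / resid$n_obs)
    conv$joint <- ref$message
    jac_cond <- ref$jac_cond
    # delta-method SDs on the natural scale for the rate constants
    sd_log <- ref$sd[seq_len(n_model)]
    sd_rates <- setNames(log(10) * (10^par) * sd_log, free_rate_names(variant))
  }

  rates_hat <- factory$report(par)
  res_vec <- resid$all(par, errors$err_s, errors$err_e)
  rss <- sum(res_vec^2)
  n_obs <- resid$n_obs
  n_params <- length(par) + 2 * n_curve
  fitted <- curves$observations$conc_nm - res_vec

  structure(list(
    rates = rates_hat, rate_sd = sd_rates, errors = errors,
    residuals = data.frame(curve_id = curves$observations$curve_id,
                           time_s = curves$observations$time_s,
                           observed = curves$observations$conc_nm,
                           fitted = fitted, residual = res_vec),
    rmse = sqrt(rss / n_obs), rss = rss, n_obs = n_obs,
    n_params = n_params, aic = aic_ls(rss, n_obs, n_params),
    variant = variant, free = free_rate_names(variant),
    stage_rmse = stage_rmse, convergence = conv, jac_cond = jac_cond,
    settings = settings, curves = curves, env = NULL),
    class = "dz_fit")
}

#' Joint refit of rates and error terms from given starting values
#'
#' Runs only the final simultaneous optimization stage of
#' [fit_kinetics()], starting from supplied rate constants and per-curve
#' error terms.  This is the refit used on bootstrap data sets.
#'
#' @param curves a [curve_set()]
#' @param rates_init starting [rate_constants()]
#' @param errors_init starting error-term data frame (`curve_id`, `err_s`,
#'   `err_e`); defaults to all 1
#' @param variant a [model_variant()] or its name
#' @param settings a [fit_settings()]
#' @return A `dz_fit`.
#' @export
joint_refit <- function(curves, rates_init, errors_init = NULL,
                        variant = "no_ligation",
                        settings = fit_settings()) {
  variant <- as_variant(variant)
  stopifnot(inherits(curves, "curve_set"))
  factory <- .factory_basic(variant)
  clist <- curve_list(curves)
  resid <- .make_resid(clist, factory, settings$rtol, settings$atol)
  n_curve <- length(clist)
  par <- factory$to_par(as_rates(rates_init))
  names(par) <- factory$par_names
  errors <- .align_errors(errors_init, curves)
  pj <- c(par, errors$err_s, errors$err_e)
  n_model <- length(par)
  lo_j <- c(rep(settings$rate_bounds_log10[1], n_model),
            rep(settings$err_bounds[1], 2 * n_curve))
  hi_j <- c(rep(settings$rate_bounds_log10[2], n_model),
            rep(settings$err_bounds[2], 2 * n_curve))
  fn <- function(p) resid$all(p[seq_len(n_model)],
                              p[n_model + seq_len(n_curve)],
                              p[n_model + n_curve + seq_len(n_curve)])
  jac <- .joint_jac(resid, n_model, n_curve, resid$n_per)
  ref <- refine_least_squares(fn, pj, lower = lo_j, upper = hi_j, jac = jac,
                              maxiter = settings$joint_maxiter)
  par <- setNames(ref$par[seq_len(n_model)], factory$par_names)
  errors$err_s <- unname(ref$par[n_model + seq_len(n_curve)])
  errors$err_e <- unname(ref$par[n_model + n_curve + seq_len(n_curve)])
  res_vec <- resid$all(par, errors$err_s, errors$err_e)
  rss <- sum(res_vec^2)
  n_obs <- resid$n_obs
  n_params <- n_model + 2 * n_curve
  sd_log <- ref$sd[seq_len(n_model)]
  structure(list(
    rates = factory$report(par),
    rate_sd = setNames(log(10) * (10^par) * sd_log, free_rate_names(variant)),
    errors = errors,
    residuals = data.frame(curve_id = curves$observations$curve_id,
                           time_s = curves$observations$time_s,
                           observed = curves$observations$conc_nm,
                           fitted = curves$observations$conc_nm - res_vec,
                           residual = res_vec),
    rmse = sqrt(rss / n_obs), rss = rss, n_obs = n_obs,
    n_params = n_params, aic = aic_ls(rss, n_obs, n_params),
    variant = variant, free = free_rate_names(variant),
    stage_rmse = c(joint = sqrt(rss / n_obs)),
    convergence = list(joint = ref$message), jac_cond = ref$jac_cond,
    settings = settings, curves = curves, env = NULL),
    class = "dz_fit")
}

#' @export
print.dz_fit <- function(x, ...) {
  cat("DNAzyme kinetic fit (", x$variant$name, ")\n", sep = "")
  est <- unclass(x$rates)[x$free]
  tab <- data.frame(estimate = signif(est, 4))
  if (!is.null(x$rate_sd)) tab$sd <- signif(x$rate_sd[x$free], 3)
  print(tab)
  cat(sprintf("RMSE %.4g nmol/L | AIC %.2f | %d obs, %d params, %d curves\n",
              x$rmse, x$aic, x$n_obs, x$n_params, nrow(x$errors)))
  invisible(x)
}

#' Akaike's information criterion for a least-squares fit
#'
#' The least-squares form `n * log(RSS/n) + 2 * (p + 1)`, counting the
#' residual variance as one extra parameter.  Only AIC differences between
#' variants fit on the same data are meaningful.
#'
#' @param rss residual sum of squares
#' @param n_obs number of observations (> `n_params`)
#' @param n_params number of free parameters
#' @return AIC (dimensionless); `-Inf` with a warning when `rss` is 0.
#' @examples
#' aic_ls(100, 100, 3)  # 100*log(1) + 2*4 = 8
#' @export
aic_ls <- function(rss, n_obs, n_params) {
  stopifnot(n_obs > n_params)
  if (rss <= 0) {
    warning("RSS is zero; AIC is -Inf")
    return(-Inf)
  }
  n_obs * log(rss / n_obs) + 2 * (n_params + 1)
}

#' Fit and compare model variants
#'
#' Fits each variant by the full staged workflow and tabulates estimates,
#' standard deviations, RMSE and AIC.  Selection rule: the lowest-AIC
#' variant wins, unless it carries estimates not significantly different
#' from zero (estimate < 2 SD), in which case the next-best fully
#' significant variant is preferred; among variants within 2 AIC units the
#' one with fewer parameters is taken.
#'
#' @param curves a [curve_set()]
#' @param variants character vector of variant names (>= 1)
#' @param init,settings passed to [fit_kinetics()]
#' @return A list of class `dz_variant_comparison` with `table`, `fits`,
#'   and `selected`.
#' @export
compare_variants <- function(curves,
                             variants = c("full_equilibrium", "no_ligation",
                                          "no_binding"),
                             init = NULL, settings = fit_settings()) {
  stopifnot(length(variants) >= 1)
  fits <- list()
  for (v in variants) {
    fits[[v]] <- tryCatch(fit_kinetics(curves, v, init = init,
                                       settings = settings),
                          error = function(e) e)
  }
  # cross-variant polishing: warm-start every variant from every other
  # converged solution so that nested variants are compared at equally
  # well-converged optima (the clamped constants are zeroed, newly freed
  # ones start at the lower bound)
  ok_names <- names(Filter(function(f) !inherits(f, "error"), fits))
  if (length(ok_names) >= 2) {
    for (a in ok_names) for (b in ok_names) {
      if (a == b) next
      fa <- fits[[a]]
      cand <- tryCatch(
        joint_refit(curves, apply_variant(fa$rates, b), fa$errors,
                    variant = b, settings = settings),
        error = function(e) NULL)
      if (!is.null(cand) && cand$rss < fits[[b]]$rss) fits[[b]] <- cand
    }
  }
  rows <- lapply(names(fits), function(v) {
    f <- fits[[v]]
    if (inherits(f, "error"))
      return(data.frame(variant = v, aic = NA_real_, rmse = NA_real_,
                        n_params = NA_integer_, significant = NA,
                        error = conditionMessage(f)))
    sig <- if (is.null(f$rate_sd)) NA else
      all(unclass(f$rates)[f$free] >= 2 * f$rate_sd[f$free], na.rm = TRUE)
    data.frame(variant = v, aic = f$aic, rmse = f$rmse,
               n_params = f$n_params, significant = sig,
               error = NA_character_)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- tab[!is.na(tab$aic), , drop = FALSE]
  if (nrow(ok) == 0) stop("every variant fit failed")
  # ties within 2 AIC units: fewest parameters first, then AIC
  near <- ok[ok$aic <= min(ok$aic) + 2, , drop = FALSE]
  near <- near[order(near$n_params, near$aic), , drop = FALSE]
  rest <- ok[ok$aic > min(ok$aic) + 2, , drop = FALSE]
  rest <- rest[order(rest$aic), , drop = FALSE]
  ranked <- rbind(near, rest)
  # lowest (parsimony-adjusted) AIC wins unless its estimates are not
  # significant while a fully significant variant is available
  sel <- ranked$variant[1]
  for (v in ranked$variant) {
    if (isTRUE(ranked$significant[ranked$variant == v])) { sel <- v; break }
  }
  structure(list(table = tab, fits = fits, selected = sel),
            class = "dz_variant_comparison")
}

#' @export
print.dz_variant_comparison <- function(x, ...) {
  cat("Model variant comparison (selected:", x$selected, ")\n")
  print(x$table[, c("variant", "aic", "rmse", "n_params", "significant")])
  invisible(x)
}
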