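#' Read kinetic curves from tidy CSV files
#'
#' `curves_csv` must hold long-format traces with columns `curve_id`,
#' `time_s` and either `conc_nm` (preprocessed product concentration) or
#' `value_au` (raw fluorescence); `meta_csv` holds one row per curve
#' keyed by `curve_id`.  Unknown metadata columns are preserved.  Rows
#' are sorted by curve and time, so shuffled files load to the same
#' object.
#'
#' @param curves_csv path to the curve file
#' @param meta_csv path to the metadata file
#' @return A [curve_set()] (if `conc_nm` present) or [raw_curves()].
#' @export
read_curves <- function(curves_csv, meta_csv) {
  cc <- read.csv(curves_csv, stringsAsFactors = FALSE)
  mm <- read.csv(meta_csv, stringsAsFactors = FALSE)
  if (!all(c("curve_id", "time_s") %in% names(cc)))
    stop("curve file must have columns curve_id and time_s")
  if (!"curve_id" %in% names(mm))
    stop("metadata file must have a curve_id column")
  if ("conc_nm" %in% names(cc)) curve_set(cc, mm)
  else if ("value_au" %in% names(cc)) raw_curves(cc, mm)
  else stop("curve file must have a conc_nm or value_au column")
}

#' Write kinetic curves to tidy CSV files
#'
#' @param x a [curve_set()] or [raw_curves()]
#' @param curves_csv,meta_csv output paths
#' @return Invisibly, the paths.
#' @export
write_curves <- function(x, curves_csv, meta_csv) {
  if (inherits(x, "curve_set")) {
    write.csv(x$observations, curves_csv, row.names = FALSE)
    write.csv(x$meta, meta_csv, row.names = FALSE)
  } else if (inherits(x, "raw_curves")) {
    write.csv(x$curves, curves_csv, row.names = FALSE)
    write.csv(x$meta, meta_csv, row.names = FALSE)
  } else stop("x must be a curve_set or raw_curves")
  invisible(c(curves_csv, meta_csv))
}

#' Export a trajectory to tidy CSV
#'
#' @param trajectory a `dz_trajectory` from [simulate_reaction()]
#' @param path output path
#' @return Invisibly, the path.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "dz_trajectory"))
  write.csv(trajectory[, c("time_s", "S", "E", "ES", "EP", "P",
                           "observable")],
            path, row.names = FALSE)
  invisible(path)
}

# md5 of a serialized object, via a temp file (base tools only)
.stamp_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Write fit results to JSON (+ residual CSV)
#'
#' Serializes the parameter estimates, standard deviations, per-curve
#' error terms, fit statistics and the settings stamp (seed + config
#' hash) to JSON; optionally writes the residual table as CSV alongside.
#'
#' @param fit a `dz_fit` or `dz_env_fit`
#' @param path JSON output path
#' @param residuals_csv optional CSV path for the residual table
#' @param seed seed to record in the stamp
#' @return Invisibly, the JSON path.
#' @export
write_fit <- function(fit, path, residuals_csv = NULL, seed = NULL) {
  payload <- if (inherits(fit, "dz_fit")) {
    list(kind = "kinetic_fit", variant = fit$variant$name,
         rates = as.list(unclass(fit$rates)),
         rate_sd = as.list(fit$rate_sd),
         errors = fit$errors, rmse = fit$rmse, aic = fit$aic,
         n_obs = fit$n_obs, n_params = fit$n_params,
         stage_rmse = as.list(fit$stage_rmse))
  } else if (inherits(fit, "dz_env_fit")) {
    if (fit$kind == "arrhenius")
      list(kind = "arrhenius_fit", t_ref = fit$t_ref,
           k_ref = as.list(unclass(fit$k_ref)), e_a = as.list(fit$e_a),
           e_a_sd = as.list(fit$e_a_sd), errors = fit$errors,
           rmse = fit$rmse, aic = fit$aic)
    else
      list(kind = "mg_fit", mg_laws = fit$mg_laws, errors = fit$errors,
           rmse = fit$rmse, aic = fit$aic)
  } else stop("fit must be a dz_fit or dz_env_fit")
  payload$stamp <- list(seed = seed,
                        config_hash = .stamp_hash(fit$settings %||% list()),
                        package = "dzkin",
                        version = as.character(utils::packageVersion("dzkin")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, force = TRUE)
  if (!is.null(residuals_csv) && !is.null(fit$residuals))
    write.csv(fit$residuals, residuals_csv, row.names = FALSE)
  invisible(path)
}

#' Read fit results written by [write_fit()]
#'
#' @param path JSON path
#' @return A list with the stored estimates and statistics.
#' @export
read_fit <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write bootstrap results (draws CSV + CI JSON)
#'
#' @param boot a `dz_boot`
#' @param ci_json path for the CI/correlation JSON
#' @param draws_csv optional path for the parameter-draw CSV
#' @param seed seed to record
#' @return Invisibly, `ci_json`.
#' @export
write_bootstrap <- function(boot, ci_json, draws_csv = NULL, seed = NULL) {
  stopifnot(inherits(boot, "dz_boot"))
  payload <- list(kind = "bootstrap", level = boot$level,
                  n_boot = boot$n_boot, n_failed = boot$n_failed,
                  ci = boot$ci, correlation = boot$correlation,
                  stamp = list(seed = seed))
  jsonlite::write_json(payload, ci_json, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, force = TRUE)
  if (!is.null(draws_csv))
    write.csv(as.data.frame(boot$draws), draws_csv, row.names = FALSE)
  invisible(ci_json)
}

#' Write a Monte Carlo prediction band (band CSV + density matrix CSV)
#'
#' @param band a `dz_prediction_band`
#' @param band_csv path for the band table
#' @param density_csv optional path for the per-time density matrix
#' @return Invisibly, `band_csv`.
#' @export
write_band <- function(band, band_csv, density_csv = NULL) {
  stopifnot(inherits(band, "dz_prediction_band"))
  write.csv(band$band, band_csv, row.names = FALSE)
  if (!is.null(density_csv)) {
    dm <- as.data.frame(band$density$freq)
    names(dm) <- paste0("bin_", seq_len(ncol(dm)))
    dm <- cbind(time_s = band$band$time_s, dm)
    write.csv(dm, density_csv, row.names = FALSE)
  }
  invisible(band_csv)
}

#' Read a run configuration (YAML or JSON)
#'
#' @param path configuration file; `.yaml`/`.yml` requires the yaml
#'   package, `.json` uses jsonlite
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}
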