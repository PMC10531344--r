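#' Raw fluorescence curve set
#'
#' Container for plate-reader traces before preprocessing.  `curves` holds
#' the long-format traces (`curve_id`, `time_s`, `value_au`); `meta` holds
#' one row per curve with the condition metadata: `substrate_nm`,
#' `enzyme_nm` (nominal concentrations, nmol/L), `temperature_c`, `mg_mm`,
#' `replicate`, `start_delay_s` (delay between substrate addition and the
#' first reading) and `role` (`"reaction"` or `"control"` for
#' substrate-only wells).  Extra metadata columns are preserved untouched.
#'
#' @param curves long-format data frame of traces
#' @param meta per-curve metadata data frame keyed by `curve_id`
#' @return An object of class `raw_curves`.
#' @export
raw_curves <- function(curves, meta) {
  need <- c("curve_id", "time_s", "value_au")
  if (!all(need %in% names(curves)))
    stop("curves must have columns: ", paste(need, collapse = ", "))
  need_m <- c("curve_id", "substrate_nm", "enzyme_nm", "temperature_c",
              "mg_mm", "replicate", "start_delay_s", "role")
  if (!all(need_m %in% names(meta)))
    stop("meta must have columns: ", paste(need_m, collapse = ", "))
  if (!all(curves$curve_id %in% meta$curve_id))
    stop("every curve_id in curves must appear in meta")
  if (!all(is.finite(curves$value_au))) stop("fluorescence must be finite")
  curves <- curves[order(curves$curve_id, curves$time_s), , drop = FALSE]
  rownames(curves) <- NULL
  bad <- vapply(split(curves$time_s, curves$curve_id),
                function(t) any(diff(t) < 0), logical(1))
  if (any(bad)) stop("times must be non-decreasing within each curve")
  meta <- meta[order(meta$curve_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(curves = curves, meta = meta), class = "raw_curves")
}

#' @export
print.raw_curves <- function(x, ...) {
  n_rx <- sum(x$meta$role == "reaction")
  cat("Raw fluorescence curves:", n_rx, "reaction curve(s),",
      sum(x$meta$role == "control"), "control(s),",
      nrow(x$curves), "readings\n")
  invisible(x)
}

#' Preprocessed concentration curve set
#'
#' Container for product-concentration progress curves ready for fitting.
#' `observations` is long-format (`curve_id`, `time_s`, `conc_nm`); `meta`
#' carries per-curve nominal concentrations and conditions.
#'
#' @param observations long-format data frame with `curve_id`, `time_s`,
#'   `conc_nm`
#' @param meta per-curve metadata with `curve_id`, `substrate_nm`,
#'   `enzyme_nm`, `temperature_c`, `mg_mm`, `replicate`
#' @return An object of class `curve_set`.
#' @export
curve_set <- function(observations, meta) {
  need <- c("curve_id", "time_s", "conc_nm")
  if (!all(need %in% names(observations)))
    stop("observations must have columns: ", paste(need, collapse = ", "))
  need_m <- c("curve_id", "substrate_nm", "enzyme_nm", "temperature_c",
              "mg_mm", "replicate")
  if (!all(need_m %in% names(meta)))
    stop("meta must have columns: ", paste(need_m, collapse = ", "))
  if (nrow(meta) < 1) stop("curve set must contain at least one curve")
  if (!all(observations$curve_id %in% meta$curve_id))
    stop("every curve_id in observations must appear in meta")
  observations <- observations[order(observations$curve_id,
                                     observations$time_s), , drop = FALSE]
  rownames(observations) <- NULL
  meta <- meta[order(meta$curve_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(observations = observations, meta = meta),
            class = "curve_set")
}

#' @export
print.curve_set <- function(x, ...) {
  cat("Curve set:", nrow(x$meta), "curve(s),", nrow(x$observations),
      "observations\n")
  cat("  substrate (nmol/L):",
      paste(sort(unique(x$meta$substrate_nm)), collapse = ", "), "\n")
  cat("  conditions: ", paste(sort(unique(x$meta$temperature_c)), collapse = "/"),
      " degC, ", paste(sort(unique(x$meta$mg_mm)), collapse = "/"),
      " mmol/L Mg2+\n", sep = "")
  invisible(x)
}

#' Combine curve sets or raw curve sets
#'
#' @param ... objects of the same class (`curve_set` or `raw_curves`)
#' @return A combined object of that class.
#' @export
combine_curves <- function(...) {
  xs <- list(...)
  if (all(vapply(xs, inherits, logical(1), "curve_set"))) {
    curve_set(do.call(rbind, lapply(xs, `[[`, "observations")),
              do.call(rbind, lapply(xs, `[[`, "meta")))
  } else if (all(vapply(xs, inherits, logical(1), "raw_curves"))) {
    raw_curves(do.call(rbind, lapply(xs, `[[`, "curves")),
               do.call(rbind, lapply(xs, `[[`, "meta")))
  } else stop("all arguments must be curve_set or all raw_curves")
}

# split observations by curve, aligned with meta rows; returns list of
# lists (curve_id, times, values, s0, e0, temperature_c, mg_mm)
curve_list <- function(cs) {
  obs <- split(cs$observations, cs$observations$curve_id)
  lapply(seq_len(nrow(cs$meta)), function(i) {
    m <- cs$meta[i, ]
    o <- obs[[as.character(m$curve_id)]]
    list(curve_id = m$curve_id, times = o$time_s, values = o$conc_nm,
         s0 = m$substrate_nm, e0 = m$enzyme_nm,
         temperature_c = m$temperature_c, mg_mm = m$mg_mm)
  })
}
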