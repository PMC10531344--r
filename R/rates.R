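#' Rate constants of the DNAzyme cleavage network
#'
#' Container for the six mass-action rate constants of the multiple-turnover
#' cleavage reaction: association (`k_on`) and dissociation (`k_off`) of the
#' DNAzyme--substrate complex, cleavage (`k_clv`) and ligation (`k_lig`)
#' within the complex, and release (`k_rls`) and re-binding (`k_bin`) of the
#' slowly dissociating product strand.  Second-order constants (`k_on`,
#' `k_bin`) are in (nmol/L)^-1 s^-1; first-order constants in s^-1.
#'
#' @param k_on association rate, (nmol/L)^-1 s^-1
#' @param k_off dissociation rate, s^-1
#' @param k_clv cleavage rate, s^-1
#' @param k_lig ligation rate, s^-1 (0 under the No Ligation variant)
#' @param k_rls product release rate, s^-1
#' @param k_bin product binding rate, (nmol/L)^-1 s^-1
#'
#' @return A named numeric vector of class `rate_constants`.
#' @examples
#' rate_constants(k_on = 4.5e-3, k_off = 0.16, k_clv = 0.22,
#'                k_lig = 0, k_rls = 20, k_bin = 0.11)
#' @export
rate_constants <- function(k_on, k_off, k_clv, k_lig = 0, k_rls, k_bin) {
  r <- c(k_on = k_on, k_off = k_off, k_clv = k_clv,
         k_lig = k_lig, k_rls = k_rls, k_bin = k_bin)
  validate_rates(r)
  structure(r, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("DNAzyme rate constants (nmol/L, s):\n")
  print(format(unclass(x), digits = 4), quote = FALSE)
  invisible(x)
}

# Coerce a named numeric vector (any order, possibly a subset replacing
# entries of `base`) to a full rate_constants vector.
as_rates <- function(x, base = NULL) {
  if (inherits(x, "rate_constants")) return(x)
  stopifnot(is.numeric(x), !is.null(names(x)))
  if (is.null(base)) {
    if (!all(.RATE_NAMES %in% names(x)))
      stop("rate vector must name all of: ", paste(.RATE_NAMES, collapse = ", "))
    r <- x[.RATE_NAMES]
  } else {
    r <- unclass(base)
    bad <- setdiff(names(x), .RATE_NAMES)
    if (length(bad)) stop("unknown rate constant(s): ", paste(bad, collapse = ", "))
    r[names(x)] <- x
  }
  validate_rates(r)
  structure(r, class = "rate_constants")
}

validate_rates <- function(r) {
  if (!all(is.finite(r))) stop("rate constants must be finite")
  if (any(r < 0)) stop("rate constants must be non-negative")
  invisible(r)
}

#' Reference rate constants for the long-armed DNAzyme
#'
#' Point estimates of the five active rate constants of the No Ligation
#' model for a long-armed 10-23 DNAzyme at 55 degrees C and 20 mmol/L
#' Mg2+ (midpoints of literature-reported 95% bootstrap confidence
#' intervals).  These serve as the default ground truth of the synthetic
#' data generator and as a realistic starting regime for simulations.
#'
#' @return A `rate_constants` vector with `k_lig = 0`.
#' @examples
#' reference_rates()
#' @export
reference_rates <- function() {
  rate_constants(k_on = 4.525e-3, k_off = 0.1555, k_clv = 0.222,
                 k_lig = 0, k_rls = 20.65, k_bin = 0.113)
}

#' Model variants of the cleavage mechanism
#'
#' The full-equilibrium mechanism treats every step as reversible.  The
#' `no_ligation` variant clamps `k_lig` to zero (cleavage irreversible);
#' the `no_binding` variant additionally clamps `k_bin` (product release
#' irreversible), nesting inside `no_ligation`.  `clamped` may be supplied
#' to override the default clamp set, e.g. to clamp `k_bin` alone.
#'
#' @param name one of `"full_equilibrium"`, `"no_ligation"`, `"no_binding"`
#' @param clamped optional character vector of rate-constant names forced
#'   to zero, overriding the variant's default
#' @return An object of class `model_variant`.
#' @examples
#' model_variant("no_ligation")
#' @export
model_variant <- function(name = c("full_equilibrium", "no_ligation", "no_binding"),
                          clamped = NULL) {
  name <- match.arg(name)
  if (is.null(clamped)) {
    clamped <- switch(name,
      full_equilibrium = character(0),
      no_ligation      = "k_lig",
      no_binding       = c("k_lig", "k_bin"))
  }
  bad <- setdiff(clamped, .RATE_NAMES)
  if (length(bad)) stop("unknown rate constant(s) in clamp set: ",
                        paste(bad, collapse = ", "))
  structure(list(name = name, clamped = clamped), class = "model_variant")
}

as_variant <- function(x) {
  if (inherits(x, "model_variant")) x else model_variant(x)
}

#' @export
print.model_variant <- function(x, ...) {
  cat("Model variant:", x$name, "\n")
  if (length(x$clamped)) cat("  clamped to zero:", paste(x$clamped, collapse = ", "), "\n")
  invisible(x)
}

#' Apply a model variant to a set of rate constants
#'
#' Sets the variant's clamped constants to exactly zero, leaving the others
#' untouched.
#'
#' @param rates a [rate_constants()] vector
#' @param variant a [model_variant()] or its name
#' @return A `rate_constants` vector.
#' @examples
#' apply_variant(reference_rates(), "no_binding")
#' @export
apply_variant <- function(rates, variant) {
  variant <- as_variant(variant)
  r <- unclass(as_rates(rates))
  r[variant$clamped] <- 0
  structure(r, class = "rate_constants")
}

# Names of the rate constants left free by a variant.
free_rate_names <- function(variant) {
  setdiff(.RATE_NAMES, as_variant(variant)$clamped)
}
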