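# Kinetic parameter set for the single-hepatocyte APAP model.

# The ten core rate constants of the metabolism network. delta_T is an
# optional extension (adduct turnover) and is off by default; it is excluded
# from the ten-constant core when zero.
.core_rate_names <- c(
  "k_sul", "k_gluc", "k_450", "k_rev", "k_GSH", "k_PSH",
  "beta_S", "delta_S", "beta_G", "delta_G"
)

# Constants whose value depends on position along the sinusoid.
.positional_rate_names <- c("k_450", "beta_G")

#' Kinetic rate constants of the hepatocyte APAP model
#'
#' Constructs and validates the parameter set of the mass-action metabolism
#' network. The core model has exactly ten rate constants:
#'
#' * `k_sul` — bimolecular sulphation rate (mM^-1 h^-1); consumes one
#'   sulphation cofactor per APAP molecule conjugated.
#' * `k_gluc` — effective first-order glucuronidation rate (h^-1); the UGT
#'   cofactor pool is assumed constant, so the step is pseudo-first-order.
#' * `k_450` — effective first-order P450 bioactivation rate to NAPQI
#'   (h^-1). Position-dependent along the sinusoid (CYP2E1/3A are enriched
#'   centrilobularly).
#' * `k_rev` — first-order NAPQI breakdown rate releasing APAP back (h^-1).
#' * `k_GSH` — bimolecular NAPQI-glutathione conjugation rate (mM^-1 h^-1).
#' * `k_PSH` — first-order NAPQI-protein adduction rate (h^-1); the
#'   protein-SH pool is treated as inexhaustible.
#' * `beta_S`, `delta_S` — constitutive production (mM h^-1) and first-order
#'   decay (h^-1) of the sulphation cofactor pool.
#' * `beta_G`, `delta_G` — constitutive production (mM h^-1) and first-order
#'   decay (h^-1) of glutathione. `beta_G` is position-dependent.
#'
#' `delta_T` (h^-1) optionally adds turnover of the cumulative adduct pool;
#' it defaults to 0, in which case the adduct pool is a pure accumulator and
#' total drug-derived mass is conserved.
#'
#' @param k_sul,k_gluc,k_450,k_rev,k_GSH,k_PSH,beta_S,delta_S,beta_G,delta_G
#'   non-negative rate constants (see above). `delta_S` and `delta_G` must be
#'   strictly positive so the drug-free baselines `beta_S/delta_S` and
#'   `beta_G/delta_G` are finite.
#' @param delta_T optional first-order decay of the adduct pool, default 0.
#' @return an object of class `rate_constants` (a named list).
#' @seealso [baseline_steady_state()], [simulate_cell()]
#' @examples
#' p <- rate_constants(k_sul = 0.3, k_gluc = 0.5, k_450 = 0.2, k_rev = 0.05,
#'                     k_GSH = 50, k_PSH = 0.4, beta_S = 0.2, delta_S = 0.4,
#'                     beta_G = 2, delta_G = 0.5)
#' baseline_steady_state(p)
#' @export
rate_constants <- function(k_sul, k_gluc, k_450, k_rev, k_GSH, k_PSH,
                           beta_S, delta_S, beta_G, delta_G, delta_T = 0) {
  p <- list(k_sul = k_sul, k_gluc = k_gluc, k_450 = k_450, k_rev = k_rev,
            k_GSH = k_GSH, k_PSH = k_PSH, beta_S = beta_S, delta_S = delta_S,
            beta_G = beta_G, delta_G = delta_G, delta_T = delta_T)
  vals <- unlist(p)
  if (!is.numeric(vals) || length(vals) != 11L) {
    stop("all rate constants must be single numeric values", call. = FALSE)
  }
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("rate constants must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (any(vals < 0)) {
    bad <- names(vals)[vals < 0]
    stop("rate constants must be non-negative; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (delta_S <= 0 || delta_G <= 0) {
    stop("delta_S and delta_G must be strictly positive ",
         "(baselines beta/delta must be finite)", call. = FALSE)
  }
  structure(p, class = "rate_constants")
}

#' Coerce a named list or vector to rate constants
#'
#' @param x a named list or numeric vector holding the ten core rate
#'   constants (and optionally `delta_T`).
#' @return a validated [rate_constants()] object.
#' @export
as_rate_constants <- function(x) {
  if (inherits(x, "rate_constants")) return(x)
  x <- as.list(x)
  missing_keys <- setdiff(.core_rate_names, names(x))
  if (length(missing_keys)) {
    stop("missing rate constants: ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(x), c(.core_rate_names, "delta_T"))
  if (length(extra)) {
    stop("unknown rate constant keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(rate_constants, x)
}

#' Names of the core rate constants
#'
#' The core model exposes exactly ten rate constants; the optional adduct
#' turnover `delta_T` joins the count only when non-zero.
#'
#' @param params optionally, a [rate_constants()] object; when given, the
#'   active constant names for that parameter set are returned (eleven if
#'   `delta_T > 0`).
#' @return character vector of rate-constant names.
#' @export
rate_constant_names <- function(params = NULL) {
  if (is.null(params)) return(.core_rate_names)
  stopifnot(inherits(params, "rate_constants"))
  if (params$delta_T > 0) c(.core_rate_names, "delta_T") else .core_rate_names
}

#' Position-dependent rate constants
#'
#' Returns the names of the constants that vary along the sinusoid axis
#' (P450 bioactivation and glutathione production).
#'
#' @return character vector.
#' @export
positional_rate_names <- function() .positional_rate_names

#' Drug-free baseline steady state
#'
#' In the absence of drug the sulphation cofactor and glutathione pools
#' relax to the constitutive balance of production over decay: `S0 =
#' beta_S/delta_S` and `G0 = beta_G/delta_G` (the glutathione level of a
#' healthy hepatocyte).
#'
#' @param params a [rate_constants()] object.
#' @return named numeric vector `c(S0 = ..., G0 = ...)` in mM.
#' @export
baseline_steady_state <- function(params) {
  stopifnot(inherits(params, "rate_constants"))
  c(S0 = params$beta_S / params$delta_S,
    G0 = params$beta_G / params$delta_G)
}

#' Instantaneous toxic branch fraction
#'
#' Fraction of the NAPQI consumption flux routed to protein adduction rather
#' than glutathione conjugation: `k_PSH / (k_PSH + k_GSH * G)`. While GSH is
#' abundant the detox branch dominates (fraction near 0); as GSH is
#' exhausted the balance switches and the fraction approaches 1.
#'
#' @param G glutathione concentration (mM), vectorized.
#' @param params a [rate_constants()] object.
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
branch_fraction <- function(G, params) {
  stopifnot(inherits(params, "rate_constants"))
  if (any(G < 0)) stop("G must be non-negative", call. = FALSE)
  denom <- params$k_PSH + params$k_GSH * G
  if (any(denom == 0)) {
    stop("branch fraction undefined: NAPQI outflux denominator is zero",
         call. = FALSE)
  }
  params$k_PSH / denom
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("APAP metabolism rate constants (mM, h):\n")
  core <- unlist(x[.core_rate_names])
  print(core)
  if (x$delta_T > 0) cat("adduct turnover delta_T =", x$delta_T, "h^-1\n")
  bl <- baseline_steady_state(x)
  cat(sprintf("drug-free baselines: S0 = %.4g mM, G0 = %.4g mM\n",
              bl[["S0"]], bl[["G0"]]))
  invisible(x)
}
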