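# Dose-response layer: Hill (four-parameter logistic) curves, exposure
# metrics, survival mapping and bounded nonlinear least-squares fitting.

#' Four-parameter logistic (Hill) parameters
#'
#' @param bottom lower asymptote (response at zero dose).
#' @param top upper asymptote (response at saturating dose), `>= bottom`.
#' @param ec50 dose at half-maximal effect, `> 0` (same units as dose).
#' @param hill_n Hill coefficient (steepness), `> 0`.
#' @return object of class `hill_params`.
#' @export
hill_params <- function(bottom, top, ec50, hill_n) {
  vals <- c(bottom = bottom, top = top, ec50 = ec50, hill_n = hill_n)
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("Hill parameters must be finite", call. = FALSE)
  }
  if (ec50 <= 0) stop("ec50 must be positive", call. = FALSE)
  if (top < bottom) stop("top must be >= bottom", call. = FALSE)
  if (hill_n <= 0) stop("hill_n must be positive", call. = FALSE)
  structure(as.list(vals), class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("Hill/4PL: bottom %.4g, top %.4g, EC50 %.4g, n %.4g\n",
              x$bottom, x$top, x$ec50, x$hill_n))
  invisible(x)
}

#' Evaluate the Hill curve
#'
#' `bottom + (top - bottom) * dose^n / (ec50^n + dose^n)`; equals the
#' midpoint `(bottom + top)/2` at `dose = ec50` and approaches the
#' asymptotes at 0 and infinity.
#'
#' @param dose non-negative dose(s).
#' @param p a [hill_params()] object.
#' @return response value(s).
#' @export
hill_curve <- function(dose, p) {
  stopifnot(inherits(p, "hill_params"))
  if (any(dose < 0, na.rm = TRUE)) {
    stop("dose must be non-negative", call. = FALSE)
  }
  r <- (dose / p$ec50)^p$hill_n
  out <- p$bottom + (p$top - p$bottom) * r / (1 + r)
  out[is.infinite(dose)] <- p$top
  out
}

#' Area under the concentration-time curve
#'
#' Composite trapezoid rule over the trajectory's output grid for one
#' species; the standard exposure metric contrasted with peak-based
#' metrics.
#'
#' @param traj an [simulate_cell()] trajectory or a data.frame with a
#'   `time` column.
#' @param species one of [state_names()] (or any column of the data).
#' @return area, mM h.
#' @export
auc_trapezoid <- function(traj, species) {
  d <- if (inherits(traj, "apap_trajectory")) traj$states else traj
  if (!is.data.frame(d) || !("time" %in% names(d))) {
    stop("trajectory must have a time column", call. = FALSE)
  }
  if (!(species %in% names(d))) {
    stop("unknown species: ", species, call. = FALSE)
  }
  if (nrow(d) < 2L) stop("need >= 2 time points", call. = FALSE)
  t <- d$time
  y <- d[[species]]
  sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
}

#' Peak concentration metric
#'
#' Maximum of one species over the trajectory's output grid; exposure
#' metric for compounds whose cytotoxicity tracks peak rather than
#' cumulative concentration.
#'
#' @inheritParams auc_trapezoid
#' @return maximal concentration, mM.
#' @export
peak_metric <- function(traj, species) {
  d <- if (inherits(traj, "apap_trajectory")) traj$states else traj
  if (!(species %in% names(d))) {
    stop("unknown species: ", species, call. = FALSE)
  }
  max(d[[species]])
}

#' Map a damage value to a survival fraction
#'
#' Decreasing Hill transform `1 - hill_curve(damage)` with the `bottom = 0`,
#' `top = 1` convention, so survival is 1 at zero damage, 0.5 at
#' `damage = ec50` and approaches 0 at saturating damage. The link between
#' adduct burden and cell death is not quantitatively established for APAP;
#' this transform is a configurable assumption, not a calibrated claim.
#'
#' @param damage non-negative damage metric value(s) (e.g. terminal adduct
#'   burden, mM).
#' @param p a [hill_params()]; only `ec50` and `hill_n` are used, the
#'   asymptotes are fixed at 0 and 1.
#' @return survival fraction(s) in `[0, 1]`.
#' @export
survival_from_damage <- function(damage, p) {
  stopifnot(inherits(p, "hill_params"))
  if (any(damage < 0, na.rm = TRUE)) {
    stop("damage must be non-negative", call. = FALSE)
  }
  1 - hill_curve(damage, hill_params(0, 1, p$ec50, p$hill_n))
}

#' Fit the four-parameter logistic to dose-response data
#'
#' Bounded Levenberg-Marquardt least squares with the EC50 parameterised on
#' the log-dose axis. Three deterministic multi-starts (EC50 at the 25th,
#' 50th and 75th log-dose percentiles) guard against local minima; ties are
#' broken by lowest residual, then lowest Hill coefficient. Bounds: both
#' asymptotes in `[0, 1]` (responses are fractions), `hill_n` in
#' `(0, 20]`, EC50 within a decade beyond the dose range.
#'
#' Degenerate inputs (constant responses, or no positive dose) are reported
#' as non-identifiable rather than fitted.
#'
#' @param doses strictly increasing non-negative dose grid (`>= 4` points —
#'   four free parameters).
#' @param responses observed responses (fractions in `[0, 1]`, increasing
#'   convention: effect, not survival).
#' @param weights optional least-squares weights.
#' @return list of class `hill_fit`: `params` ([hill_params()] or NULL),
#'   `residual_norm`, `converged`, `identifiable`, `message`.
#' @export
fit_hill <- function(doses, responses, weights = NULL) {
  if (length(doses) != length(responses)) {
    stop("doses and responses must have equal length", call. = FALSE)
  }
  if (length(doses) < 4L) {
    stop("need >= 4 dose points to fit 4 parameters", call. = FALSE)
  }
  if (any(doses < 0)) stop("doses must be non-negative", call. = FALSE)
  if (is.unsorted(doses)) {
    stop("doses must be sorted increasing", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(doses))
  pos <- doses > 0
  if (sum(pos) < 2L || diff(range(responses)) < 1e-12) {
    return(structure(list(params = NULL, residual_norm = NA_real_,
                          converged = FALSE, identifiable = FALSE,
                          message = "non-identifiable: degenerate dose-response data"),
                     class = "hill_fit"))
  }
  ld <- log(doses[pos])
  lo <- c(bottom = 0, top = 0, lec50 = min(ld) - log(10), ln = log(1e-2))
  hi <- c(bottom = 1, top = 1, lec50 = max(ld) + log(10), ln = log(20))
  model <- function(par, d) {
    r <- (d / exp(par[3]))^exp(par[4])
    out <- par[1] + (par[2] - par[1]) * r / (1 + r)
    out
  }
  resid_fun <- function(par) sqrt(weights) * (model(par, doses) - responses)

  b0 <- max(0, min(1, min(responses)))
  t0 <- max(0, min(1, max(responses)))
  starts <- lapply(quantile(ld, c(0.25, 0.5, 0.75), names = FALSE),
                   function(le) c(b0, t0, le, log(1)))
  fits <- lapply(starts, function(st) {
    tryCatch(minpack.lm::nls.lm(par = st, lower = lo, upper = hi,
                                fn = resid_fun,
                                control = minpack.lm::nls.lm.control(maxiter = 200)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) {
    return(structure(list(params = NULL, residual_norm = NA_real_,
                          converged = FALSE, identifiable = FALSE,
                          message = "all starts failed"),
                     class = "hill_fit"))
  }
  norms <- vapply(fits, function(f) sqrt(sum(f$fvec^2)), numeric(1))
  hills <- vapply(fits, function(f) exp(f$par[4]), numeric(1))
  best <- order(round(norms, 12), hills)[1]
  f <- fits[[best]]
  par <- f$par
  # the fitted curve may be decreasing in which case top < bottom on the
  # 4PL convention; normalise so top >= bottom by flipping the axis sense
  bottom <- min(par[1], par[2]); top <- max(par[1], par[2])
  structure(list(
    params = hill_params(bottom, top, exp(par[3]), exp(par[4])),
    increasing = par[2] >= par[1],
    residual_norm = norms[best],
    converged = f$info %in% 1:4,
    identifiable = TRUE,
    message = f$message),
    class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("Hill fit: non-identifiable (", x$message, ")\n", sep = "")
  } else {
    print(x$params)
    cat(sprintf("residual norm %.4g; converged: %s\n",
                x$residual_norm, x$converged))
  }
  invisible(x)
}

#' Dose-response scan of the cell model
#'
#' For each dose on the grid, simulates the cell model, evaluates the
#' configured damage metric (terminal adduct burden `terminal_T`, NAPQI
#' exposure `auc_N`, or NAPQI peak `peak_N`), maps damage to survival
#' through the configured Hill transform, and fits a four-parameter
#' logistic to the resulting effect (1 - survival) curve. Deterministic
#' given its inputs.
#'
#' @param doses strictly increasing dose grid (mM), `>= 4` points.
#' @param params a [rate_constants()] object.
#' @param t_end simulation end time (h).
#' @param metric one of `"terminal_T"`, `"auc_N"`, `"peak_N"`.
#' @param survival_params a [hill_params()] for the damage-to-survival map.
#' @param ... further arguments to [simulate_cell()].
#' @return object of class `dose_response_result`: `doses`, `metric`,
#'   `metric_values`, `survival`, `fit` (a `hill_fit`), `fitted_survival`.
#' @export
dose_response_scan <- function(doses, params, t_end,
                               metric = c("terminal_T", "auc_N", "peak_N"),
                               survival_params = hill_params(0, 1, 1, 2),
                               ...) {
  metric <- match.arg(metric)
  stopifnot(inherits(params, "rate_constants"))
  if (length(doses) < 4L) stop("need >= 4 doses", call. = FALSE)
  if (is.unsorted(doses)) {
    stop("doses must be sorted increasing", call. = FALSE)
  }
  vals <- vapply(doses, function(d) {
    traj <- simulate_cell(params, P0 = d, t_end = t_end, ...)
    switch(metric,
           terminal_T = terminal_adduct(traj),
           auc_N = auc_trapezoid(traj, "N"),
           peak_N = peak_metric(traj, "N"))
  }, numeric(1))
  surv <- survival_from_damage(vals, survival_params)
  fit <- fit_hill(doses, 1 - surv)
  fitted_survival <- if (is.null(fit$params)) {
    rep(NA_real_, length(doses))
  } else {
    1 - hill_curve(doses, fit$params)
  }
  structure(list(doses = doses, metric = metric, metric_values = vals,
                 survival = surv, fit = fit,
                 fitted_survival = fitted_survival,
                 survival_params = survival_params),
            class = "dose_response_result")
}

#' @export
print.dose_response_result <- function(x, ...) {
  cat(sprintf("Dose-response scan: %d doses in [%.4g, %.4g] mM, metric %s\n",
              length(x$doses), min(x$doses), max(x$doses), x$metric))
  cat(sprintf("survival range [%.4g, %.4g]\n",
              min(x$survival), max(x$survival)))
  print(x$fit)
  invisible(x)
}

#' @export
as.data.frame.dose_response_result <- function(x, ...) {
  data.frame(dose = x$doses, metric = x$metric_values,
             survival = x$survival, fitted_survival = x$fitted_survival)
}
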