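# Synthetic fixture generation: random parameter sets, noisy trajectories
# and noisy dose-response tables for exercising the fitting routines.
# The published model carries no experimental parameter values, so every
# numeric set produced here is synthetic by construction.

#' Specification for synthetic fixture generation
#'
#' @param ranges named list of `c(min, max)` positive ranges, one per rate
#'   constant to sample (log-uniformly); constants not listed stay at the
#'   reference defaults of [default_config()].
#' @param noise_level multiplicative Gaussian noise standard deviation
#'   applied to trajectory values (e.g. 0.01 for 1%).
#' @param n_replicates number of fixtures to generate (`>= 0`).
#' @param seed RNG seed; identical specs yield identical fixtures.
#' @param P0 dose used for the fixture trajectories (mM).
#' @param t_end,n_times trajectory horizon (h) and grid size.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(ranges = list(), noise_level = 0.01,
                         n_replicates = 1L, seed = 1L,
                         P0 = 5, t_end = 24, n_times = 41L) {
  for (k in names(ranges)) {
    r <- ranges[[k]]
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2]) {
      stop("range for ", k, " must be positive c(min, max)", call. = FALSE)
    }
    if (!k %in% rate_constant_names()) {
      stop("unknown rate constant in ranges: ", k, call. = FALSE)
    }
  }
  if (noise_level < 0) stop("noise_level must be >= 0", call. = FALSE)
  if (n_replicates < 0) stop("n_replicates must be >= 0", call. = FALSE)
  structure(list(ranges = ranges, noise_level = noise_level,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), P0 = P0, t_end = t_end,
                 n_times = as.integer(n_times)),
            class = "fixture_spec")
}

#' Sample a random rate-constant set
#'
#' Log-uniform sampling within the spec's ranges, holding all unlisted
#' constants at the reference defaults. Uses the current RNG stream.
#'
#' @param spec a [fixture_spec()].
#' @return a [rate_constants()] object.
#' @export
sample_rate_constants <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  p <- default_config()$model$rates
  for (k in names(spec$ranges)) {
    r <- spec$ranges[[k]]
    p[[k]] <- exp(runif(1, log(r[1]), log(r[2])))
  }
  as_rate_constants(p)
}

#' Add multiplicative Gaussian noise to a trajectory
#'
#' Each state value x becomes `x * (1 + noise_level * Z)` with independent
#' standard normal Z, floored at zero (concentrations cannot be negative).
#' Uses the current RNG stream.
#'
#' @param traj an [simulate_cell()] trajectory.
#' @param noise_level relative noise standard deviation.
#' @return a data.frame like `traj$states` with noisy state columns.
#' @export
add_trajectory_noise <- function(traj, noise_level) {
  stopifnot(inherits(traj, "apap_trajectory"))
  d <- traj$states
  for (col in state_names()) {
    z <- rnorm(nrow(d))
    d[[col]] <- pmax(d[[col]] * (1 + noise_level * z), 0)
  }
  d
}

#' Generate synthetic fixtures
#'
#' For each replicate: samples a rate-constant set, simulates a clean
#' trajectory, verifies the mass-conservation identity before any noise is
#' injected (a broken fixture generator must not silently poison the
#' fitting tests), then produces a noisy copy. Fully deterministic given
#' the spec's seed.
#'
#' @param spec a [fixture_spec()].
#' @return list of fixtures, each `list(params, clean, noisy)` where
#'   `clean` is an `apap_trajectory` and `noisy` its perturbed data.frame.
#' @export
generate_fixtures <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$n_replicates == 0L) return(list())
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  lapply(seq_len(spec$n_replicates), function(i) {
    params <- sample_rate_constants(spec)
    traj <- simulate_cell(params, P0 = spec$P0, t_end = spec$t_end,
                          times = seq(0, spec$t_end,
                                      length.out = spec$n_times))
    cons <- conservation_residual(traj)
    if (spec$P0 > 0 && cons$max_relative > 1e-6) {
      stop("fixture ", i, " violates mass conservation before noise ",
           "(relative residual ", signif(cons$max_relative, 3), ")",
           call. = FALSE)
    }
    list(params = params, clean = traj,
         noisy = add_trajectory_noise(traj, spec$noise_level))
  })
}

#' Generate a noisy synthetic dose-response table
#'
#' Survival values are generated exactly from a known Hill transform of
#' dose and perturbed with multiplicative Gaussian noise, clamped to
#' `[0, 1]` — the standard fixture for EC50-recovery checks.
#'
#' @param p_true a [hill_params()] generating the survival curve (bottom/top
#'   convention of [survival_from_damage()]).
#' @param doses strictly increasing positive dose grid.
#' @param noise_level relative noise standard deviation (e.g. 0.02).
#' @param seed RNG seed.
#' @return data.frame `dose, survival_true, survival`.
#' @export
synthetic_dose_response <- function(p_true, doses, noise_level = 0.02,
                                    seed = 1L) {
  stopifnot(inherits(p_true, "hill_params"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  s_true <- survival_from_damage(doses, p_true)
  s_obs <- pmin(pmax(s_true * (1 + noise_level * rnorm(length(doses))), 0), 1)
  data.frame(dose = doses, survival_true = s_true, survival = s_obs)
}
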