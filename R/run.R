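# High-level run functions backing the command-line subcommands.

.log <- function(level, run_level, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[run_level]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
}

#' Run a single-cell simulation from a configuration
#'
#' Backs the `simulate` subcommand: loads the model block, integrates the
#' cell model, and writes the trajectory CSV + JSON sidecar.
#'
#' @param config a `run_config` or path to a YAML file.
#' @param out output directory (created if absent).
#' @param seed RNG seed recorded in provenance (the simulation itself is
#'   deterministic).
#' @param log_level one of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return the `apap_trajectory`, invisibly; side effect: files in `out`.
#' @export
run_simulate <- function(config, out = ".", seed = 0L, log_level = "info") {
  cfg_path <- if (is.character(config)) config else NULL
  cfg <- if (is.character(config)) load_config(config) else config
  stopifnot(inherits(cfg, "run_config"))
  m <- cfg$model
  params <- .config_rates(cfg)
  .log("info", log_level, "simulating cell model: P0 = ", m$P0,
       " mM, t_end = ", m$t_end, " h")
  traj <- simulate_cell(params, P0 = m$P0, t_end = m$t_end,
                        times = seq(0, m$t_end, length.out = m$n_times),
                        rtol = m$rtol, atol = m$atol)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_results(traj, file.path(out, "trajectory.csv"),
                seed = seed, config_path = cfg_path)
  .log("info", log_level, "wrote ", file.path(out, "trajectory.csv"))
  invisible(traj)
}

#' Run a zonated sinusoid simulation from a configuration
#'
#' Backs the `zonate` subcommand: builds the oxygen profile and parameter
#' fields, runs the cell model per zone, classifies the injury pattern and
#' writes the injury map CSV + JSON sidecar.
#'
#' @inheritParams run_simulate
#' @param pattern_threshold injury threshold on terminal T (mM); default:
#'   the config's `zonation$threshold`.
#' @return the `injury_map`, invisibly.
#' @export
run_zonate <- function(config, out = ".", seed = 0L, log_level = "info",
                       pattern_threshold = NULL) {
  cfg_path <- if (is.character(config)) config else NULL
  cfg <- if (is.character(config)) load_config(config) else config
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$zonation)) {
    .config_error("zonation block required for the zonate command")
  }
  zones <- .config_zones(cfg)
  params <- .config_rates(cfg)
  thr <- if (is.null(pattern_threshold)) cfg$zonation$threshold else
    pattern_threshold
  .log("info", log_level, "simulating ", length(zones$z), " zones")
  inj <- simulate_sinusoid(zones, params, t_end = cfg$model$t_end,
                           keep_trajectories = FALSE,
                           rtol = cfg$model$rtol, atol = cfg$model$atol)
  cls <- classify_injury(inj, thr)
  .log("info", log_level, "injury pattern: ", cls$pattern)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_results(inj, file.path(out, "injury_map.csv"),
                seed = seed, config_path = cfg_path, injury_threshold = thr)
  invisible(inj)
}

#' Run a dose-response scan from a configuration
#'
#' Backs the `dose-response` subcommand: expands the dose grid, scans the
#' cell model, maps damage to survival, fits the Hill curve and writes the
#' CSV + JSON sidecar.
#'
#' @inheritParams run_simulate
#' @param metric optional override of the config's damage metric.
#' @return the `dose_response_result`, invisibly.
#' @export
run_dose_response <- function(config, out = ".", seed = 0L,
                              log_level = "info", metric = NULL) {
  cfg_path <- if (is.character(config)) config else NULL
  cfg <- if (is.character(config)) load_config(config) else config
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$doseresponse)) {
    .config_error("doseresponse block required for the dose-response command")
  }
  d <- cfg$doseresponse
  doses <- expand_doses(d$doses)
  metric <- if (is.null(metric)) d$metric else metric
  sp <- hill_params(0, 1, d$survival$ec50, d$survival$hill_n)
  .log("info", log_level, "scanning ", length(doses), " doses, metric ",
       metric)
  res <- dose_response_scan(doses, .config_rates(cfg),
                            t_end = cfg$model$t_end, metric = metric,
                            survival_params = sp,
                            rtol = cfg$model$rtol, atol = cfg$model$atol)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_results(res, file.path(out, "dose_response.csv"),
                seed = seed, config_path = cfg_path)
  invisible(res)
}
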