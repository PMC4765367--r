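# Result serialization: schema-stable CSV outputs with JSON sidecars
# carrying units, parameters and provenance.

.provenance <- function(seed = NULL, config_path = NULL) {
  prov <- list(package = "zonatox",
               version = as.character(packageVersion("zonatox")))
  if (!is.null(seed)) prov$seed <- as.integer(seed)
  if (!is.null(config_path) && file.exists(config_path)) {
    prov$config_md5 <- unname(tools::md5sum(config_path))
  }
  prov
}

.write_sidecar <- function(meta, csv_path) {
  side <- paste0(tools::file_path_sans_ext(csv_path), ".json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  side
}

#' Write a result object to disk
#'
#' Serializes trajectories, injury maps and dose-response results to a
#' schema-stable CSV (plus a JSON sidecar with units, parameters and
#' provenance) or to a single JSON document.
#'
#' Schemas: trajectory CSV has header
#' `time,P,S,N,G,T,E_sul,E_gluc,C_GSH`; injury-map CSV has
#' `z,oxygen,k450,betaG,P0,terminal_T,zone_label` and its sidecar carries
#' the pattern label and the anoxia flag; dose-response CSV has
#' `dose,metric,survival,fitted_survival` with the fitted Hill parameters
#' in the sidecar.
#'
#' @param result an `apap_trajectory`, `injury_map` or
#'   `dose_response_result`.
#' @param path output file path (extension not enforced).
#' @param format `"csv"` (with JSON sidecar) or `"json"`.
#' @param seed,config_path optional provenance fields recorded in the
#'   sidecar.
#' @param injury_threshold for injury maps: threshold used to derive the
#'   pattern label recorded in the sidecar (default: midpoint of the
#'   terminal-T range).
#' @return invisibly, the paths written.
#' @export
write_results <- function(result, path, format = c("csv", "json"),
                          seed = NULL, config_path = NULL,
                          injury_threshold = NULL) {
  format <- tryCatch(match.arg(format), error = function(e) {
    stop("unknown format: must be 'csv' or 'json'", call. = FALSE)
  })
  meta <- list(provenance = .provenance(seed, config_path))
  if (inherits(result, "apap_trajectory")) {
    tab <- result$states
    meta$units <- list(time = "h", concentration = "mM")
    meta$parameters <- unclass(result$params)
    meta$P0 <- result$P0
    meta$solver <- result$solver
  } else if (inherits(result, "injury_map")) {
    tab <- result$map
    if (is.null(injury_threshold)) {
      injury_threshold <- mean(range(result$map$terminal_T))
    }
    cls <- classify_injury(result, injury_threshold)
    meta$units <- list(z = "fraction of L", concentration = "mM")
    meta$pattern <- cls$pattern
    meta$pattern_threshold <- injury_threshold
    meta$anoxic <- result$anoxic
    meta$t_end <- result$t_end
  } else if (inherits(result, "dose_response_result")) {
    tab <- as.data.frame(result)
    meta$units <- list(dose = "mM")
    meta$metric <- result$metric
    meta$hill_fit <- if (is.null(result$fit$params)) {
      list(identifiable = FALSE, message = result$fit$message)
    } else {
      c(unclass(result$fit$params),
        list(residual_norm = result$fit$residual_norm,
             converged = result$fit$converged, identifiable = TRUE))
    }
  } else {
    stop("unsupported result class: ", paste(class(result), collapse = "/"),
         call. = FALSE)
  }

  if (format == "csv") {
    write.csv(tab, path, row.names = FALSE, quote = FALSE)
    side <- .write_sidecar(meta, path)
    invisible(c(path, side))
  } else {
    jsonlite::write_json(c(meta, list(data = tab)), path,
                         auto_unbox = TRUE, digits = NA, dataframe = "columns",
                         pretty = TRUE)
    invisible(path)
  }
}

#' Read a trajectory CSV back into an `apap_trajectory`
#'
#' Reconstructs the object from a CSV written by [write_results()]; the
#' JSON sidecar, when present alongside, restores the rate constants and
#' solver metadata.
#'
#' @param path trajectory CSV path.
#' @return an `apap_trajectory`.
#' @export
read_trajectory <- function(path) {
  tab <- read.csv(path)
  need <- c("time", state_names())
  if (!all(need %in% names(tab))) {
    stop("not a trajectory CSV: missing ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  }
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  params <- NULL; P0 <- tab$P[1]; solver <- list()
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$parameters)) params <- as_rate_constants(meta$parameters)
    if (!is.null(meta$P0)) P0 <- meta$P0
    if (!is.null(meta$solver)) solver <- meta$solver
  }
  structure(list(states = tab[need], params = params, P0 = P0,
                 solver = solver),
            class = "apap_trajectory")
}
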