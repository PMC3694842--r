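#' Load a run configuration
#'
#' Reads a YAML or JSON configuration holding the model parameters and,
#' optionally, the input signal, integrator settings and a seed.  Unknown keys
#' are rejected; validation errors name the offending field.  A run is
#' reproducible from its configuration plus seed alone.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file with top-level keys
#'   `params` (required), `signal`, `integrator`, `seed`.
#' @return A list of class `nfkb_config` with elements `params`
#'   (`nfkb_params`), `signal` (`nfkb_signal`), `integrator`
#'   (`nfkb_integrator_config`), `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else stop("config must be a .yaml or .json file", call. = FALSE)
  known <- c("params", "signal", "integrator", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(raw$params)) stop("configuration lacks `params`", call. = FALSE)
  cfg <- list(
    params = do.call(model_params, raw$params),
    signal = do.call(input_signal, if (is.null(raw$signal)) list()
                     else raw$signal),
    integrator = do.call(integrator_config,
                         if (is.null(raw$integrator)) list()
                         else raw$integrator),
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed))
  class(cfg) <- "nfkb_config"
  cfg
}

#' Write a configuration
#'
#' Serializes a configuration so that `load_config()` round-trips it.
#'
#' @param config An `nfkb_config` (or a list with the same elements).
#' @param path Output path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  obj <- list(params = unclass(config$params),
              signal = unclass(config$signal),
              integrator = unclass(config$integrator),
              seed = config$seed)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path, precision = 12)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Write a trajectory as CSV
#'
#' Fixed column order `time_min,y_alpha_nM,y_eps_nM,x_nM` and 12-significant-
#' digit formatting, so identical inputs give bit-stable output.
#'
#' @param traj An `nfkb_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  cols <- c("time_min", "y_alpha_nM", "y_eps_nM", "x_nM")
  df <- as.data.frame(lapply(traj[cols], function(v) signif(v, 12)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path CSV written by [write_trajectory()] (or any CSV with the same
#'   header).
#' @return An `nfkb_trajectory` data frame.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_min", "y_alpha_nM", "y_eps_nM", "x_nM")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  class(df) <- c("nfkb_trajectory", "data.frame")
  df
}

#' Write an analysis result as JSON or CSV
#'
#' Scan results serialize their grids, metric surface and argmin; duration
#' curves and ensembles serialize their columns; plain lists/data frames are
#' serialized as-is.  Floats are kept at 12 significant digits.
#'
#' @param result A result object (`nfkb_scan`, `nfkb_duration_curve`,
#'   `nfkb_ensemble`, data frame, or list).
#' @param path Output path.
#' @param format `"json"` or `"csv"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path,
                          format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  obj <- if (inherits(result, "nfkb_scan")) {
    list(tau2_grid = result$tau2_grid, eps_grid = result$eps_grid,
         metric = unname(apply(result$metric, 1, as.numeric,
                               simplify = FALSE)),
         argmin = as.list(result$argmin), t_cut = result$t_cut, K = result$K)
  } else if (is.data.frame(result)) {
    as.data.frame(result)
  } else {
    result
  }
  if (format == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    if (!is.data.frame(obj))
      stop("CSV output requires a tabular result", call. = FALSE)
    obj <- as.data.frame(lapply(obj, function(v)
      if (is.numeric(v)) signif(v, 12) else v))
    utils::write.csv(obj, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
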