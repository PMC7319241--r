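# Light-weight configuration and table I/O.

#' Read a minimal-model configuration file
#'
#' Reads a JSON or YAML file with any of the entries `b`, `r`, `h`, `p`,
#' `a_low`, `a_high`, `total_steps`, `direction`, `substeps` (missing
#' entries take the package defaults) and returns ready-to-use model
#' objects.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with `params` ([minimal_model_params()]), `ramp`
#'   ([driver_ramp()]) and `substeps`.
#' @export
read_model_config <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  cfg <- if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON configuration requires the 'jsonlite' package")
    jsonlite::fromJSON(path)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configuration requires the 'yaml' package")
    yaml::read_yaml(path)
  } else stop("unsupported configuration format: .", ext)
  get <- function(nm, default) if (!is.null(cfg[[nm]])) cfg[[nm]] else default
  list(
    params = minimal_model_params(p = get("p", 0), b = get("b", 1),
                                  r = get("r", 1), h = get("h", 1)),
    ramp = driver_ramp(total_steps = get("total_steps", 200),
                       direction = get("direction", "up_first"),
                       a_low = get("a_low", 0), a_high = get("a_high", 1)),
    substeps = get("substeps", 10)
  )
}

#' Write / read a simulated trajectory as CSV
#'
#' @param traj An `oef_trajectory` from [simulate_model()].
#' @param path CSV file path.
#' @return `read_trajectory()` returns a `data.frame` with columns `t`,
#'   `a`, `Y`, `phase`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "oef_trajectory"))
  write.csv(as.data.frame(traj)[, c("t", "a", "Y", "phase")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
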