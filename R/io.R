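#' Read and write time-series CSV files
#'
#' Time series travel as plain CSV with header `t,S,I,nu` (comma separated,
#' UTF-8, `.` decimal).  Writing also drops a YAML sidecar
#' (`<path>.meta.yml`) with the run's method, seed and parameters so any
#' stochastic artifact can be regenerated exactly; reading picks the sidecar
#' up when present.  Round-trips are lossless to 12 significant digits.
#'
#' @param series A `sir_timeseries` (or any tibble with columns `t,S,I,nu`).
#' @param path File path.
#' @return `read_timeseries()` returns a `sir_timeseries` tibble;
#'   `write_timeseries()` returns `path` invisibly.
#' @export
write_timeseries <- function(series, path) {
  check_series(series)
  df <- as.data.frame(series)[, c("t", "S", "I", "nu")]
  df[] <- lapply(df, function(x) signif(x, 15))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- ts_meta(series)
  if (!is.null(meta)) {
    m <- meta
    if (inherits(m$params, "sir_params")) {
      m$params <- as.list(as.data.frame(m$params))
    }
    if (inherits(m$schedule, "vaccine_schedule")) {
      m$schedule <- unclass(m$schedule)
      m$schedule$breakpoints <- NULL
    }
    m <- m[!vapply(m, function(x) is.matrix(x) || is.function(x), logical(1))]
    yaml::write_yaml(m, paste0(path, ".meta.yml"), precision = 15)
  }
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  missing_cols <- setdiff(c("t", "S", "I", "nu"), names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("empty time series in ", path, call. = FALSE)
  if (any(diff(df$t) <= 0)) {
    stop("time column must be strictly increasing in ", path, call. = FALSE)
  }
  if (any(df$S < 0, na.rm = TRUE) || any(df$I < 0, na.rm = TRUE)) {
    stop("negative counts in ", path, call. = FALSE)
  }
  meta <- NULL
  side <- paste0(path, ".meta.yml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    if (!is.null(meta$params)) {
      meta$params <- do.call(
        sir_params,
        meta$params[c("R0", "b", "mu", "gamma", "eta", "nu")]
      )
    }
  }
  new_timeseries(df$t, df$S, df$I, df$nu, meta = meta)
}

#' Read a run configuration file
#'
#' Flat YAML key-value configuration mirroring the CLI flags.  Recognized
#' keys: the model parameters (`b`, `mu`, `gamma`, `eta`, `nu`, `R0`), the
#' schedule (`schedule_mode`, `nu0`, `ramp_rate`, `ramp_start`), the
#' simulation block (`method`, `T`, `dt`, `sample_dt`, `seed`, `replicates`)
#' and the indicator block (`window`, `stride`, `lag`).  Unknown keys are
#' rejected; a seed is mandatory for stochastic methods.
#'
#' @param path Path to the YAML file.
#' @return A named list of validated settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  allowed <- c("b", "mu", "gamma", "eta", "nu", "R0",
               "schedule_mode", "nu0", "ramp_rate", "ramp_start",
               "method", "T", "dt", "sample_dt", "seed", "replicates",
               "window", "stride", "lag", "output")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(cfg$method) &&
      cfg$method %in% c("gillespie", "euler_maruyama") &&
      is.null(cfg$seed)) {
    stop("a seed is mandatory for stochastic methods", call. = FALSE)
  }
  cfg
}
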