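#' Read and write sampled signals as CSV
#'
#' Signals travel as two-column CSV (`time_ms`, `voltage`); a single-column
#' file (one voltage per line, e.g. an exported recording) is accepted on
#' read when `fs` is supplied, so experimental traces can be analysed with
#' the same feature functions.
#'
#' @param path File path.
#' @param fs Sampling rate in Hz, required for single-column files and used
#'   as metadata otherwise.
#' @return `read_signal_csv()`: a `semg_signal` tibble;
#'   `write_signal_csv()`: the input, invisibly.
#' @export
read_signal_csv <- function(path, fs = NULL) {
  df <- utils::read.csv(path)
  if (ncol(df) == 1L) {
    if (is.null(fs)) stop("single-column signal files need an explicit fs", call. = FALSE)
    v <- as.numeric(df[[1]])
    df <- tibble::tibble(time_ms = (seq_along(v) - 1L) / fs * 1000, voltage = v)
  } else {
    if (!all(c("time_ms", "voltage") %in% names(df))) {
      stop("expected columns time_ms and voltage (or a single voltage column)",
           call. = FALSE)
    }
    df <- tibble::as_tibble(df[c("time_ms", "voltage")])
    if (is.null(fs)) fs <- 1000 / stats::median(diff(df$time_ms))
  }
  class(df) <- c("semg_signal", class(df))
  attr(df, "fs") <- fs
  df
}

#' @rdname read_signal_csv
#' @param signal A signal tibble with `time_ms` and `voltage` columns.
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot(all(c("time_ms", "voltage") %in% names(signal)))
  utils::write.csv(as.data.frame(signal)[c("time_ms", "voltage")], path,
                   row.names = FALSE)
  invisible(signal)
}

#' Serialise parameter objects to and from JSON/YAML
#'
#' Membrane, pool and simulation parameters round-trip through plain named
#' lists, so a whole study configuration can live in one JSON or YAML file.
#'
#' @param p A [membrane_params()] or [pool_params()] object.
#' @param path Destination/source file; extension `.yaml`/`.yml` selects
#'   YAML, anything else JSON.
#' @return `write_params()` returns `p` invisibly; `read_membrane_params()`
#'   and `read_pool_params()` return the reconstructed object.
#' @export
write_params <- function(p, path) {
  x <- unclass(p)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(p)
}

read_params_list <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname write_params
#' @export
read_membrane_params <- function(path) {
  do.call(membrane_params, read_params_list(path))
}

#' @rdname write_params
#' @export
read_pool_params <- function(path) {
  do.call(pool_params, read_params_list(path))
}

#' Serialise spike trains to JSON
#'
#' One record per motor unit (index, firing rate, firing times in ms) plus
#' the generating seed, drive and duration as metadata, so a simulation's
#' spike input can be archived or replayed elsewhere.
#'
#' @param trains A [generate_spike_trains()] tibble.
#' @param path Destination JSON file.
#' @return `trains`, invisibly.
#' @export
write_spike_trains <- function(trains, path) {
  stopifnot(all(c("unit", "rate_hz", "firing_times") %in% names(trains)))
  x <- list(
    seed = attr(trains, "seed"),
    drive = attr(trains, "drive"),
    duration_ms = attr(trains, "duration_ms"),
    units = purrr::pmap(
      list(trains$unit, trains$rate_hz, trains$firing_times),
      function(u, r, ft) list(unit = u, rate_hz = r, firing_times = ft)
    )
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(trains)
}
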