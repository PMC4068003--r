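#' Spike raster objects
#'
#' A `spike_raster` is the universal currency between all analysis stages: a
#' set of spike times (in ms) with the unit that emitted each spike, the
#' number of units and the recording duration. Spikes are stored pooled and
#' sorted by time; unit ids are integers in `1:n_units`. Rasters produced by
#' the driven simulators carry a per-spike `is_input` flag separating
#' externally driven spikes from synaptically propagated ones.
#'
#' @param times numeric vector of spike times in ms, `0 <= t < duration`.
#' @param units integer vector of unit ids (same length as `times`).
#' @param n_units number of units in the recording (may exceed `max(units)`;
#'   silent units are legal).
#' @param duration recording duration in ms.
#' @param is_input optional logical vector flagging externally driven spikes.
#' @param meta list of free-form metadata (model config, seed, ...).
#' @return an object of class `spike_raster`.
#' @export
spike_raster <- function(times, units, n_units, duration, is_input = NULL,
                         meta = list()) {
  stopifnot(length(times) == length(units), n_units >= 1, duration > 0)
  units <- as.integer(units)
  if (length(times)) {
    if (min(times) < 0 || max(times) >= duration)
      stop("spike times must satisfy 0 <= t < duration")
    if (min(units) < 1L || max(units) > n_units)
      stop("unit ids must lie in 1:n_units")
    ord <- order(times, units)
    times <- times[ord]; units <- units[ord]
    if (!is.null(is_input)) is_input <- is_input[ord]
  }
  structure(
    list(times = times, units = units, n_units = as.integer(n_units),
         duration = as.numeric(duration), is_input = is_input, meta = meta),
    class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike_raster: %d spikes, %d units, %.1f s\n",
              length(x$times), x$n_units, x$duration / 1000))
  cat(sprintf("  population rate R = %.2f Hz, single-unit rate r = %.3f Hz\n",
              population_rate(x), population_rate(x) / x$n_units))
  if (!is.null(x$is_input))
    cat(sprintf("  input spikes: %d (fraction %.3g)\n",
                sum(x$is_input), mean(x$is_input)))
  invisible(x)
}

#' @export
summary.spike_raster <- function(object, ...) {
  ur <- tabulate(object$units, object$n_units) / (object$duration / 1000)
  out <- list(n_spikes = length(object$times), n_units = object$n_units,
              duration_ms = object$duration,
              population_rate = population_rate(object),
              unit_rate_mean = mean(ur), unit_rate_range = range(ur),
              mean_iei = mean_iei(object))
  class(out) <- "summary.spike_raster"
  out
}

#' @export
print.summary.spike_raster <- function(x, ...) {
  cat(sprintf("%d spikes from %d units over %.1f s\n",
              x$n_spikes, x$n_units, x$duration_ms / 1000))
  cat(sprintf("R = %.2f Hz, <IEI> = %.3f ms, unit rates %.2f-%.2f Hz (mean %.2f)\n",
              x$population_rate, x$mean_iei,
              x$unit_rate_range[1], x$unit_rate_range[2], x$unit_rate_mean))
  invisible(x)
}

#' @export
plot.spike_raster <- function(x, max_units = 100, xlim = NULL, ...) {
  keep <- x$units <= max_units
  if (!is.null(xlim)) keep <- keep & x$times >= xlim[1] & x$times <= xlim[2]
  plot(x$times[keep], x$units[keep], pch = ".", cex = 2,
       xlab = "time [ms]", ylab = "unit", ...)
  invisible(x)
}

#' Population rate, single-unit rate and mean inter-event interval
#'
#' The population rate R is the rate of all units together (spikes per second
#' of recording, in Hz). The mean inter-event interval of the pooled spike
#' train is its inverse, `<IEI> = 1/R`, returned in ms; it serves as a
#' rate-normalized unit for bin sizes.
#'
#' @param raster a [spike_raster()].
#' @return `population_rate`: Hz. `mean_iei`: ms.
#' @export
population_rate <- function(raster) {
  length(raster$times) / (raster$duration / 1000)
}

#' @rdname population_rate
#' @export
mean_iei <- function(raster) {
  if (length(raster$times) == 0L) stop("empty raster has no <IEI>")
  raster$duration / length(raster$times)
}

#' Summed population activity at 1 ms resolution
#'
#' Counts the total number of spikes across all units in each 1 ms step of the
#' recording; this is the time series the detrended fluctuation analysis is
#' applied to.
#'
#' @param raster a [spike_raster()].
#' @param step_ms sampling step of the output series (default 1 ms).
#' @return integer vector of length `floor(duration / step_ms)`.
#' @export
population_signal <- function(raster, step_ms = 1) {
  n <- floor(raster$duration / step_ms)
  idx <- floor(raster$times / step_ms) + 1
  tabulate(idx[idx <= n], nbins = n)
}

#' Read and write spike rasters as plain text
#'
#' The format is two whitespace-separated columns (unit id, spike time in ms),
#' preceded by a single comment line holding a JSON object with `n_units`,
#' `duration` and any metadata, so that a written raster reads back losslessly
#' including its provenance. Files without the header are accepted if
#' `n_units` and `duration` are supplied.
#'
#' @param raster a [spike_raster()].
#' @param path file path.
#' @param n_units,duration required when reading a headerless file.
#' @return `read_raster` returns a [spike_raster()]; `write_raster` returns
#'   `path` invisibly.
#' @export
write_raster <- function(raster, path) {
  hdr <- jsonlite::toJSON(
    c(list(n_units = raster$n_units, duration = raster$duration,
           has_input_flags = !is.null(raster$is_input)),
      raster$meta),
    auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  if (is.null(raster$is_input)) {
    writeLines(sprintf("%d %.6f", raster$units, raster$times), con)
  } else {
    writeLines(sprintf("%d %.6f %d", raster$units, raster$times,
                       as.integer(raster$is_input)), con)
  }
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path, n_units = NULL, duration = NULL) {
  first <- readLines(path, n = 1)
  meta <- list()
  skip <- 0
  if (length(first) && startsWith(first, "#")) {
    meta <- jsonlite::fromJSON(sub("^#", "", first))
    skip <- 1
    n_units <- meta$n_units
    duration <- meta$duration
  }
  if (is.null(n_units) || is.null(duration))
    stop("headerless raster file: supply n_units and duration")
  tab <- utils::read.table(path, skip = skip)
  is_input <- if (ncol(tab) >= 3) as.logical(tab[[3]]) else NULL
  keep <- setdiff(names(meta), c("n_units", "duration", "has_input_flags"))
  if (nrow(tab) == 0)
    return(spike_raster(numeric(0), integer(0), n_units, duration,
                        meta = meta[keep]))
  spike_raster(tab[[2]], tab[[1]], n_units, duration, is_input = is_input,
               meta = meta[keep])
}
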