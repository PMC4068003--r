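#' Continuous multichannel traces
#'
#' A light container for uniformly sampled continuous signals (LFP-like):
#' a samples matrix (time x channels) plus the sampling rate in Hz.
#'
#' @param samples numeric matrix, one column per channel.
#' @param fs sampling rate in Hz (e.g. 400).
#' @param channels optional channel labels.
#' @return object of class `continuous_trace`.
#' @export
continuous_trace <- function(samples, fs, channels = NULL) {
  samples <- as.matrix(samples)
  stopifnot(fs > 0, all(is.finite(samples)))
  if (is.null(channels)) channels <- seq_len(ncol(samples))
  structure(list(samples = samples, fs = fs, channels = channels),
            class = "continuous_trace")
}

#' @export
print.continuous_trace <- function(x, ...) {
  cat(sprintf("continuous_trace: %d channels, %.1f s at %g Hz\n",
              ncol(x$samples), nrow(x$samples) / x$fs, x$fs))
  invisible(x)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a 4th-order Butterworth low-pass (default 40 Hz cutoff) in both
#' directions (`signal::filtfilt`), so event times are not shifted by filter
#' delay — binning at a few ms is phase-sensitive.
#'
#' @param trace a [continuous_trace()].
#' @param cutoff cutoff frequency in Hz.
#' @param order filter order.
#' @return the filtered [continuous_trace()].
#' @export
lfp_lowpass <- function(trace, cutoff = 40, order = 4) {
  stopifnot(inherits(trace, "continuous_trace"), cutoff < trace$fs / 2)
  bf <- signal::butter(order, cutoff / (trace$fs / 2), type = "low")
  out <- apply(trace$samples, 2, function(x) signal::filtfilt(bf, x))
  continuous_trace(out, trace$fs, trace$channels)
}

#' Areas of positive deflection lobes
#'
#' Finds zero crossings of a single-channel signal by sign change with linear
#' interpolation, and integrates each positive lobe between consecutive
#' crossings with the trapezoidal rule. The lobe area is proportional to the
#' displaced charge and is the quantity thresholded to define binary events.
#' Lobes truncated by the record boundary are integrated from/to the boundary
#' sample.
#'
#' @param x numeric signal of one channel.
#' @param fs sampling rate in Hz.
#' @return data.frame with `t_start`, `t_end`, `t_peak` (s), `area`
#'   (signal units x s), one row per positive lobe; zero rows if the signal
#'   is never positive.
#' @export
positive_lobe_areas <- function(x, fs) {
  n <- length(x)
  dt <- 1 / fs
  pos <- x > 0
  if (!any(pos))
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      t_peak = numeric(0), area = numeric(0)))
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  occ <- which(r$values)
  res <- lapply(occ, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    seg <- x[i0:i1]
    # trapezoid over the positive samples
    area <- if (length(seg) > 1) sum((seg[-1] + seg[-length(seg)]) / 2) * dt
            else 0
    t0 <- (i0 - 1) * dt; t1 <- (i1 - 1) * dt
    # interpolated zero crossing before the lobe
    if (i0 > 1) {
      f <- x[i0 - 1] / (x[i0 - 1] - x[i0])   # fraction of dt past sample i0-1
      tz <- (i0 - 2 + f) * dt
      area <- area + 0.5 * x[i0] * (t0 - tz)  # triangle from crossing
      t0 <- tz
    } else {
      area <- area + 0.5 * x[i0] * dt * 0     # boundary: start at sample
    }
    if (i1 < n) {
      f <- x[i1] / (x[i1] - x[i1 + 1])
      tz <- (i1 - 1 + f) * dt
      area <- area + 0.5 * x[i1] * (tz - t1)
      t1 <- tz
    }
    ipk <- i0 - 1 + which.max(seg)
    c(t0, t1, (ipk - 1) * dt, area)
  })
  m <- do.call(rbind, res)
  data.frame(t_start = m[, 1], t_end = m[, 2], t_peak = m[, 3],
             area = m[, 4])
}

#' Rate-matched thresholding of lobe areas
#'
#' Selects the per-channel area threshold such that each channel has the same
#' event rate (default 1/4 Hz): the `floor(target_rate * duration)` lobes
#' with the largest areas become events, ties broken by earliest time. The
#' event time is the lobe maximum.
#'
#' @param lobes a data.frame from [positive_lobe_areas()] (one channel).
#' @param duration_s record duration in s.
#' @param target_rate events per second per channel.
#' @return list with `times` (event times, ms), `threshold` (area units) and
#'   `rate` (achieved events/s).
#' @export
threshold_to_rate <- function(lobes, duration_s, target_rate = 0.25) {
  n_events <- floor(target_rate * duration_s)
  if (n_events < 1) stop("record too short for the target rate")
  if (nrow(lobes) < n_events)
    stop(sprintf("only %d lobes for %d required events", nrow(lobes), n_events))
  ord <- order(-lobes$area, lobes$t_peak)
  sel <- ord[seq_len(n_events)]
  thr <- min(lobes$area[sel])
  list(times = sort(lobes$t_peak[sel]) * 1000, threshold = thr,
       rate = n_events / duration_s)
}

#' Convert continuous traces to a binary event raster
#'
#' The full human-LFP analysis path: low-pass filter each channel (40 Hz,
#' 4th-order zero-phase Butterworth), compute positive-deflection-lobe areas,
#' threshold each channel to the common target event rate, and assemble the
#' events of all channels into a [spike_raster()] (events play the role of
#' spikes, so the avalanche statistics apply unchanged).
#'
#' @param trace a [continuous_trace()].
#' @param target_rate per-channel event rate in Hz (default 0.25).
#' @param cutoff low-pass cutoff in Hz; `NA` skips filtering.
#' @return a [spike_raster()]; per-channel thresholds in `meta$thresholds`.
#' @export
lfp_events <- function(trace, target_rate = 0.25, cutoff = 40) {
  stopifnot(inherits(trace, "continuous_trace"))
  if (!is.na(cutoff)) trace <- lfp_lowpass(trace, cutoff)
  duration_s <- nrow(trace$samples) / trace$fs
  per_ch <- lapply(seq_len(ncol(trace$samples)), function(ch) {
    lobes <- positive_lobe_areas(trace$samples[, ch], trace$fs)
    threshold_to_rate(lobes, duration_s, target_rate)
  })
  times <- unlist(lapply(per_ch, `[[`, "times"))
  units <- rep(seq_along(per_ch),
               vapply(per_ch, function(p) length(p$times), integer(1)))
  spike_raster(times, units, length(per_ch), duration_s * 1000,
               meta = list(thresholds = vapply(per_ch, `[[`, numeric(1),
                                               "threshold"),
                           target_rate = target_rate, fs = trace$fs))
}
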