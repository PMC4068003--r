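#' Temporal binning of a spike raster
#'
#' Pools the spikes of all units and counts them in half-open bins
#' `[j*bs, (j+1)*bs)`. The trailing partial bin is dropped. Temporal binning
#' is the basis of the avalanche definition used for driven activity and for
#' recordings, which lack a separation of time scales.
#'
#' @param raster a [spike_raster()] (or a numeric vector of spike times, in
#'   which case `duration` must be given).
#' @param bs bin size in ms.
#' @param duration recording duration in ms when `raster` is a plain vector.
#' @return object of class `binned_counts`: integer `counts`, `bs`, `n_bins`.
#' @export
bin_spikes <- function(raster, bs, duration = NULL) {
  if (inherits(raster, "spike_raster")) {
    times <- raster$times
    duration <- raster$duration
  } else {
    times <- raster
    if (is.null(duration)) duration <- max(times) + 1e-9
  }
  stopifnot(bs > 0)
  if (length(times) == 0L) stop("cannot bin an empty raster")
  n_bins <- floor(duration / bs)
  if (n_bins < 1) stop("bin size exceeds the recording duration")
  idx <- floor(times / bs) + 1
  counts <- tabulate(idx[idx <= n_bins], nbins = n_bins)
  structure(list(counts = counts, bs = bs, n_bins = n_bins),
            class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf("binned_counts: %d bins of %g ms, %d spikes, %.1f%% empty\n",
              x$n_bins, x$bs, sum(x$counts), 100 * mean(x$counts == 0)))
  invisible(x)
}

#' Extract avalanches from binned counts
#'
#' An avalanche is the ensemble of spikes in a maximal run of non-empty bins;
#' it is preceded and followed by an empty bin. Its size is the total spike
#' count of the run. Runs touching the start or end of the record cannot be
#' delimited by an empty bin on that side; they are kept but flagged, so
#' statistics can be computed with or without them.
#'
#' @param counts a [bin_spikes()] result.
#' @return object of class `avalanche_set`: `sizes`, `durations` (bins),
#'   `boundary` flags, `bs`, `n_avalanches`.
#' @export
extract_avalanches <- function(counts) {
  stopifnot(inherits(counts, "binned_counts"))
  cc <- counts$counts
  r <- rle(cc > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  occ <- which(r$values)
  if (length(occ) == 0L) {
    out <- list(sizes = integer(0), durations = integer(0),
                boundary = logical(0), bs = counts$bs, n_avalanches = 0L)
    class(out) <- "avalanche_set"
    return(out)
  }
  cs <- c(0, cumsum(cc))
  sizes <- cs[ends[occ] + 1] - cs[starts[occ]]
  boundary <- (starts[occ] == 1) | (ends[occ] == counts$n_bins)
  out <- list(sizes = as.integer(sizes), durations = r$lengths[occ],
              boundary = boundary, bs = counts$bs,
              n_avalanches = length(occ))
  class(out) <- "avalanche_set"
  out
}

#' @export
print.avalanche_set <- function(x, ...) {
  cat(sprintf("avalanche_set: %d avalanches at bs = %g ms, <s> = %.3f, max s = %d\n",
              x$n_avalanches, x$bs,
              if (x$n_avalanches) mean(x$sizes) else NA_real_,
              if (x$n_avalanches) max(x$sizes) else NA_integer_))
  invisible(x)
}

#' Mean avalanche size
#'
#' @param av an [extract_avalanches()] result.
#' @param boundary include record-boundary avalanches (default TRUE).
#' @return arithmetic mean of avalanche sizes.
#' @export
mean_size <- function(av, boundary = TRUE) {
  stopifnot(inherits(av, "avalanche_set"))
  s <- if (boundary) av$sizes else av$sizes[!av$boundary]
  if (length(s) == 0L) stop("no avalanches")
  mean(s)
}

#' Bin-ratio estimate of the branching parameter
#'
#' `sigma*_i` is the spike count in bin i divided by the count in bin i-1,
#' defined only where the preceding bin is non-empty (an empty successor
#' counts as ratio 0). `sigma*` is the mean of the defined ratios. For a
#' branching process observed fully and bin-by-bin this estimates the
#' branching parameter; under subsampling, binning and drive it acquires
#' strong bin-size dependence.
#'
#' @param counts a [bin_spikes()] result.
#' @param keep_ratios retain the individual ratios (for standard errors).
#' @return object of class `branching_estimate` with `sigma`, `n_defined`,
#'   `bs` (and `ratios` if requested).
#' @export
estimate_sigma <- function(counts, keep_ratios = FALSE) {
  stopifnot(inherits(counts, "binned_counts"))
  cc <- counts$counts
  if (length(cc) < 2) stop("need at least two bins")
  prev <- cc[-length(cc)]
  cur <- cc[-1]
  ok <- prev > 0
  if (!any(ok)) stop("no defined ratios: every predecessor bin is empty")
  ratios <- cur[ok] / prev[ok]
  structure(list(sigma = mean(ratios), n_defined = sum(ok),
                 bs = counts$bs,
                 ratios = if (keep_ratios) ratios),
            class = "branching_estimate")
}

#' @export
print.branching_estimate <- function(x, ...) {
  cat(sprintf("sigma* = %.4f (bs = %g ms, %d defined ratios)\n",
              x$sigma, x$bs, x$n_defined))
  invisible(x)
}

#' Bin-size families of avalanche statistics
#'
#' Computes, for each bin size in `bs_list` (ms), the avalanche statistics
#' whose bin-size dependence discriminates dynamical regimes: the mean
#' avalanche size `<s>`, the frequency of size-one avalanches `f(s=1, bs)`,
#' the estimated branching parameter `sigma*`, and the number of avalanches.
#' Bin sizes can also be given in units of the mean inter-event interval.
#'
#' @param raster a [spike_raster()].
#' @param bs_list bin sizes, ascending.
#' @param units `"ms"` or `"iei"`; with `"iei"`, `bs_list` is multiplied by
#'   `mean_iei(raster)`.
#' @param boundary include record-boundary avalanches.
#' @return a `data.frame` with columns `bs` (ms), `bs_iei`, `n_avalanches`,
#'   `mean_size`, `f1` (count of size-one avalanches), `sigma`.
#' @export
avalanche_statistics <- function(raster, bs_list, units = c("ms", "iei"),
                                 boundary = TRUE) {
  units <- match.arg(units)
  iei <- mean_iei(raster)
  bs_ms <- if (units == "iei") bs_list * iei else bs_list
  rows <- lapply(seq_along(bs_ms), function(i) {
    bc <- bin_spikes(raster, bs_ms[i])
    av <- extract_avalanches(bc)
    s <- if (boundary) av$sizes else av$sizes[!av$boundary]
    sg <- tryCatch(estimate_sigma(bc)$sigma, error = function(e) NA_real_)
    data.frame(bs = bs_ms[i], bs_iei = bs_ms[i] / iei,
               n_avalanches = length(s),
               mean_size = if (length(s)) mean(s) else NA_real_,
               f1 = sum(s == 1L), sigma = sg)
  })
  out <- do.call(rbind, rows)
  attr(out, "iei") <- iei
  out
}

#' Normalized frequency of size-one avalanches versus bin size
#'
#' `f(s = 1, bs)` is the number of avalanches of size one at each bin size.
#' Following the convention used for cross-experiment comparison, the curve
#' is normalized so that its value at `bs = 1 <IEI>` equals 1 (the grid is
#' augmented with `1 <IEI>` if absent). For a driven critical system this
#' curve is a power law in `bs`; for Poisson activity it decays
#' exponentially.
#'
#' @param raster a [spike_raster()].
#' @param bs_iei bin sizes in units of the mean inter-event interval.
#' @param boundary include record-boundary avalanches.
#' @return a `data.frame` with `bs_iei`, `bs` (ms), `f1` (raw count) and
#'   `f1_norm` (normalized), with the normalization value as an attribute.
#' @export
f1_curve <- function(raster, bs_iei = 2^(-1:6), boundary = TRUE) {
  grid <- sort(unique(c(1, bs_iei)))
  st <- avalanche_statistics(raster, grid, units = "iei", boundary = boundary)
  ref <- st$f1[match(1, grid)]
  if (is.na(ref) || ref == 0)
    stop("no size-one avalanches at the normalization bin of 1 <IEI>")
  out <- data.frame(bs_iei = st$bs_iei, bs = st$bs, f1 = st$f1,
                    f1_norm = st$f1 / ref)
  out <- out[out$bs_iei %in% bs_iei | abs(out$bs_iei - 1) < 1e-12, ]
  attr(out, "f1_at_1iei") <- ref
  out
}

#' Avalanche size distribution
#'
#' Tabulates avalanche sizes into the frequency distribution `f(s)` (absolute
#' counts) and the probability distribution `p(s)`.
#'
#' @param sizes integer avalanche sizes, or an [extract_avalanches()] result.
#' @return object of class `size_distribution`: data.frame with `s`, `count`,
#'   `p`.
#' @export
size_dist <- function(sizes) {
  if (inherits(sizes, "avalanche_set")) sizes <- sizes$sizes
  if (inherits(sizes, "avalanche_records")) sizes <- sizes$size
  if (length(sizes) == 0L) stop("no sizes")
  tab <- table(sizes)
  s <- as.integer(names(tab))
  out <- data.frame(s = s, count = as.integer(tab),
                    p = as.integer(tab) / length(sizes))
  class(out) <- c("size_distribution", "data.frame")
  attr(out, "n") <- length(sizes)
  out
}

#' Logarithmic binning of a size distribution
#'
#' Rebins `f(s)` into geometrically spaced bins: the height of each bin is
#' the total count divided by the bin width (a per-unit-size density) and its
#' support point is the geometric mean of the bin edges. Log binning smooths
#' the noisy tail of heavy-tailed distributions without distorting a power
#' law, whose log-binned densities lie on the original line.
#'
#' @param dist a [size_dist()] result.
#' @param bins_per_decade geometric bin density (default 10).
#' @return data.frame with `s` (support point), `density` (counts per unit
#'   size), `count`, `lo`, `hi` (bin edges); empty bins are dropped.
#' @export
log_bin <- function(dist, bins_per_decade = 10) {
  stopifnot(inherits(dist, "size_distribution"))
  if (nrow(dist) == 0L) stop("empty distribution")
  smin <- min(dist$s); smax <- max(dist$s)
  lo10 <- log10(smin - 0.5 + 1e-9)
  hi10 <- log10(smax + 0.5)
  n_bins <- max(1L, ceiling((hi10 - lo10) * bins_per_decade))
  edges <- 10^seq(lo10, hi10, length.out = n_bins + 1)
  idx <- findInterval(dist$s, edges, rightmost.closed = TRUE)
  cnt <- vapply(seq_len(n_bins),
                function(b) sum(dist$count[idx == b]), numeric(1))
  width <- diff(edges)
  keep <- cnt > 0
  data.frame(s = sqrt(edges[-length(edges)] * edges[-1])[keep],
             density = (cnt / width)[keep], count = cnt[keep],
             lo = edges[-length(edges)][keep], hi = edges[-1][keep])
}

#' @export
plot.size_distribution <- function(x, log_binned = TRUE, bins_per_decade = 10,
                                   ...) {
  if (log_binned) {
    lb <- log_bin(x, bins_per_decade)
    plot(lb$s, lb$density, log = "xy", xlab = "avalanche size s",
         ylab = "f(s) [density]", ...)
  } else {
    plot(x$s, x$count, log = "xy", xlab = "avalanche size s",
         ylab = "f(s) [counts]", ...)
  }
  invisible(x)
}
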