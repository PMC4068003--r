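#' Independent Poisson spike raster
#'
#' Homogeneous Poisson spiking, independent across units — the `alpha = 0`
#' limit of both network models and the null model for all avalanche
#' statistics (their closed-form Poisson expectations are the standard
#' oracles).
#'
#' @param n_units number of units.
#' @param rate single-unit rate in Hz.
#' @param duration_ms record length in ms.
#' @param seed optional integer seed.
#' @return a [spike_raster()].
#' @export
make_poisson_raster <- function(n_units, rate, duration_ms, seed = NULL) {
  stopifnot(n_units >= 1, rate >= 0, duration_ms > 0)
  if (!is.null(seed)) set.seed(seed)
  n_sp <- stats::rpois(n_units, rate * duration_ms / 1000)
  if (sum(n_sp) == 0L)
    warning("empty raster: no spikes at rate ", rate, " Hz")
  times <- stats::runif(sum(n_sp), 0, duration_ms)
  units <- rep(seq_len(n_units), n_sp)
  spike_raster(times, units, n_units, duration_ms,
               meta = list(kind = "poisson", rate = rate, seed = seed))
}

#' Surrogate raster with lognormal avalanche sizes
#'
#' An explicit caricature of an in-vivo-like recording built for testing the
#' statistics path, not for modelling cortex: avalanche sizes are drawn from
#' the mass-discretized lognormal (defaults match in vivo estimates,
#' `mu = 0.89`, `sigma2 = 1.2`), each avalanche's spikes occupy consecutive
#' non-empty bins of width one target `<IEI>`, and avalanches are separated
#' by geometrically distributed runs of empty bins tuned so that the
#' population rate matches `target_R`. Extracting avalanches at
#' `bs = 1 <IEI>` recovers the generated sizes exactly.
#'
#' @param n_units number of units events are attributed to.
#' @param mu,sigma2 lognormal parameters of the size distribution.
#' @param target_R target population rate in Hz (in vivo range ~37-1560 Hz).
#' @param duration_ms record length in ms.
#' @param seed optional integer seed.
#' @return a [spike_raster()]; `meta$bin_ms` records the construction bin.
#' @export
make_invivo_like_raster <- function(n_units = 100, mu = 0.89, sigma2 = 1.2,
                                    target_R = 320, duration_ms = 6e5,
                                    seed = NULL) {
  stopifnot(target_R > 0, duration_ms > 0)
  if (!is.null(seed)) set.seed(seed)
  bin_ms <- 1000 / target_R                 # one target <IEI>
  n_bins <- floor(duration_ms / bin_ms)
  # draw generously, then trim to the duration
  mean_s <- exp(mu + sigma2 / 2)
  n_av <- ceiling(n_bins / mean_s * 1.5) + 100
  sizes <- rlnorm_discrete(n_av, mu, sigma2)
  occ <- pmax(1, ceiling(sizes / 2))        # bins occupied per avalanche
  # average bins consumed per avalanche must be mean(sizes) so that
  # R = spikes / time matches the target; the remainder goes into gaps
  gap_mean <- mean(sizes) - mean(occ)
  if (gap_mean < 1) gap_mean <- 1
  gaps <- 1 + stats::rgeom(n_av, 1 / gap_mean)
  start_bin <- cumsum(c(1, (occ + gaps)[-n_av]))
  keep <- (start_bin + occ - 1) <= (n_bins - 1)  # leave the final bin empty
  sizes <- sizes[keep]; occ <- occ[keep]; start_bin <- start_bin[keep]
  # round-robin spike placement guarantees every occupied bin is non-empty
  bin_of <- unlist(lapply(seq_along(sizes), function(i)
    start_bin[i] + (seq_len(sizes[i]) - 1) %% occ[i]))
  times <- (bin_of - 1) * bin_ms + stats::runif(length(bin_of)) * bin_ms
  units <- sample.int(n_units, length(bin_of), replace = TRUE)
  spike_raster(times, units, n_units, duration_ms,
               meta = list(kind = "invivo_like", mu = mu, sigma2 = sigma2,
                           target_R = target_R, bin_ms = bin_ms,
                           sizes = sizes, seed = seed))
}

#' Fractional noise with a prescribed Hurst exponent
#'
#' Spectral synthesis: Fourier amplitudes follow `f^-(2H - 1)/2` (power
#' spectrum `f^-(2H - 1)`) with random phases, so the detrended fluctuation
#' exponent of the output is `beta = H` (`H = 0.5` white, `H = 1` pink).
#' Used to calibrate the DFA estimator against a known truth.
#'
#' @param H Hurst exponent (0 < H < 1.5).
#' @param n series length.
#' @param seed optional integer seed.
#' @return numeric series, standardized to mean 0, sd 1.
#' @export
make_fractional_noise <- function(H, n, seed = NULL) {
  stopifnot(H > 0, H < 1.5, n >= 16)
  if (!is.null(seed)) set.seed(seed)
  m <- n %/% 2
  f <- seq_len(m)
  amp <- f^(-(2 * H - 1) / 2)
  phase <- stats::runif(m, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(m + 1)] <- spec
  # taking the real part below Hermitian-symmetrizes the spectrum implicitly
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Surrogate multichannel LFP-like traces
#'
#' Each channel is a mix of low-frequency sinusoids with random phases and
#' amplitudes plus pink-noise background, sampled at `fs` Hz. The slow
#' oscillations create well-separated positive deflection lobes, the input
#' class the event-extraction stage consumes.
#'
#' @param n_channels number of channels.
#' @param duration_s record length in seconds.
#' @param fs sampling rate in Hz.
#' @param osc_freqs oscillation frequencies in Hz.
#' @param noise_sd pink-noise amplitude relative to the oscillation mix.
#' @param seed optional integer seed.
#' @return a [continuous_trace()].
#' @export
make_lfp_surrogate <- function(n_channels = 50, duration_s = 60, fs = 400,
                               osc_freqs = c(0.7, 1.3, 2.1, 3.5),
                               noise_sd = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  t <- seq_len(n) / fs
  samples <- vapply(seq_len(n_channels), function(ch) {
    x <- numeric(n)
    for (f in osc_freqs)
      x <- x + stats::runif(1, 0.5, 1.5) *
        sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
    if (noise_sd > 0)
      x <- x + noise_sd * make_fractional_noise(1, n)
    x
  }, numeric(n))
  continuous_trace(samples, fs)
}
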