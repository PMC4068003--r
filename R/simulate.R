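#' Simulate avalanches under separation of time scales
#'
#' In separation-of-time-scales (STS) mode, external input is applied only
#' when the network is quiescent: one uniformly random unit is set above
#' threshold, the resulting cascade is run to extinction, and its total spike
#' count is recorded as one avalanche size. This implements the `h -> 0`
#' limit in which the lattice model is the classic self-organized critical
#' sandpile.
#'
#' @param cfg a [soc_config()] or [branching_config()] with `mode = "STS"`.
#' @param n_avalanches number of avalanches to record (after the transient).
#' @param seed optional integer; if given, `set.seed(seed)` is called so the
#'   run is bit-reproducible.
#' @param size_cap abort threshold for non-terminating cascades (possible
#'   only for supercritical parameters); capped avalanches are flagged.
#' @return a `data.frame` of class `avalanche_records` with columns `size`
#'   (total spikes), `duration` (steps) and `capped`, plus the config and
#'   seed as attributes.
#' @export
run_sts <- function(cfg, n_avalanches, seed = NULL, size_cap = 1e7) {
  stopifnot(inherits(cfg, "model_config"), n_avalanches >= 1)
  if (cfg$mode != "STS") stop("run_sts needs a config with mode = 'STS'")
  if (!is.null(seed)) set.seed(seed)
  if (inherits(cfg, "soc_config")) {
    transient <- if (is.null(cfg$transient)) 10000L else cfg$transient
    res <- soc_sts_cpp(cfg$L, cfg$alpha, as.integer(n_avalanches),
                       as.integer(transient), size_cap)
  } else {
    # cascades are started from a memoryless network: no state persists
    # between avalanches, so no transient is required
    transient <- if (is.null(cfg$transient)) 0L else cfg$transient
    res <- branching_sts_cpp(cfg$n_neurons, cfg$k, cfg$alpha, cfg$p_diss,
                             as.integer(n_avalanches), as.integer(transient),
                             size_cap)
  }
  if (any(res$capped))
    warning(sum(res$capped), " cascade(s) hit the size cap of ", size_cap)
  out <- data.frame(size = res$sizes, duration = res$durations,
                    capped = res$capped)
  attr(out, "cfg") <- cfg
  attr(out, "seed") <- seed
  class(out) <- c("avalanche_records", "data.frame")
  out
}

#' Simulate the driven network
#'
#' In driven mode every unit independently receives a Poisson external input
#' at rate `cfg$drive_rate` (Hz) that sets it above threshold; inputs and
#' synaptic propagation run concurrently, so avalanches overlap and form a
#' melange. Each spike carries an origin flag separating externally driven
#' (input) spikes from synaptically propagated ones.
#'
#' @param cfg a [soc_config()] or [branching_config()] with `mode = "driven"`.
#' @param duration_ms recorded duration in ms (after the transient).
#' @param seed optional integer seed.
#' @param max_spikes abort threshold guarding runaway activity.
#' @return a [spike_raster()] with `is_input` flags; its `meta` records the
#'   config, seed and the realized input-spike count.
#' @export
run_driven <- function(cfg, duration_ms, seed = NULL, max_spikes = 5e8) {
  stopifnot(inherits(cfg, "model_config"), duration_ms >= 1)
  if (cfg$mode != "driven") stop("run_driven needs a config with mode = 'driven'")
  if (!is.null(seed)) set.seed(seed)
  transient <- if (is.null(cfg$transient)) 100000L else as.integer(cfg$transient)
  h_ms <- cfg$drive_rate / 1000 * cfg$step_ms
  res <- if (inherits(cfg, "soc_config")) {
    soc_driven_cpp(cfg$L, cfg$alpha, h_ms, as.integer(duration_ms),
                   transient, TRUE, max_spikes)
  } else {
    branching_driven_cpp(cfg$n_neurons, cfg$k, cfg$alpha, cfg$p_diss, h_ms,
                         as.integer(duration_ms), transient, TRUE, max_spikes)
  }
  spike_raster(as.numeric(res$times), res$units + 1L, cfg$n_neurons,
               duration_ms, is_input = res$is_input,
               meta = list(cfg = unclass(cfg), model = class(cfg)[1],
                           seed = seed, transient = transient,
                           input_spikes = res$input_spikes,
                           total_spikes = res$total_spikes))
}

#' Stationary single-unit rate of a driven model
#'
#' Runs the model without recording individual spikes and returns the
#' post-transient single-unit rate, total spikes / (N x duration), in Hz.
#'
#' @param cfg a driven-mode config.
#' @param duration_ms measurement window in ms.
#' @param transient_ms discarded warm-up in ms.
#' @return single-unit rate in Hz.
#' @export
estimate_rate <- function(cfg, duration_ms = 2e5, transient_ms = 1e5) {
  h_ms <- cfg$drive_rate / 1000 * cfg$step_ms
  res <- if (inherits(cfg, "soc_config")) {
    soc_driven_cpp(cfg$L, cfg$alpha, h_ms, as.integer(duration_ms),
                   as.integer(transient_ms), FALSE, Inf)
  } else {
    branching_driven_cpp(cfg$n_neurons, cfg$k, cfg$alpha, cfg$p_diss, h_ms,
                         as.integer(duration_ms), as.integer(transient_ms),
                         FALSE, Inf)
  }
  res$total_spikes / cfg$n_neurons / (duration_ms / 1000)
}

#' Calibrate the drive rate to a target single-unit rate
#'
#' Finds the per-neuron Poisson drive rate `h` at which the driven model
#' fires at `target_rate` Hz per unit, by monotone bisection on `log h`. The
#' rate at each candidate `h` is estimated from a fixed-length post-transient
#' run. At `alpha = 0` the units are independent Poisson processes firing at
#' exactly the drive rate, so the target itself is returned.
#'
#' @param cfg a [soc_config()] or [branching_config()]; its `drive_rate` is
#'   ignored and replaced by each candidate.
#' @param target_rate desired single-unit rate in Hz.
#' @param tol relative tolerance on the achieved rate (default 2%).
#' @param seed optional integer seed.
#' @param est_duration_ms,transient_ms simulated window per bisection step.
#' @param max_iter bisection iteration cap.
#' @return the calibrated `h` in Hz, with the achieved rate and iteration
#'   count as attributes.
#' @export
calibrate_drive <- function(cfg, target_rate, tol = 0.02, seed = NULL,
                            est_duration_ms = 2e5, transient_ms = 1e5,
                            max_iter = 30) {
  stopifnot(target_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  if (cfg$alpha == 0) {
    h <- target_rate
    attr(h, "achieved_rate") <- target_rate
    attr(h, "iterations") <- 0L
    return(h)
  }
  rate_at <- function(h) {
    cfg$drive_rate <- h
    cfg$mode <- "driven"
    estimate_rate(cfg, est_duration_ms, transient_ms)
  }
  # every input spike yields at least one spike, so r(h) >= h up to input
  # collisions: h = target_rate is an upper bracket; amplification is bounded
  # by the charge balance of the models, so a generous lower bracket works
  lo <- target_rate / 2e4; hi <- target_rate
  r_lo <- rate_at(lo); r_hi <- rate_at(hi)
  if (r_lo > target_rate || r_hi < target_rate * (1 - tol))
    stop(sprintf(
      "bisection bracket failed: r(%.3g) = %.3g, r(%.3g) = %.3g, target %.3g",
      lo, r_lo, hi, r_hi, target_rate))
  h <- hi; r <- r_hi; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    mid <- sqrt(lo * hi)
    r_mid <- rate_at(mid)
    if (abs(r_mid - target_rate) / target_rate < tol) {
      h <- mid; r <- r_mid
      break
    }
    if (r_mid < target_rate) lo <- mid else hi <- mid
    h <- mid; r <- r_mid
  }
  if (abs(r - target_rate) / target_rate >= tol) {
    # fall back to the geometric midpoint of the final bracket
    h <- sqrt(lo * hi)
    r <- rate_at(h)
    if (abs(r - target_rate) / target_rate >= 3 * tol)
      stop(sprintf("calibration did not converge: r(%.3g) = %.3g, target %.3g",
                   h, r, target_rate))
  }
  attr(h, "achieved_rate") <- r
  attr(h, "iterations") <- it
  h
}
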