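#' Run a model-side avalanche experiment end to end
#'
#' For each requested coupling strength `alpha`, simulates the chosen model
#' (STS mode, or driven mode with the drive calibrated to `target_rate` per
#' unit), applies the sampling scheme, and computes the bin-size families of
#' avalanche statistics (`<s>`, `f(s=1, bs)`, `sigma*`) plus the DFA exponent
#' of the full-sampling population signal. Each (alpha, replicate) cell is
#' simulated with its own derived seed, so the whole table is reproducible
#' from `seed` alone.
#'
#' @param alphas coupling strengths to sweep.
#' @param model `"soc"` or `"branching"`.
#' @param mode `"driven"` or `"STS"`.
#' @param scheme a [sampling_scheme()] or NULL for full sampling.
#' @param bs_list bin sizes in ms for the statistics.
#' @param duration_ms driven-mode recorded duration per cell.
#' @param n_avalanches STS-mode avalanche count per cell.
#' @param target_rate driven-mode single-unit rate in Hz.
#' @param replicates independent seeds per cell.
#' @param seed master seed.
#' @param dfa_windows window widths for the DFA stage (NULL skips DFA).
#' @return object of class `experiment_result`: a long data.frame with one
#'   row per (alpha, replicate, bs) and columns `mean_size`, `f1`, `sigma`,
#'   plus per-cell `beta` and the calibrated `h`; provenance (seeds, configs)
#'   in attributes.
#' @export
run_experiment <- function(alphas, model = c("soc", "branching"),
                           mode = c("driven", "STS"), scheme = NULL,
                           bs_list = 2^(0:9), duration_ms = 2e5,
                           n_avalanches = 1e4, target_rate = 5,
                           replicates = 1, seed = 1,
                           dfa_windows = 2^(4:11)) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  if (replicates < 1) stop("need at least one replicate")
  cells <- expand.grid(alpha = alphas, replicate = seq_len(replicates))
  rows <- list(); cell_rows <- list()
  for (i in seq_len(nrow(cells))) {
    a <- cells$alpha[i]; rep_i <- cells$replicate[i]
    cell_seed <- (seed * 10007L + i) %% .Machine$integer.max
    mk <- function(h = 0, md = mode) {
      if (model == "soc") soc_config(alpha = a, drive_rate = h, mode = md)
      else branching_config(alpha = a, drive_rate = h, mode = md)
    }
    if (mode == "driven") {
      h <- calibrate_drive(mk(1e-3), target_rate, seed = cell_seed)
      raster <- run_driven(mk(as.numeric(h)), duration_ms,
                           seed = cell_seed + 1L)
    } else {
      rec <- run_sts(mk(), n_avalanches, seed = cell_seed)
      # STS cascades laid end to end with one empty step between them give a
      # raster whose bin statistics reflect the separated avalanches
      raster <- sts_raster(rec, mk())
      h <- 0
    }
    beta <- if (!is.null(dfa_windows) &&
                raster$duration >= 4 * max(dfa_windows)) {
      dfa(population_signal(raster), dfa_windows)$beta
    } else NA_real_
    sub <- if (!is.null(scheme)) subsample(raster, scheme) else raster
    st <- avalanche_statistics(sub, bs_list)
    st$alpha <- a; st$replicate <- rep_i; st$h <- as.numeric(h)
    st$beta <- beta
    rows[[i]] <- st
    cell_rows[[i]] <- list(alpha = a, replicate = rep_i, seed = cell_seed,
                           h = as.numeric(h), beta = beta)
  }
  out <- do.call(rbind, rows)
  attr(out, "cells") <- cell_rows
  attr(out, "model") <- model
  attr(out, "mode") <- mode
  attr(out, "seed") <- seed
  class(out) <- c("experiment_result", "data.frame")
  out
}

#' Lay separated avalanches out as a spike raster
#'
#' Places the cascades of an STS run end to end on a 1 ms grid with a fixed
#' pause of `gap_steps` empty steps between consecutive avalanches. Under
#' separation of time scales the pauses are arbitrarily long, so their exact
#' length is irrelevant to any bin statistic computed at bin sizes well below
#' the pause; `gap_steps` only needs to exceed the largest analysis bin.
#' Spikes are spread uniformly over each avalanche's recorded duration; unit
#' identity is drawn uniformly.
#'
#' @param records an [run_sts()] result.
#' @param cfg the generating config (supplies `n_neurons`).
#' @param gap_steps empty steps between avalanches (default 1024 ms, above
#'   the largest bin size in common use).
#' @return a [spike_raster()].
#' @export
sts_raster <- function(records, cfg, gap_steps = 1024) {
  dur <- pmax(records$duration, 1L)
  gaps <- rep(as.integer(gap_steps), nrow(records))
  starts <- cumsum(c(0L, (dur + gaps)[-nrow(records)]))
  # spread each avalanche's spikes uniformly over its duration in steps
  times <- unlist(mapply(function(s, d, t0)
    t0 + (seq_len(s) - 1) %% d + stats::runif(s), records$size, dur, starts,
    SIMPLIFY = FALSE))
  total <- sum(records$size)
  units <- sample.int(cfg$n_neurons, total, replace = TRUE)
  spike_raster(times, units, cfg$n_neurons, sum(dur + gaps) + 1,
               meta = list(kind = "sts_raster", cfg = unclass(cfg)))
}

#' Peak of a branching-parameter curve
#'
#' Locates the maximum of `sigma*` over the bin-size grid, refining the
#' location by a quadratic fit through the maximum and its neighbours in
#' `log2(bs)`. A maximum at the grid boundary is returned unrefined and
#' flagged, since no interior peak exists.
#'
#' @param bs bin sizes (ms), ascending.
#' @param sigma the matching `sigma*` values.
#' @return list with `bs_peak`, `sigma_max`, `boundary` (TRUE if the maximum
#'   sits on the grid edge).
#' @export
sigma_peak <- function(bs, sigma) {
  stopifnot(length(bs) == length(sigma), length(bs) >= 3)
  i <- which.max(sigma)
  if (i == 1L || i == length(bs))
    return(list(bs_peak = bs[i], sigma_max = sigma[i], boundary = TRUE))
  x <- log2(bs[(i - 1):(i + 1)])
  y <- sigma[(i - 1):(i + 1)]
  # exact parabola through three points
  d21 <- (y[2] - y[1]) / (x[2] - x[1])
  d32 <- (y[3] - y[2]) / (x[3] - x[2])
  curv <- (d32 - d21) / (x[3] - x[1])
  if (curv >= 0)
    return(list(bs_peak = bs[i], sigma_max = sigma[i], boundary = FALSE))
  xv <- (x[1] + x[2]) / 2 - d21 / (2 * curv)
  xv <- min(max(xv, x[1]), x[3])
  # evaluate the interpolating parabola at xv (Newton form)
  yv <- y[1] + d21 * (xv - x[1]) + curv * (xv - x[1]) * (xv - x[2])
  list(bs_peak = 2^xv, sigma_max = yv, boundary = FALSE)
}
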