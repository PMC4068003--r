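#' Model configurations
#'
#' `soc_config()` describes the modified Bak-Tang-Wiesenfeld lattice: `L^2`
#' non-leaky integrate-and-fire neurons on an `L x L` grid with open
#' boundaries, nearest-neighbour coupling `alpha`, spike threshold 0 and a
#' per-neuron Poisson drive of rate `drive_rate` (Hz) that sets a unit just
#' above threshold. `branching_config()` describes the stochastic branching
#' network: each active unit picks `k` random targets and activates each with
#' probability `alpha / k`, attenuated by the dissipation probability
#' `p_diss`.
#'
#' In `"STS"` mode (separation of time scales, the `h -> 0` limit) external
#' input is applied only when the network is quiescent, so avalanches never
#' overlap; in `"driven"` mode drive and propagation run concurrently.
#'
#' @param L lattice side (L^2 neurons).
#' @param alpha coupling strength in `[0, 1]` (1 = conservative/critical).
#' @param drive_rate per-neuron Poisson input rate h in Hz (driven mode).
#' @param mode `"STS"` or `"driven"`.
#' @param transient discard period before statistics are collected: number of
#'   avalanches (STS) or of 1 ms steps (driven). `NULL` picks the default
#'   (1e4 avalanches / 1e5 steps).
#' @param n_neurons,k,p_diss branching-network size, out-degree and
#'   per-target dissipation probability.
#' @return a config object of class `soc_config` or `branching_config`.
#' @export
soc_config <- function(L = 50, alpha = 1, drive_rate = 0,
                       mode = c("STS", "driven"), transient = NULL) {
  mode <- match.arg(mode)
  stopifnot(L >= 2, alpha >= 0, alpha <= 1, drive_rate >= 0)
  if (mode == "driven" && drive_rate <= 0)
    stop("driven mode needs drive_rate > 0")
  structure(list(L = as.integer(L), n_neurons = as.integer(L)^2,
                 alpha = alpha, drive_rate = drive_rate, threshold = 0,
                 mode = mode, step_ms = 1, transient = transient),
            class = c("soc_config", "model_config"))
}

#' @rdname soc_config
#' @export
branching_config <- function(n_neurons = 2500, k = 4, alpha = 1,
                             p_diss = 0.001, drive_rate = 0,
                             mode = c("STS", "driven"), transient = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_neurons >= 2, k >= 1, alpha >= 0, p_diss >= 0, p_diss <= 1,
            drive_rate >= 0)
  if (alpha / k > 1) stop("activation probability alpha/k must be <= 1")
  if (mode == "driven" && drive_rate <= 0)
    stop("driven mode needs drive_rate > 0")
  structure(list(n_neurons = as.integer(n_neurons), k = as.integer(k),
                 alpha = alpha, p_diss = p_diss, drive_rate = drive_rate,
                 mode = mode, step_ms = 1, transient = transient),
            class = c("branching_config", "model_config"))
}

#' @export
print.model_config <- function(x, ...) {
  kind <- if (inherits(x, "soc_config")) {
    sprintf("SOC lattice %dx%d", x$L, x$L)
  } else {
    sprintf("branching network n=%d k=%d p_diss=%g", x$n_neurons, x$k, x$p_diss)
  }
  cat(sprintf("%s | alpha=%g mode=%s h=%g Hz\n",
              kind, x$alpha, x$mode, x$drive_rate))
  invisible(x)
}

#' Single synchronous update of the SOC lattice (reference implementation)
#'
#' Applies one 1 ms step of the lattice rule to an explicit state: every unit
#' with `V > 0` (including units in `forced_units`, which are first set just
#' above threshold) spikes; a spiker's potential drops by 4 and each of its
#' existing lattice neighbours gains `alpha`; edge and corner units deliver to
#' only 3 and 2 neighbours (open boundary, the remainder is dissipated).
#' This plain-R version defines the update rule; the long simulations run the
#' same rule in compiled code.
#'
#' @param state list with `V` (numeric vector of length `L^2`, row-major
#'   lattice order) and `t` (current time, ms).
#' @param cfg a [soc_config()].
#' @param forced_units integer ids of units externally set above threshold at
#'   this step.
#' @return list with the updated `state` and `spikers`, the integer ids of
#'   units that spiked during the step.
#' @export
soc_step <- function(state, cfg, forced_units = integer(0)) {
  L <- cfg$L
  V <- state$V
  stopifnot(length(V) == L^2)
  if (length(forced_units)) V[forced_units] <- pmax(V[forced_units], 1e-6)
  spikers <- which(V > cfg$threshold)
  if (length(spikers)) {
    V[spikers] <- V[spikers] - 4
    idx0 <- spikers - 1L
    r <- idx0 %/% L; cc <- idx0 %% L
    up <- spikers[r > 0] - L
    dn <- spikers[r < L - 1] + L
    lf <- spikers[cc > 0] - 1L
    rt <- spikers[cc < L - 1] + 1L
    for (nb in list(up, dn, lf, rt)) {
      if (length(nb)) {
        inc <- tabulate(nb, L^2) * cfg$alpha
        V <- V + inc
      }
    }
  }
  list(state = list(V = V, t = state$t + cfg$step_ms), spikers = spikers)
}

#' Initial lattice state
#'
#' Potentials start uniform on `[-4, 0)`; the transient discarded by the
#' simulators then lets the lattice self-organize to its stationary state.
#'
#' @param cfg a [soc_config()].
#' @return list with `V` and `t = 0`.
#' @export
soc_init <- function(cfg) {
  list(V = stats::runif(cfg$L^2, -4, 0), t = 0)
}

#' Single step of the stochastic branching network (reference implementation)
#'
#' Each currently active unit draws `k` uniformly random targets (with
#' replacement; self-targets allowed) and each target independently becomes
#' active with probability `alpha / k * (1 - p_diss)`. A unit activated by at
#' least one source is active exactly once next step.
#'
#' @param active integer ids of currently active units.
#' @param cfg a [branching_config()].
#' @return integer ids of units active at the next step.
#' @export
branching_step <- function(active, cfg) {
  if (length(active) == 0L) return(integer(0))
  p_eff <- cfg$alpha / cfg$k * (1 - cfg$p_diss)
  n_draws <- length(active) * cfg$k
  hit <- stats::runif(n_draws) < p_eff
  if (!any(hit)) return(integer(0))
  targets <- sample.int(cfg$n_neurons, sum(hit), replace = TRUE)
  sort(unique(targets))
}

#' Cascade-size distribution of the branching network
#'
#' For a Galton-Watson process with Binomial(k, p) offspring, the total
#' progeny S of one ancestor has `P(S = s) = dbinom(s - 1, k s, p) / s`
#' (Dwass-Otter formula), with `p = alpha / k * (1 - p_diss)`. The mean total
#' size in the subcritical regime is `1 / (1 - alpha (1 - p_diss))`. These
#' closed forms hold exactly in the infinite-network limit and serve as the
#' analytic reference for the simulated cascades.
#'
#' @param s integer vector of cascade sizes (s >= 1).
#' @param alpha branching strength.
#' @param k out-degree.
#' @param p_diss per-target dissipation probability.
#' @return `branching_size_pmf`: P(S = s); `branching_mean_size`: E(S).
#' @export
branching_size_pmf <- function(s, alpha, k = 4, p_diss = 0.001) {
  p <- alpha / k * (1 - p_diss)
  stats::dbinom(s - 1, k * s, p) / s
}

#' @rdname branching_size_pmf
#' @export
branching_mean_size <- function(alpha, p_diss = 0.001) {
  m <- alpha * (1 - p_diss)
  if (m >= 1) return(Inf)
  1 / (1 - m)
}
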