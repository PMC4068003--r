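#' Detrended fluctuation analysis
#'
#' Order-1 DFA of a uniformly sampled series (1 ms resolution for spike-count
#' signals): the mean-subtracted series is cumulatively summed, tiled into
#' non-overlapping windows of width `w` (trailing partial window discarded),
#' a per-window linear trend is removed, and `F(w)` is the root-mean-square
#' residual. The scaling exponent `beta` is the least-squares slope of
#' `log2 F` versus `log2 w`. `beta = 0.5` indicates an uncorrelated series,
#' `beta ~ 1` pink (1/f) noise and `beta ~ 1.5` Brownian noise.
#'
#' @param signal numeric series.
#' @param windows window widths in samples (default `2^(4:11)`, i.e. 16 ms to
#'   about 2 s at 1 ms resolution; larger windows are avoided because the
#'   scaling of spiking signals breaks down beyond ~2 s).
#' @return object of class `dfa_result` with `windows`, `F`, `beta` and the
#'   `lm` fit.
#' @export
dfa <- function(signal, windows = 2^(4:11)) {
  windows <- sort(as.integer(windows))
  n <- length(signal)
  if (n < 4 * max(windows))
    stop("signal shorter than 4x the largest window")
  if (stats::sd(signal) == 0)
    stop("constant signal: fluctuation is zero, beta undefined")
  y <- cumsum(signal - mean(signal))
  F <- vapply(windows, function(w) {
    nseg <- n %/% w
    m <- matrix(y[seq_len(nseg * w)], nrow = w)
    t <- seq_len(w) - (w + 1) / 2           # centered regressor
    stt <- sum(t * t)
    slope <- colSums(m * t) / stt
    resid <- m - rep(colMeans(m), each = w) - outer(t, slope)
    sqrt(mean(resid^2))
  }, numeric(1))
  if (any(F <= 0)) stop("zero fluctuation in some window: beta undefined")
  fit <- stats::lm(log2(F) ~ log2(windows))
  structure(list(windows = windows, F = F,
                 beta = unname(stats::coef(fit)[2]), fit = fit),
            class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("DFA: beta = %.3f over windows %d-%d samples\n",
              x$beta, min(x$windows), max(x$windows)))
  invisible(x)
}

#' @export
plot.dfa_result <- function(x, ...) {
  plot(x$windows, x$F, log = "xy", xlab = "window width [samples]",
       ylab = "F(w)", ...)
  lines(x$windows, 2^stats::predict(x$fit), lty = 2)
  invisible(x)
}

#' @export
coef.dfa_result <- function(object, ...) c(beta = object$beta)
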