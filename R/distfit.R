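#' Hurwitz zeta function
#'
#' `sum((a + j)^-tau, j = 0, 1, ...)` for `tau > 1`, by direct summation plus
#' an Euler-Maclaurin tail. Normalization constant of the discrete power law.
#'
#' @param tau exponent (> 1).
#' @param a offset (> 0).
#' @return the zeta value.
#' @export
hurwitz_zeta <- function(tau, a = 1) {
  stopifnot(tau > 1, a > 0)
  J <- 10000
  j <- 0:(J - 1)
  head <- sum((a + j)^(-tau))
  b <- a + J
  head + b^(1 - tau) / (tau - 1) + 0.5 * b^(-tau) +
    tau / 12 * b^(-tau - 1)
}

# log of G(a) - G(b) for a < b given logG values (both <= 0), stable in the
# far tail where both survival values underflow
.log_diff <- function(log_ga, log_gb) {
  log_ga + log1p(-pmin(exp(log_gb - log_ga), 1 - 1e-16))
}

#' Discrete probability mass of the fitted families
#'
#' All families are defined on the integer support `s >= s_min`. Continuous
#' densities are discretized by the mass on `[s - 0.5, s + 0.5)` and
#' renormalized over the support, so every family is an exactly normalized
#' discrete distribution:
#' * `lognormal`: parameters `mu` (meanlog) and `sigma2` (variance of log s);
#' * `powerlaw`: `p(s) ~ s^-tau`, normalized with the Hurwitz zeta function;
#' * `powerlaw_cutoff`: `p(s) ~ s^-tau exp(-lambda s)`;
#' * `exponential`: `p(s) ~ exp(-lambda s)` (a shifted geometric law);
#' * `stretched_exponential`: survival `exp(-(lambda s)^beta)` discretized by
#'   differencing.
#'
#' @param s integer sizes.
#' @param family family name.
#' @param params named parameter vector as returned by [fit_family()].
#' @param s_min lower support bound.
#' @param log return log-probabilities.
#' @return vector of (log) probabilities; zero (or -Inf) below `s_min`.
#' @export
family_pmf <- function(s, family, params, s_min = 1, log = FALSE) {
  lp <- rep(-Inf, length(s))
  ok <- s >= s_min
  si <- s[ok]
  lp[ok] <- switch(
    family,
    lognormal = {
      mu <- params[["mu"]]; sd <- sqrt(params[["sigma2"]])
      la <- stats::plnorm(si - 0.5, mu, sd, lower.tail = FALSE, log.p = TRUE)
      lb <- stats::plnorm(si + 0.5, mu, sd, lower.tail = FALSE, log.p = TRUE)
      lz <- stats::plnorm(s_min - 0.5, mu, sd, lower.tail = FALSE, log.p = TRUE)
      .log_diff(la, lb) - lz
    },
    powerlaw = {
      tau <- params[["tau"]]
      -tau * base::log(si) - base::log(hurwitz_zeta(tau, s_min))
    },
    powerlaw_cutoff = {
      tau <- params[["tau"]]; lam <- params[["lambda"]]
      -tau * base::log(si) - lam * si -
        base::log(.plc_norm(tau, lam, s_min))
    },
    exponential = {
      lam <- params[["lambda"]]
      # telescoped mass-discretization: shifted geometric
      log1p(-exp(-lam)) - lam * (si - s_min)
    },
    stretched_exponential = {
      lam <- params[["lambda"]]; beta <- params[["beta"]]
      la <- -(lam * (si - 0.5))^beta
      lb <- -(lam * (si + 0.5))^beta
      lz <- -(lam * (s_min - 0.5))^beta
      .log_diff(la, lb) - lz
    },
    stop("unknown family: ", family))
  if (log) lp else exp(lp)
}

# normalization sum for the power law with exponential cutoff: exact partial
# sum plus integral tail
.plc_norm <- function(tau, lam, s_min) {
  S0 <- 100000L
  s <- s_min:S0
  head <- sum(s^(-tau) * exp(-lam * s))
  tail <- tryCatch(
    stats::integrate(function(x) x^(-tau) * exp(-lam * x),
                     S0 + 0.5, Inf, rel.tol = 1e-10)$value,
    error = function(e) 0)
  head + tail
}

.families <- c("lognormal", "powerlaw", "powerlaw_cutoff", "exponential",
               "stretched_exponential")

#' Maximum-likelihood fit of an avalanche-size distribution family
#'
#' Fits one of the discrete families of [family_pmf()] to integer avalanche
#' sizes by maximizing the likelihood over the support `s >= s_min`
#' (observations below `s_min` are dropped). The discrete power law uses the
#' standard zeta-normalized MLE; the exponential (geometric) family has a
#' closed-form MLE; the remaining families are optimized numerically.
#'
#' @param sizes integer avalanche sizes.
#' @param family one of `"lognormal"`, `"powerlaw"`, `"powerlaw_cutoff"`,
#'   `"exponential"`, `"stretched_exponential"`.
#' @param s_min lower bound of the fitted support (default 1, i.e. size-one
#'   avalanches are included).
#' @return object of class `avalanche_fit`: `family`, `params` (named),
#'   `loglik` (total), `loglik_per_datum`, `n`, `s_min`.
#' @export
fit_family <- function(sizes, family = .families, s_min = 1) {
  family <- match.arg(family)
  if (inherits(sizes, "avalanche_set")) sizes <- sizes$sizes
  if (inherits(sizes, "avalanche_records")) sizes <- sizes$size
  s <- as.numeric(sizes[sizes >= s_min])
  n <- length(s)
  if (n < 2) stop("need at least 2 sizes >= s_min")
  if (n < 100) warning("fewer than 100 sizes above s_min; fit is unstable")
  if (length(unique(s)) == 1L)
    stop("degenerate data: all sizes equal, distribution shape unidentifiable")
  tab <- table(s)
  u <- as.numeric(names(tab)); w <- as.numeric(tab)
  nll <- function(params) {
    lp <- family_pmf(u, family, params, s_min, log = TRUE)
    if (any(!is.finite(lp))) return(1e12)
    -sum(w * lp)
  }
  params <- switch(
    family,
    exponential = {
      m <- mean(s) - s_min
      q <- m / (1 + m)
      c(lambda = -base::log(q))
    },
    powerlaw = {
      opt <- stats::optimize(function(tau) nll(c(tau = tau)),
                             c(1 + 1e-6, 20), tol = 1e-8)
      c(tau = opt$minimum)
    },
    lognormal = {
      start <- c(mean(base::log(s)), base::log(max(stats::sd(base::log(s)), 0.05)))
      opt <- stats::optim(start, function(p)
        nll(c(mu = p[1], sigma2 = exp(p[2])^2)), method = "Nelder-Mead",
        control = list(maxit = 2000, reltol = 1e-12))
      c(mu = opt$par[1], sigma2 = exp(opt$par[2])^2)
    },
    powerlaw_cutoff = {
      tau0 <- min(max(1 + n / sum(base::log(s / (s_min - 0.5))), 0.2), 3)
      start <- c(tau0, base::log(1 / mean(s)))
      opt <- stats::optim(start, function(p)
        nll(c(tau = p[1], lambda = exp(p[2]))), method = "L-BFGS-B",
        lower = c(-1, base::log(1e-9)), upper = c(8, base::log(2)),
        control = list(maxit = 500))
      c(tau = opt$par[1], lambda = exp(opt$par[2]))
    },
    stretched_exponential = {
      start <- c(base::log(1 / mean(s)), base::log(0.5))
      opt <- stats::optim(start, function(p)
        nll(c(lambda = exp(p[1]), beta = exp(p[2]))), method = "Nelder-Mead",
        control = list(maxit = 2000, reltol = 1e-12))
      c(lambda = exp(opt$par[1]), beta = exp(opt$par[2]))
    })
  ll <- -nll(params)
  structure(list(family = family, params = params, loglik = ll,
                 loglik_per_datum = ll / n, n = n, s_min = s_min),
            class = "avalanche_fit")
}

#' @export
print.avalanche_fit <- function(x, ...) {
  cat(sprintf("%s fit (s_min = %g, n = %d)\n", x$family, x$s_min, x$n))
  cat("  ", paste(sprintf("%s = %.4g", names(x$params), x$params),
                  collapse = ", "), "\n")
  cat(sprintf("  log-likelihood: %.2f (%.4f per datum)\n",
              x$loglik, x$loglik_per_datum))
  invisible(x)
}

#' @export
logLik.avalanche_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$params), nobs = object$n,
            class = "logLik")
}

#' @export
coef.avalanche_fit <- function(object, ...) object$params

#' Rank candidate families by likelihood
#'
#' Fits each family to the same sizes on the identical support and ranks them
#' by total log-likelihood. For each family the log-likelihood-ratio against
#' the best family is assessed with a Vuong-style normal approximation
#' (`z = mean(d) * sqrt(n) / sd(d)` over the per-observation differences).
#'
#' @param sizes integer avalanche sizes.
#' @param families character vector of family names (at least one).
#' @param s_min lower support bound shared by all fits.
#' @return object of class `family_comparison`: ranked data.frame with
#'   `family`, `loglik`, `loglik_per_datum`, `n_par`, `delta_ll` (vs best),
#'   `vuong_z`, `vuong_p`; fitted objects in `attr(, "fits")`.
#' @export
compare_families <- function(sizes, families = .families, s_min = 1) {
  if (length(families) == 0L) stop("empty family list")
  families <- match.arg(families, .families, several.ok = TRUE)
  if (inherits(sizes, "avalanche_set")) sizes <- sizes$sizes
  if (inherits(sizes, "avalanche_records")) sizes <- sizes$size
  s <- as.numeric(sizes[sizes >= s_min])
  fits <- lapply(families, function(f) fit_family(s, f, s_min))
  names(fits) <- families
  lp <- vapply(fits, function(f)
    family_pmf(s, f$family, f$params, s_min, log = TRUE),
    numeric(length(s)))
  ll <- colSums(lp)
  ord <- order(ll, decreasing = TRUE)
  best <- ord[1]
  z <- p <- rep(NA_real_, length(families))
  for (i in seq_along(families)) {
    if (i == best) next
    d <- lp[, best] - lp[, i]
    if (stats::sd(d) > 0) {
      z[i] <- mean(d) * sqrt(length(s)) / stats::sd(d)
      p[i] <- 2 * stats::pnorm(-abs(z[i]))
    }
  }
  out <- data.frame(family = families, loglik = ll,
                    loglik_per_datum = ll / length(s),
                    n_par = vapply(fits, function(f) length(f$params),
                                   numeric(1)),
                    delta_ll = ll - ll[best], vuong_z = z, vuong_p = p)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  class(out) <- c("family_comparison", "data.frame")
  out
}

#' @export
print.family_comparison <- function(x, ...) {
  cat("family comparison (ranked by log-likelihood):\n")
  print.data.frame(x, digits = 5)
  invisible(x)
}

#' Graphical power-law slope of a size distribution
#'
#' Least-squares slope of the log-binned `f(s)` densities on log-log axes
#' over `fit_range`. This reproduces the figure-style exponent read-off
#' (e.g. `tau ~ 1` for the sandpile lattice, 1.5 for critical branching);
#' for family comparison the likelihood fits of [fit_family()] are
#' authoritative.
#'
#' @param dist a [size_dist()] result, or an already log-binned data.frame
#'   with columns `s` and `density`.
#' @param fit_range numeric `c(lo, hi)`: sizes included in the regression.
#' @param bins_per_decade log-binning density.
#' @return list with `tau` (positive exponent, i.e. minus the slope),
#'   `intercept` (density at s = 1), `r_squared`, `lb` (the binned points)
#'   and the `lm` fit.
#' @export
powerlaw_slope_fit <- function(dist, fit_range = c(1, 300),
                               bins_per_decade = 10) {
  lb <- if (is.data.frame(dist) && "density" %in% names(dist)) dist
        else log_bin(dist, bins_per_decade)
  pts <- lb[lb$s >= fit_range[1] & lb$s <= fit_range[2] & lb$density > 0, ]
  if (nrow(pts) < 3) stop("fewer than 3 log-binned points in fit_range")
  fit <- stats::lm(log10(density) ~ log10(s), data = pts)
  list(tau = -unname(stats::coef(fit)[2]),
       intercept = 10^unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared, lb = lb, fit = fit)
}

#' Finite-size cutoff of a power-law size distribution
#'
#' Fits the power-law slope over `fit_range` and locates the size at which
#' the log-binned density has fallen below the power-law extrapolation by
#' `factor` (default 10x), interpolating between binned support points in
#' log-log coordinates. This is the scale at which the finite system can no
#' longer sustain larger avalanches.
#'
#' @param dist a [size_dist()] result.
#' @param fit_range scaling range used for the slope fit.
#' @param factor departure factor defining the cutoff.
#' @param bins_per_decade log-binning density.
#' @return the cutoff size (NA if the density never departs by `factor`).
#' @export
find_cutoff <- function(dist, fit_range = c(1, 300), factor = 10,
                        bins_per_decade = 10) {
  sf <- powerlaw_slope_fit(dist, fit_range, bins_per_decade)
  lb <- sf$lb[sf$lb$s > fit_range[1], ]
  pred <- sf$intercept * lb$s^(-sf$tau)
  lr <- log10(lb$density / pred)          # 0 on the power law
  thr <- -log10(factor)
  below <- which(lr < thr & lb$s > fit_range[2] / 3)
  if (length(below) == 0L) return(NA_real_)
  i <- below[1]
  if (i == 1L) return(lb$s[1])
  # linear interpolation in (log s, log ratio)
  x1 <- log10(lb$s[i - 1]); x2 <- log10(lb$s[i])
  y1 <- lr[i - 1]; y2 <- lr[i]
  10^(x1 + (thr - y1) * (x2 - x1) / (y2 - y1))
}

#' Samplers for the fitted families
#'
#' `rpowerlaw_discrete` draws from the zeta-normalized discrete power law by
#' inverse CDF (exact up to size 1e5, continuous-tail approximation beyond).
#' `rlnorm_discrete` draws from the mass-discretized lognormal restricted to
#' `s >= s_min` by rejection. Both are used as simulation truths in
#' parameter-recovery checks.
#'
#' @param n number of draws.
#' @param tau,mu,sigma2,lambda family parameters.
#' @param s_min support lower bound.
#' @return integer sizes.
#' @export
rpowerlaw_discrete <- function(n, tau, s_min = 1) {
  S0 <- 100000L
  s <- s_min:S0
  pmf <- s^(-tau) / hurwitz_zeta(tau, s_min)
  cdf <- cumsum(pmf)
  u <- stats::runif(n)
  out <- integer(n)
  inside <- u <= cdf[length(cdf)]
  out[inside] <- s[findInterval(u[inside], cdf) + 1L]
  if (any(!inside)) {
    # continuous Pareto tail beyond S0; kept numeric, extreme tail draws of
    # shallow power laws exceed the integer range
    out <- as.numeric(out)
    v <- stats::runif(sum(!inside))
    out[!inside] <- round((S0 + 0.5) * v^(-1 / (tau - 1)))
  }
  out
}

#' @rdname rpowerlaw_discrete
#' @export
rlnorm_discrete <- function(n, mu, sigma2, s_min = 1) {
  out <- integer(0)
  sd <- sqrt(sigma2)
  while (length(out) < n) {
    x <- stats::rlnorm(2 * n, mu, sd)
    s <- as.integer(floor(x + 0.5))
    out <- c(out, s[s >= s_min])
  }
  out[seq_len(n)]
}
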