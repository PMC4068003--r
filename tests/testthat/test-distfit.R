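# Discrete ML fitting of the candidate size-distribution families.

test_that("discrete power-law MLE recovers the generating exponent", {
  set.seed(60)
  s <- rpowerlaw_discrete(1e5, tau = 1.5)
  fit <- fit_family(s, "powerlaw", s_min = 1)
  expect_lt(abs(fit$params[["tau"]] - 1.5), 0.02)
})

test_that("discretized lognormal parameters are recovered", {
  set.seed(61)
  s <- rlnorm_discrete(3e4, mu = 0.89, sigma2 = 1.2)
  fit <- fit_family(s, "lognormal")
  # ~3 SE at this sample size
  expect_lt(abs(fit$params[["mu"]] - 0.89), 0.05)
  expect_lt(abs(fit$params[["sigma2"]] - 1.2), 0.10)
})

test_that("degenerate and undersized inputs error or warn", {
  expect_error(fit_family(rep(1L, 500), "powerlaw"), "degenerate")
  expect_error(suppressWarnings(fit_family(c(3L, 3L, 3L), "lognormal")),
               "degenerate")
  expect_warning(fit_family(c(1:20), "exponential"), "fewer than 100")
  expect_error(compare_families(1:1000, character(0)), "empty")
})

test_that("all fitted densities are normalized over the discrete support", {
  cases <- list(
    list(family = "lognormal", params = c(mu = 0.89, sigma2 = 1.2)),
    list(family = "powerlaw", params = c(tau = 1.5)),
    list(family = "powerlaw_cutoff", params = c(tau = 1.0, lambda = 1e-3)),
    list(family = "exponential", params = c(lambda = 0.3)),
    list(family = "stretched_exponential",
         params = c(lambda = 0.2, beta = 0.6)))
  for (cs in cases) {
    s <- 1:100000
    total <- sum(family_pmf(s, cs$family, cs$params, s_min = 1))
    if (cs$family == "powerlaw") {
      # analytic tail beyond the summed support
      total <- total + hurwitz_zeta(1.5, 100001) / hurwitz_zeta(1.5, 1)
    }
    # every other family's tail beyond 1e5 is below 1e-40 at these parameters
    expect_lt(abs(total - 1), 1e-6)
  }
})

test_that("fits are local likelihood maxima", {
  set.seed(62)
  s <- rlnorm_discrete(5000, 1.0, 1.0)
  ll_of <- function(family, params)
    sum(family_pmf(s, family, params, 1, log = TRUE))
  for (family in c("lognormal", "powerlaw", "exponential")) {
    fit <- fit_family(s, family)
    for (i in seq_along(fit$params)) for (eps in c(-0.02, 0.02)) {
      p <- fit$params
      p[i] <- p[i] * (1 + eps)
      expect_lte(ll_of(family, p), fit$loglik + 1e-6)
    }
  }
})

test_that("family comparison ranks the generating family first", {
  set.seed(63)
  s <- rlnorm_discrete(2e4, 0.89, 1.2)
  cmp <- compare_families(s, c("lognormal", "powerlaw", "exponential",
                               "powerlaw_cutoff"))
  expect_equal(cmp$family[1], "lognormal")
  expect_true(all(cmp$delta_ll <= 0))
  # pure power-law data: the cutoff family gains at most a parameter's worth
  s2 <- rpowerlaw_discrete(2e4, 1.8)
  cmp2 <- compare_families(s2, c("powerlaw", "powerlaw_cutoff"))
  expect_lt(abs(cmp2$loglik[1] - cmp2$loglik[2]), 2 + 1e-6)
})

test_that("graphical slope fit reads an exact power law exactly", {
  s <- 1:5000
  counts <- 1e8 * s^(-1.5)
  d <- structure(data.frame(s = s, count = counts, p = counts / sum(counts)),
                 class = c("size_distribution", "data.frame"))
  sf <- powerlaw_slope_fit(d, fit_range = c(10, 1000))
  expect_lt(abs(sf$tau - 1.5), 0.02)
  expect_gt(sf$r_squared, 0.999)
})

test_that("the cutoff locator finds the 10x departure of a truncated power law", {
  s <- 1:20000
  lambda <- 1 / 500
  counts <- round(1e8 * s^(-1.5) * exp(-lambda * s))
  d <- structure(data.frame(s = s, count = counts, p = counts / sum(counts)),
                 class = c("size_distribution", "data.frame"))
  cut <- find_cutoff(d, fit_range = c(1, 100), factor = 10)
  # departure at e^(-lambda s) = 1/10, i.e. s ~ ln(10)/lambda ~ 1150, up to
  # the slope absorbed into the fit
  expect_gt(cut, 1151 / 2)
  expect_lt(cut, 1151 * 2)
})
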