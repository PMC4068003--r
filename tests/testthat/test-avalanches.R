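# Binning, avalanche extraction and the bin-size statistics, including the
# closed-form Poisson oracles.

test_that("binning uses half-open bins and drops the trailing partial bin", {
  bc <- bin_spikes(c(0.2, 0.7, 3.1), bs = 1, duration = 4)
  expect_equal(bc$counts, c(2, 0, 0, 1))
  bc2 <- bin_spikes(c(0.2, 0.7, 3.1), bs = 1, duration = 4.7)
  expect_equal(bc2$counts, c(2, 0, 0, 1))   # partial 5th bin dropped
  expect_error(bin_spikes(numeric(0), 1, duration = 10), "empty")
  ras <- make_poisson_raster(5, 2, 1000, seed = 40)
  expect_error(bin_spikes(ras, 2000), "exceeds")
})

test_that("avalanches are maximal runs of non-empty bins", {
  bc <- structure(list(counts = c(2, 1, 0, 3, 1, 0, 0, 1), bs = 1,
                       n_bins = 8L), class = "binned_counts")
  av <- extract_avalanches(bc)
  expect_equal(av$sizes, c(3L, 4L, 1L))
  expect_equal(av$durations, c(2L, 2L, 1L))
  expect_equal(av$boundary, c(TRUE, FALSE, TRUE))
  expect_equal(mean_size(av), 8 / 3)
  # all bins occupied: a single avalanche of the total count
  bc2 <- structure(list(counts = c(2, 5, 1), bs = 1, n_bins = 3L),
                   class = "binned_counts")
  expect_equal(extract_avalanches(bc2)$sizes, 8L)
})

test_that("sigma* follows the bin-ratio definition with zeros counted", {
  bc <- structure(list(counts = c(2, 4, 0, 1, 1), bs = 1, n_bins = 5L),
                  class = "binned_counts")
  est <- estimate_sigma(bc)
  expect_equal(est$sigma, 1)        # ratios {2, 0, nd, 1}
  expect_equal(est$n_defined, 3L)
  bc2 <- structure(list(counts = rep(3, 10), bs = 1, n_bins = 10L),
                   class = "binned_counts")
  expect_equal(estimate_sigma(bc2)$sigma, 1)
  bc3 <- structure(list(counts = c(0, 0, 0), bs = 1, n_bins = 3L),
                   class = "binned_counts")
  expect_error(estimate_sigma(bc3), "no defined ratios")
})

test_that("mean IEI is the inverse population rate", {
  ras <- spike_raster(c(1, 3, 5, 7, 9), rep(1L, 5), 1, 10)
  expect_equal(mean_iei(ras), 2)
  expect_equal(population_rate(ras), 500)
})

test_that("Poisson rasters match the closed-form oracles for the bin statistics", {
  ras <- poisson_fixture()
  R <- population_rate(ras) / 1000          # spikes per ms
  for (bs in c(1, 2, 4)) {
    lam <- R * bs
    bc <- bin_spikes(ras, bs)
    # void probability
    expect_lt(abs(mean(bc$counts == 0) - exp(-lam)),
              4 * sqrt(exp(-lam) / bc$n_bins) + 1e-3)
    av <- extract_avalanches(bc)
    # mean size
    se_s <- stats::sd(av$sizes) / sqrt(av$n_avalanches)
    expect_lt(abs(mean_size(av) - poisson_mean_size(lam)), 4 * se_s + 0.01)
    # rate of size-1 avalanches per unit time ~ R exp(-3 lambda)
    f1_rate <- sum(av$sizes == 1) / (bc$n_bins * bs)
    expect_lt(abs(f1_rate - R * exp(-3 * lam)),
              4 * sqrt(sum(av$sizes == 1) + 1) / (bc$n_bins * bs))
    # sigma* from independent bins
    est <- estimate_sigma(bc, keep_ratios = TRUE)
    se_sig <- stats::sd(est$ratios) / sqrt(est$n_defined)
    expect_lt(abs(est$sigma - poisson_sigma(lam)), 4 * se_sig + 0.005)
  }
})

test_that("avalanche sizes partition the spikes and merge monotonically in bs", {
  for (ras in list(poisson_fixture(), sts_soc_raster_fixture())) {
    prev_n <- Inf
    for (bs in 2^(0:7)) {
      bc <- bin_spikes(ras, bs)
      av <- extract_avalanches(bc)
      expect_equal(sum(av$sizes), sum(bc$counts))
      expect_lte(av$n_avalanches, prev_n)
      prev_n <- av$n_avalanches
    }
  }
})

test_that("f1 curves are normalized at one <IEI> and decay for Poisson input", {
  ras <- poisson_fixture()
  fc <- f1_curve(ras, bs_iei = 2^(-1:3))
  expect_equal(fc$f1_norm[abs(fc$bs_iei - 1) < 1e-9], 1)
  expect_true(all(diff(fc$f1) <= 0))
  # exponential decay: log f1 is linear in bs with slope ~ -3R
  R <- population_rate(ras) / 1000
  keep <- fc$f1 > 50
  fit <- stats::lm(log(fc$f1[keep]) ~ fc$bs[keep])
  expect_lt(abs(-stats::coef(fit)[2] / (3 * R) - 1), 0.1)
})

test_that("log binning preserves an exact power law", {
  s <- 1:3000
  counts <- 1e7 * s^(-2.0)
  d <- structure(data.frame(s = s, count = counts, p = counts / sum(counts)),
                 class = c("size_distribution", "data.frame"))
  lb <- log_bin(d, bins_per_decade = 8)
  # below s ~ 10 a log bin holds a single integer size and the geometric-mean
  # support point is off the line by discreteness, so fit above it
  fit <- stats::lm(log10(density) ~ log10(s),
                   data = lb[lb$s > 10 & lb$s < 1000, ])
  expect_lt(abs(-stats::coef(fit)[2] - 2), 0.03)
  expect_gt(summary(fit)$r.squared, 0.999)
  # a single size occupies exactly one bin
  d1 <- size_dist(rep(7L, 12))
  lb1 <- log_bin(d1)
  expect_equal(sum(lb1$count), 12)
  expect_equal(nrow(lb1), 1L)
  expect_error(size_dist(integer(0)), "no sizes")
})

test_that("boundary avalanches barely affect statistics on long records", {
  ras <- poisson_fixture()
  bc <- bin_spikes(ras, 4)
  av <- extract_avalanches(bc)
  expect_lt(abs(mean_size(av) - mean_size(av, boundary = FALSE)) /
              mean_size(av), 0.01)
})
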