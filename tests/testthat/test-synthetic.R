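# Surrogate generators: rates, reproducibility, and self-consistency of the
# lognormal-avalanche raster.

test_that("poisson rasters hit their population rate", {
  ras <- make_poisson_raster(100, 3.2, 3e5, seed = 80)
  expect_lt(abs(population_rate(ras) - 320) / 320, 0.05)
  expect_warning(make_poisson_raster(10, 0, 1000), "empty")
  a <- make_poisson_raster(20, 5, 1e4, seed = 81)
  b <- make_poisson_raster(20, 5, 1e4, seed = 81)
  expect_identical(a$times, b$times)
})

test_that("the in-vivo-like raster reproduces its target rate and sizes", {
  ras <- make_invivo_like_raster(n_units = 100, target_R = 320,
                                 duration_ms = 6e5, seed = 82)
  expect_lt(abs(population_rate(ras) - 320) / 320, 0.05)
  # avalanche extraction at the construction bin recovers the sizes exactly
  av <- extract_avalanches(bin_spikes(ras, ras$meta$bin_ms))
  expect_equal(sort(av$sizes), sort(ras$meta$sizes))
  # and the lognormal fit recovers the generating parameters
  fit <- fit_family(av$sizes, "lognormal")
  expect_lt(abs(fit$params[["mu"]] - 0.89), 0.06)
  expect_lt(abs(fit$params[["sigma2"]] - 1.2), 0.12)
  # f(s) is monotonically decreasing from s = 1 (mode below 1)
  d <- size_dist(av$sizes)
  expect_gt(d$count[d$s == 1], d$count[d$s == 2])
  expect_gt(d$count[d$s == 2], d$count[d$s == 3])
})

test_that("fractional noise is reproducible and standardized", {
  x <- make_fractional_noise(0.8, 4096, seed = 83)
  y <- make_fractional_noise(0.8, 4096, seed = 83)
  expect_identical(x, y)
  expect_lt(abs(mean(x)), 1e-10)
  expect_equal(stats::sd(x), 1, tolerance = 1e-10)
})

test_that("lfp surrogates have the advertised shape and reproduce", {
  tr <- make_lfp_surrogate(n_channels = 3, duration_s = 10, seed = 84)
  expect_equal(dim(tr$samples), c(4000, 3))
  tr2 <- make_lfp_surrogate(n_channels = 3, duration_s = 10, seed = 84)
  expect_identical(tr$samples, tr2$samples)
  # a pure sinusoid channel yields the analytic lobe area
  fs <- 400
  t <- seq_len(10 * fs) / fs
  lobes <- positive_lobe_areas(2 * sin(2 * pi * 1.5 * t), fs)
  interior <- lobes[lobes$t_start > 0.5 & lobes$t_end < 9.5, ]
  expect_true(all(abs(interior$area - 2 / (pi * 1.5)) < 0.01))
})

test_that("raster text round-trip is lossless including metadata", {
  ras <- make_poisson_raster(10, 5, 5000, seed = 85)
  path <- tempfile(fileext = ".txt")
  write_raster(ras, path)
  back <- read_raster(path)
  expect_equal(back$times, ras$times, tolerance = 1e-9)
  expect_identical(back$units, ras$units)
  expect_equal(back$n_units, ras$n_units)
  expect_equal(back$duration, ras$duration)
  expect_equal(back$meta$rate, 5)
  # rasters with origin flags keep them
  cfg <- soc_config(alpha = 0.5, drive_rate = 2, mode = "driven",
                    transient = 1000)
  dr <- run_driven(cfg, 5000, seed = 86)
  write_raster(dr, path)
  back2 <- read_raster(path)
  expect_identical(back2$is_input, dr$is_input)
  unlink(path)
})
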