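# Shared simulated fixtures, built once per test run and cached. The driven
# critical raster is the expensive one (drive calibration + a long run); the
# cache keeps the whole suite inside a sane runtime.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# driven SOC lattice at the critical coupling, drive calibrated to ~5 Hz per
# unit; full sampling, 3e5 ms
driven_soc_fixture <- function() {
  fixture("driven_soc", function() {
    h <- calibrate_drive(soc_config(alpha = 1, drive_rate = 1e-3,
                                    mode = "driven"),
                         target_rate = 5, seed = 401,
                         est_duration_ms = 1e5, transient_ms = 5e4)
    run_driven(soc_config(alpha = 1, drive_rate = as.numeric(h),
                          mode = "driven"),
               duration_ms = 3e5, seed = 402)
  })
}

# separated avalanches from the critical lattice, as records and as a raster
sts_soc_fixture <- function() {
  fixture("sts_soc", function()
    run_sts(soc_config(alpha = 1), n_avalanches = 3e4, seed = 403))
}

sts_soc_raster_fixture <- function() {
  fixture("sts_soc_raster", function() {
    set.seed(404)
    sts_raster(sts_soc_fixture(), soc_config(alpha = 1))
  })
}

# acceptance-scale driven critical raster: calibrated drive, 1e6 ms
driven_soc_acc_fixture <- function() {
  fixture("driven_soc_acc", function() {
    h <- calibrate_drive(soc_config(alpha = 1, drive_rate = 1e-3,
                                    mode = "driven"),
                         target_rate = 5, seed = 411)
    run_driven(soc_config(alpha = 1, drive_rate = as.numeric(h),
                          mode = "driven"),
               duration_ms = 1e6, seed = 412)
  })
}

poisson_fixture <- function() {
  fixture("poisson", function()
    make_poisson_raster(n_units = 50, rate = 10, duration_ms = 2e5,
                        seed = 405))
}

# closed-form Poisson oracles for the bin statistics: counts in disjoint bins
# are iid Poisson(lambda), lambda = R * bs
poisson_mean_size <- function(lambda) {
  p0 <- exp(-lambda)
  lambda / (p0 * (1 - p0))
}

poisson_sigma <- function(lambda, kmax = 200) {
  k <- 1:kmax
  lambda * sum(stats::dpois(k, lambda) / k) / (1 - exp(-lambda))
}
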