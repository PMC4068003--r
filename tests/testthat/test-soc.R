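# The lattice update rule, its conservation properties, and the driven mode.

test_that("subthreshold states are fixed points of the update", {
  cfg <- soc_config(L = 5, alpha = 1)
  st <- list(V = rep(-1, 25), t = 0)
  out <- soc_step(st, cfg)
  expect_identical(out$spikers, integer(0))
  expect_equal(out$state$V, st$V)
  expect_equal(out$state$t, 1)
})

test_that("a single spiker drops by 4 and feeds each neighbour alpha", {
  cfg <- soc_config(L = 5, alpha = 1)
  V <- rep(-3, 25)
  center <- 13L                       # row 3, col 3 on the 5x5 lattice
  V[center] <- 0.5
  out <- soc_step(list(V = V, t = 0), cfg)
  expect_equal(out$spikers, center)
  expect_equal(out$state$V[center], 0.5 - 4)
  nbs <- c(center - 5L, center + 5L, center - 1L, center + 1L)
  expect_equal(out$state$V[nbs], rep(-2, 4))
  # no second-generation spikes
  out2 <- soc_step(out$state, cfg)
  expect_identical(out2$spikers, integer(0))
})

test_that("a forced center on a uniform 3x3 lattice topples as hand-executed", {
  # all V = -0.5, alpha = 1, center forced: generations are
  # {center}, {4 edge units}, {center again + 4 corners}, then extinction
  cfg <- soc_config(L = 3, alpha = 1)
  st <- list(V = rep(-0.5, 9), t = 0)
  out <- soc_step(st, cfg, forced_units = 5L)
  sizes <- length(out$spikers)
  expect_equal(out$spikers, 5L)
  repeat {
    out <- soc_step(out$state, cfg)
    if (length(out$spikers) == 0) break
    sizes <- c(sizes, length(out$spikers))
  }
  expect_equal(sizes, c(1L, 4L, 5L))
  expect_true(all(out$state$V <= 0))
})

test_that("open-boundary charge bookkeeping: loss is 4(1-alpha) per interior spike", {
  for (alpha in c(0.5, 0.9, 1)) {
    cfg <- soc_config(L = 5, alpha = alpha)
    V <- stats::runif(25, -4, 0)
    center <- 13L
    V[center] <- 0.25
    out <- soc_step(list(V = V, t = 0), cfg)
    expect_equal(sum(V) - sum(out$state$V), 4 * (1 - alpha))
    # corner spike: only 2 neighbours exist, 4 - 2 alpha is dissipated
    V2 <- stats::runif(25, -4, 0)
    V2[1L] <- 0.25
    out2 <- soc_step(list(V = V2, t = 0), cfg)
    expect_equal(sum(V2) - sum(out2$state$V), 4 - 2 * alpha)
  }
})

test_that("STS avalanches partition all spikes and sizes are >= 1", {
  rec <- run_sts(soc_config(L = 20, alpha = 1), 2000, seed = 7)
  expect_true(all(rec$size >= 1))
  expect_true(all(rec$duration >= 1))
  expect_false(any(rec$capped))
})

test_that("driven lattice at alpha = 0 is Poisson with r = h", {
  cfg <- soc_config(alpha = 0, drive_rate = 5, mode = "driven")
  ras <- run_driven(cfg, 1e5, seed = 8)
  r <- population_rate(ras) / ras$n_units
  expect_lt(abs(r - 5) / 5, 0.05)
  # with no coupling every spike is an input spike
  expect_true(all(ras$is_input))
  # per-unit inter-spike intervals are exponential: CV ~ 1 (per-unit rates
  # are low enough that the 1 ms step quantization is negligible)
  isi <- unlist(lapply(split(ras$times, ras$units), diff))
  expect_lt(abs(stats::sd(isi) / mean(isi) - 1), 0.02)
  # counts in disjoint windows have Fano factor ~ 1
  cnt <- population_signal(ras, step_ms = 10)
  expect_lt(abs(stats::var(cnt) / mean(cnt) - 1), 0.06)
})

test_that("input-spike bookkeeping matches the drive rate", {
  cfg <- soc_config(alpha = 0.9, drive_rate = 2, mode = "driven")
  ras <- run_driven(cfg, 1e5, seed = 9)
  n_in <- sum(ras$is_input)
  expected <- 2 * ras$n_units * (ras$duration / 1000) / 1000 * 1000
  expect_lt(abs(n_in - expected) / expected, 3 / sqrt(expected) + 0.01)
  # propagated spikes exist at alpha > 0
  expect_gt(sum(!ras$is_input), 0)
})

test_that("fixed seeds give bit-identical runs", {
  cfg <- soc_config(alpha = 1, drive_rate = 0.05, mode = "driven",
                    transient = 1e4)
  a <- run_driven(cfg, 2e4, seed = 10)
  b <- run_driven(cfg, 2e4, seed = 10)
  expect_identical(a$times, b$times)
  expect_identical(a$units, b$units)
  expect_identical(a$is_input, b$is_input)
  r1 <- run_sts(soc_config(alpha = 1), 500, seed = 11)
  r2 <- run_sts(soc_config(alpha = 1), 500, seed = 11)
  expect_identical(r1$size, r2$size)
})

test_that("calibrate_drive hits the target and h decreases with alpha", {
  expect_equal(as.numeric(calibrate_drive(
    soc_config(alpha = 0, drive_rate = 1, mode = "driven"), 5)), 5)
  hs <- vapply(c(0, 0.5, 0.9, 0.99), function(a) {
    as.numeric(calibrate_drive(
      soc_config(alpha = a, drive_rate = 1e-3, mode = "driven"),
      target_rate = 5, seed = 12,
      est_duration_ms = 6e4, transient_ms = 4e4))
  }, numeric(1))
  expect_true(all(diff(hs) < 0))
})
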