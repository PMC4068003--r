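# Event extraction from continuous traces: filter response, lobe areas,
# rate-matched thresholding and composition with the avalanche path.

test_that("the low-pass filter passes 5 Hz, kills 100 Hz and keeps DC", {
  fs <- 400
  t <- seq(0, 10, by = 1 / fs)[-1]
  tr <- continuous_trace(cbind(sin(2 * pi * 5 * t),
                               sin(2 * pi * 100 * t),
                               rep(2, length(t))), fs)
  out <- lfp_lowpass(tr)
  mid <- seq(1000, length(t) - 1000)      # avoid filter edge transients
  a5 <- max(abs(out$samples[mid, 1]))
  a100 <- max(abs(out$samples[mid, 2]))
  expect_lt(abs(a5 - 1), 0.01)
  expect_lt(a100, 10^(-40 / 20))          # > 40 dB down
  expect_lt(max(abs(out$samples[mid, 3] - 2)), 1e-6)
})

test_that("positive lobe areas match the analytic sinusoid integral", {
  fs <- 400; f <- 2; A <- 3
  t <- seq(0, 5, by = 1 / fs)[-1]
  lobes <- positive_lobe_areas(A * sin(2 * pi * f * t), fs)
  interior <- lobes[lobes$t_start > 0.1 & lobes$t_end < 4.9, ]
  expect_true(all(abs(interior$area - A / (pi * f)) / (A / (pi * f)) < 0.01))
  # strictly negative trace: no lobes
  expect_equal(nrow(positive_lobe_areas(rep(-1, 100) + 0.1 *
                                          sin(seq_len(100)), fs)), 0)
  # single-sample blip of height A between -A neighbours: two half-triangles
  x <- rep(-1, 101); x[51] <- 1
  lb <- positive_lobe_areas(x, fs)
  expect_equal(nrow(lb), 1)
  expect_equal(lb$area, 1 / fs / 2, tolerance = 1e-9)
})

test_that("rate matching keeps the top-k lobes with deterministic ties", {
  lobes <- data.frame(t_start = 1:10, t_end = 1:10 + 0.5,
                      t_peak = 1:10 + 0.2, area = c(5, 9, 1, 7, 3, 8, 2, 6, 4, 10))
  ev <- threshold_to_rate(lobes, duration_s = 20, target_rate = 0.25)
  expect_length(ev$times, 5)
  expect_equal(ev$threshold, sort(lobes$area, decreasing = TRUE)[5])
  expect_equal(ev$rate, 0.25)
  # all areas equal: earliest lobes win
  lob2 <- data.frame(t_start = 1:10, t_end = 1:10, t_peak = 1:10,
                     area = rep(1, 10))
  ev2 <- threshold_to_rate(lob2, 20, 0.25)
  expect_equal(ev2$times, (1:5) * 1000)
  expect_error(threshold_to_rate(lob2[1:3, ], 20, 0.25), "lobes")
})

test_that("the surrogate-to-avalanche path achieves the target rate and <IEI>", {
  tr <- make_lfp_surrogate(n_channels = 50, duration_s = 60, seed = 70)
  ras <- lfp_events(tr, target_rate = 0.25)
  expect_equal(ras$n_units, 50L)
  # per-channel rate is exact by construction (floor(0.25 * 60) events)
  expect_equal(unname(table(ras$units))[1], 15L)
  expect_lt(abs(mean_iei(ras) - 80), 1)    # pooled <IEI> ~ 80 ms
  # events feed the avalanche machinery unchanged
  av <- extract_avalanches(bin_spikes(ras, mean_iei(ras)))
  expect_equal(sum(av$sizes), length(ras$times))
  expect_gt(av$n_avalanches, 10)
})

test_that("a silent trace produces no events", {
  tr <- continuous_trace(matrix(0, 16000, 2), 400)   # 40 s of silence
  expect_error(lfp_events(tr, cutoff = NA), "lobes")
})
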