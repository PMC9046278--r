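make_sine_ts <- function(freq, dur = 4, rate = 250, amp = 1) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  timeseries(t, matrix(amp * sin(2 * pi * freq * t), ncol = 1))
}

test_that("band power tracks the analytic envelope of in-band tones", {
  p <- mu_band_power(make_sine_ts(10))
  interior <- p$values[126:875, 1]   # exclude 0.5 s at each edge
  expect_true(all(abs(interior - 1) < 0.06))
  expect_true(all(p$values >= 0))

  p40 <- mu_band_power(make_sine_ts(40))
  expect_lt(max(p40$values[126:875, 1]), 0.01)

  z <- mu_band_power(timeseries(seq(0, 1, by = 0.004),
                                matrix(0, 251, 2)))
  expect_true(all(z$values == 0))
  expect_error(mu_band_power(make_sine_ts(10, rate = 20)), "Nyquist")
})

test_that("power inversion maps dips to peaks in both modes", {
  t <- seq(0, 3, by = 0.01)
  pow <- timeseries(t, matrix(1 - 0.8 * exp(-(t - 1.5)^2 / 0.05), ncol = 1))
  for (mode in c("reciprocal", "negate")) {
    inv <- invert_power(pow, mode = mode)
    expect_equal(which.max(inv$values[, 1]), which.min(pow$values[, 1]))
  }
  const <- invert_power(timeseries(t, matrix(2, length(t), 1)),
                        epsilon = 1e-8)
  expect_equal(unname(const$values[1, 1]), 1 / (2 + 1e-8))
  # involution on strictly positive input
  x <- timeseries(t, matrix(runif(length(t), 0.5, 2), ncol = 1))
  back <- invert_power(invert_power(x, epsilon = 1e-300),
                       epsilon = 1e-300)
  expect_equal(back$values, x$values, tolerance = 1e-12)
  expect_error(invert_power(pow, epsilon = 0), "positive")
})

test_that("gamma HRF peaks at (shape-1)*scale with unit area", {
  k <- gamma_hrf(6, 1, 30, 100)
  expect_equal(k$peak_time, 5)
  expect_equal((which.max(k$kernel) - 1) / 100, 5, tolerance = 0.011)
  expect_equal(sum(k$kernel) / 100, 1, tolerance = 1e-6)
  # doubling the rate leaves peak time and area unchanged
  k2 <- gamma_hrf(6, 1, 30, 200)
  expect_equal((which.max(k2$kernel) - 1) / 200, 5, tolerance = 0.006)
  expect_equal(sum(k2$kernel) / 200, 1, tolerance = 1e-6)
  expect_warning(gamma_hrf(6, 2, duration = 5), "truncates")
  expect_error(gamma_hrf(0.5, 1), "shape")
})

test_that("HRF convolution is causal, linear and step-convergent", {
  rate <- 10
  k <- gamma_hrf(rate = rate)
  n <- 600
  t <- seq(0, (n - 1) / rate, by = 1 / rate)
  zero <- convolve_hrf(timeseries(t, matrix(0, n, 1)), k)
  expect_true(all(zero$values == 0))

  imp <- matrix(0, n, 1); imp[51] <- rate   # discrete unit impulse
  y <- convolve_hrf(timeseries(t, imp), k)
  expect_equal(y$values[51:350, 1], k$kernel, tolerance = 1e-8)

  step <- convolve_hrf(timeseries(t, matrix(1, n, 1)), k)
  expect_equal(unname(step$values[n, 1]), 1, tolerance = 1e-6)

  set.seed(3)
  a <- matrix(rnorm(n), n, 1); b <- matrix(rnorm(n), n, 1)
  lin <- convolve_hrf(timeseries(t, 2 * a + 3 * b), k)
  parts <- 2 * convolve_hrf(timeseries(t, a), k)$values +
    3 * convolve_hrf(timeseries(t, b), k)$values
  expect_equal(lin$values, parts, tolerance = 1e-9)

  expect_error(convolve_hrf(timeseries(t, imp), gamma_hrf(rate = 20)),
               "rates differ")
})

test_that("epoching follows the half-open convention exactly", {
  ts1k <- timeseries(seq(0, 10 - 1e-3, by = 1e-3), matrix(0, 10000, 1))
  ep <- epoch_around_markers(ts1k, 5, -1.5, 1.5)
  expect_length(ep, 1)
  expect_equal(nrow(ep[[1]]$values), 3000)

  ts10 <- timeseries(seq(0, 40 - 0.1, by = 0.1), matrix(0, 400, 2))
  ep2 <- epoch_around_markers(ts10, 6, -5, 25)
  expect_equal(dim(ep2[[1]]$values), c(300L, 2L))

  expect_warning(out <- epoch_around_markers(ts10, c(6, 39), -5, 25),
                 "skipped")
  expect_length(out, 1)
  expect_equal(attr(out, "skipped"), 39)
  expect_warning(epoch_around_markers(ts10, 6, 0, 0), "zero-length")
})

test_that("trial averaging reduces noise like one over root n", {
  sig <- sin(2 * pi * seq(0, 1, length.out = 200))
  set.seed(4)
  epochs <- lapply(1:15, function(i) {
    epoched_signal(matrix(sig + rnorm(200, sd = 1), ncol = 1), 200, 0, 1)
  })
  avg <- average_trials(epochs)
  resid_sd <- sd(avg$values[, 1] - sig)
  expect_gt(resid_sd, (1 / sqrt(15)) * 0.7)
  expect_lt(resid_sd, (1 / sqrt(15)) * 1.3)

  one <- average_trials(epochs[1])
  expect_identical(one$values, epochs[[1]]$values)
  v <- epochs[[1]]
  neg <- epoched_signal(-v$values, 200, 0, 1)
  expect_true(all(average_trials(list(v, neg))$values == 0))
})

test_that("baseline correction subtracts the pre-marker mean", {
  e <- epoched_signal(matrix(1:30 + 100, ncol = 1), 1, -10, 20)
  out <- average_trials(list(e), baseline = c(-10, 0))
  expect_equal(mean(out$values[1:10, 1]), 0, tolerance = 1e-12)
})

test_that("Fourier resampling preserves band-limited content", {
  t <- seq(0, 3 - 1e-3, by = 1e-3)
  e <- epoched_signal(matrix(sin(2 * pi * 10 * t), ncol = 1), 1000, 0, 3)
  r <- resample_to(e, 300)
  expect_equal(nrow(r$values), 300)
  expect_equal(r$rate, 100)
  ref <- sin(2 * pi * 10 * seq(0, 3 - 0.01, by = 0.01))
  expect_gte(cor(r$values[, 1], ref), 0.999)

  same <- resample_to(e, 3000)
  expect_equal(same$values, e$values, tolerance = 1e-9)
  expect_error(resample_to(e, 3000 * 101), "100x")
})

test_that("fusion matrices assemble with aligned shapes and labels", {
  g <- gen_modalities(n_trials = 4, seed = 6)
  fused <- assemble_fusion_matrices(g$eeg, g$eeg_markers, g$fnirs,
                                    g$fnirs_markers, g$roi_map)
  expect_equal(dim(fused$E$values), c(300L, 2L))
  expect_equal(dim(fused$N$values), c(300L, 2L))
  expect_identical(fused$E$set_id, "EEG")
  expect_identical(fused$N$set_id, "fNIRS")
  expect_identical(fused$E$feature_labels, g$eeg$channel_labels)
  expect_identical(fused$N$feature_labels, unique(g$roi_map$roi))

  # all channels in one ROI: the ROI trace is the channel mean
  one_roi <- data.frame(channel = g$fnirs$channel_labels, roi = "ALL")
  f2 <- assemble_fusion_matrices(g$eeg, g$eeg_markers, g$fnirs,
                                 g$fnirs_markers, one_roi)
  ep <- epoch_around_markers(g$fnirs, g$fnirs_markers, -5, 25)
  avg <- average_trials(ep, baseline = c(-5, 0))
  expect_equal(unname(f2$N$values[, 1]), unname(rowMeans(avg$values)),
               tolerance = 1e-10)
})

test_that("time series, marker and ROI files round-trip", {
  g <- gen_modalities(n_trials = 2, seed = 7)
  f <- tempfile(fileext = ".tsv")
  write_timeseries(g$fnirs, f)
  ts2 <- read_timeseries(f)
  expect_equal(ts2$values, g$fnirs$values, tolerance = 1e-6)
  expect_equal(ts2$rate, g$fnirs$rate, tolerance = 1e-6)

  fm <- tempfile(fileext = ".tsv")
  write_markers(g$eeg_markers, fm)
  mk <- read_markers(fm)
  expect_equal(mk$time, g$eeg_markers$time)
})
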