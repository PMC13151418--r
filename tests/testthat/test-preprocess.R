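make_scan <- function(intensity, fs = 10, layout = NULL, design = NULL) {
  n_ch <- dim(intensity)[2]
  if (is.null(layout)) layout <- probe_layout(roi_only = TRUE)
  structure(list(intensity = intensity,
                 time = seq(0, by = 1 / fs, length.out = dim(intensity)[1]),
                 sampling_rate = fs, wavelengths = c(695, 830),
                 layout = layout, design = design,
                 participant_id = "sub-01", seed = 1L),
            class = "nirs_scan")
}

test_that("channel pruning applies the SNR rule with the boundary retained", {
  fs <- 10
  t <- seq(0, 19.9, by = 1 / fs)       # whole periods of a 0.5 Hz tone
  n <- length(t)
  arr <- array(1, dim = c(n, 3, 2))
  arr[, 2, 1] <- 1 + 0.6 * sin(2 * pi * 0.5 * t)   # SNR ~ 2.36 -> retained
  arr[, 3, 1] <- 1 + 0.8 * sin(2 * pi * 0.5 * t)   # SNR ~ 1.77 -> pruned
  scan <- make_scan(arr)
  keep <- prune_channels(scan, preprocess_params())
  snr2 <- mean(arr[, 2, 1]) / sd(arr[, 2, 1])
  snr3 <- mean(arr[, 3, 1]) / sd(arr[, 3, 1])
  expect_gt(snr2, 2); expect_lt(snr3, 2)
  expect_true(keep[1])    # constant trace: sd = 0, SNR +Inf
  expect_true(keep[2])
  expect_false(keep[3])
  # a channel whose SNR equals the threshold exactly is retained
  keep_boundary <- prune_channels(scan, preprocess_params(snr_thresh = snr2))
  expect_true(keep_boundary[2])
  keep_above <- prune_channels(scan,
                               preprocess_params(snr_thresh = snr2 * (1 + 1e-12)))
  expect_false(keep_above[2])
  expect_warning(
    prune_channels(make_scan(array(c(-1, rep(1, 2 * n * 4 - 1)),
                                   c(n, 4, 2))), preprocess_params()),
    "non-positive")
})

test_that("band-pass filter passes 0.03 Hz, rejects 0.5 Hz, zero maps to zero", {
  fs <- 10
  t <- seq(0, 2000, by = 1 / fs)
  gain <- function(f) {
    y <- bandpass_filter(sin(2 * pi * f * t), preprocess_params(), fs)
    core <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
    max(abs(y[core]))
  }
  expect_gte(gain(0.03), 0.9)
  expect_lte(gain(0.5), 0.1)
  # monotone stopband below the passband
  expect_lt(gain(0.001), gain(0.005))
  expect_true(all(bandpass_filter(rep(0, 500), preprocess_params(), fs) == 0))
  expect_error(bandpass_filter(rep(0, 100),
                               preprocess_params(band_high = 6), fs),
               "Nyquist")
})

test_that("zero-phase filtering does not shift in-band components", {
  fs <- 10
  t <- seq(0, 3000, by = 1 / fs)
  x <- sin(2 * pi * 0.03 * t)
  y <- bandpass_filter(x, preprocess_params(), fs)
  core <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  lag <- which.max(ccf(y[core], x[core], lag.max = 30, plot = FALSE)$acf) - 31
  expect_equal(lag, 0)
})

test_that("block validity flags respond only to artifacts inside epoch windows", {
  fs <- 10
  design <- make_block_design(design_params(baseline_choices = 20), seed = 2)
  n <- floor((design$total_duration + 20) * fs) + 1
  clean <- array(rnorm(n * 2 * 2, sd = 1e-4), dim = c(n, 2, 2))
  p <- preprocess_params()
  # clean series: every block valid everywhere
  valid <- redetect_and_flag(clean, p, design, fs, epoch_window())
  expect_true(all(valid))
  # artifact at block-5 onset only -> exactly block 5 invalid on channel 1
  od <- clean
  i5 <- floor(design$events$onset[5] * fs) + 1
  od[i5, 1, 1] <- od[i5, 1, 1] + 0.5
  valid <- redetect_and_flag(od, p, design, fs, epoch_window())
  expect_false(valid[5, 1])
  expect_true(all(valid[-5, 1]))
  expect_true(all(valid[, 2]))
  # artifact inside a baseline gap: after the previous epoch window closes
  # and more than 3 s (+ mask margin) before the next onset -> nothing
  # invalidated (needs gaps wider than the 30 s epoch tail to exist)
  design_w <- make_block_design(design_params(baseline_choices = 40), seed = 2)
  n_w <- floor((design_w$total_duration + 20) * fs) + 1
  set.seed(2)
  clean_w <- array(rnorm(n_w * 2 * 2, sd = 1e-4), dim = c(n_w, 2, 2))
  od2 <- clean_w
  gap_t <- design_w$events$onset[6] - 8
  od2[floor(gap_t * fs) + 1, 1, 1] <- od2[floor(gap_t * fs) + 1, 1, 1] + 0.5
  valid <- redetect_and_flag(od2, p, design_w, fs, epoch_window())
  expect_true(all(valid))
})

test_that("noiseless cascade output tracks the band-passed ground truth", {
  cfg <- quick_config(noise = noise_params_silent(), seed = 13)
  ps <- simulate_participant(cfg, 1)
  pp <- preprocess_scan(ps$scan, preprocess_params(), cfg$extinction)
  expect_true(all(pp$available))
  truth_band <- bandpass_filter(ps$truth$hb_clean$values[, , "oxy"],
                                preprocess_params(), cfg$sampling_rate)
  for (c_i in seq_len(6)) {
    r <- cor(pp$hb$values[, c_i, "oxy"], truth_band[, c_i])
    expect_gt(r, 0.95)
  }
})

test_that("10-sigma motion spikes are recalled at >= 90%", {
  # realistic background: slow oscillations dominate the channel OD sd,
  # white noise dominates the sample-to-sample change statistic
  fs <- 10
  t <- seq(0, 600, by = 1 / fs)
  n <- length(t)
  p <- preprocess_params()
  n_spikes <- 0; n_recalled <- 0
  for (seed in 1:10) {
    set.seed(seed)
    x <- 0.01 * sin(2 * pi * 0.1 * t + runif(1, 0, 2 * pi)) +
      0.02 * sin(2 * pi * 0.002 * t + runif(1, 0, 2 * pi)) +
      rnorm(n, sd = 0.005)
    sd_ch <- sd(x)
    at <- seq(300, n - 300, length.out = 12)
    spike_amp <- 10 * sd_ch
    x2 <- x
    x2[round(at)] <- x2[round(at)] + spike_amp
    mask <- detect_motion(array(x2, c(n, 1, 1)), p, fs)
    n_spikes <- n_spikes + length(at)
    n_recalled <- n_recalled + sum(mask[round(at), 1])
  }
  expect_gte(n_recalled / n_spikes, 0.9)
})

test_that("the full cascade prunes, flags and masks without reshaping data", {
  cfg <- quick_config(seed = 17)
  ps <- simulate_participant(cfg, 1)
  # force one channel to be pruned: replace with high-variance noise
  ps$scan$intensity[, 2, ] <-
    abs(1 + rnorm(length(ps$scan$intensity[, 2, ]), sd = 1)) + 1e-6
  pp <- preprocess_scan(ps$scan, preprocess_params(), cfg$extinction)
  expect_false(pp$available[2])
  expect_true(all(is.na(pp$hb$values[, 2, ])))
  expect_true(all(!pp$block_valid[, 2]))
  expect_identical(dim(pp$hb$values)[1], dim(ps$scan$intensity)[1])
  expect_identical(pp$log$order,
                   c("prune", "od", "detect", "spline", "wavelet",
                     "redetect", "bandpass", "concentration"))
})
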