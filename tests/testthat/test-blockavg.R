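make_design_20 <- function() make_block_design(design_params(baseline_choices = 20),
                                               seed = 7)

test_that("epoch grid spans -3 to 30 s inclusively: 331 samples at 10 Hz", {
  design <- make_design_20()
  hb <- constant_hb(1, n_time = floor((design$total_duration + 20) * 10) + 1)
  ep <- epoch_blocks(hb, design, epoch_window())
  expect_equal(dim(ep$epochs)[2], 331)
  expect_equal(ep$rel_time[1], -3)
  expect_equal(ep$rel_time[331], 30)
})

test_that("a constant series epochs to identically zero after baseline correction", {
  design <- make_design_20()
  hb <- constant_hb(5.5, n_time = floor((design$total_duration + 20) * 10) + 1)
  ep <- epoch_blocks(hb, design, epoch_window())
  expect_true(all(ep$epochs == 0))
  # idempotence: re-epoching an already baseline-corrected constant series
  # changes nothing
  hb0 <- constant_hb(0, n_time = dim(hb$values)[1])
  ep0 <- epoch_blocks(hb0, design, epoch_window())
  expect_identical(ep$epochs, ep0$epochs)
})

test_that("a noiseless single-block epoch matches the convolution oracle", {
  cfg <- quick_config(noise = noise_params_silent(), n_blocks = 1)
  cfg$amplitudes[] <- 0
  cfg$amplitudes["19", "HL"] <- 0.3
  d <- make_block_design(cfg$design, seed = 5)
  sim <- simulate_hb(d, cfg, participant_seed = 5)
  fs <- cfg$sampling_rate
  ep <- epoch_blocks(sim$hb, d, epoch_window())
  b <- which(d$events$condition == "HL")
  # oracle: direct convolution of the boxcar with the kernel on the window
  kern <- hrf_kernel(seq(0, max(30, 2.5 * cfg$hrf$undershoot_time),
                         by = 1 / fs), cfg$hrf)
  block_len <- round(15 * fs)
  single <- conv_oracle(c(rep(1, block_len), rep(0, length(kern))), kern) / fs
  n <- dim(sim$hb$values)[1]
  u <- numeric(n)
  i0 <- floor(d$events$onset[b] * fs) + 1
  u[i0:(i0 + block_len - 1)] <- 1
  full <- 0.3 * conv_oracle(u, kern) / fs / max(single)
  idx <- i0 + round(-3 * fs):round(30 * fs)
  expected <- full[idx] - mean(full[i0 + round(-3 * fs):(-1)])
  expect_equal(ep$epochs[b, , which(ep$channel_ids == 19), 1], expected,
               tolerance = 1e-9)
})

test_that("onsets too close to the recording edge invalidate that block", {
  design <- make_design_20()
  # recording ends exactly at schedule end: last block's +30 s tail missing
  hb <- constant_hb(1, n_time = floor(design$total_duration * 10) + 1)
  expect_warning(ep <- epoch_blocks(hb, design, epoch_window()),
                 "leaves the recording")
  expect_false(any(ep$valid[14, ]))
  expect_true(all(ep$valid[1:13, ]))
})

test_that("participant summaries average valid epochs then the stat interval", {
  design <- make_design_20()
  n_time <- floor((design$total_duration + 20) * 10) + 1
  hb <- constant_hb(0, n_time)
  # channel 1: inject constant offsets post-onset per block so the
  # stat-interval means are controlled exactly
  fs <- 10
  vals <- 1:14                            # block b has stat-interval mean b
  for (b in 1:14) {
    i0 <- floor(design$events$onset[b] * fs) + 1
    hb$values[i0:(i0 + 30 * fs), , 1] <- vals[b]
  }
  # channel 2: only two blocks of the first condition valid, means 1 and 3
  valid <- matrix(TRUE, 14, 6)
  valid[-c(1, 3), 2] <- FALSE
  ep <- epoch_blocks(hb, design, epoch_window(), block_valid = valid)
  s <- participant_summary(ep)$summary
  c1 <- design$events$condition[1]
  m_c1 <- s$mean_change[s$channel == 6 & s$condition == c1 & s$hb == "oxy"]
  expect_equal(m_c1, mean(vals[design$events$condition == c1]),
               tolerance = 1e-9)
  expect_equal(s$n_valid_blocks[s$channel == 6 & s$condition == "HL" &
                                  s$hb == "oxy"], 7)
  # arithmetic mean of the two valid epochs: (1 + 3) / 2 = 2
  expect_equal(s$mean_change[s$channel == 7 & s$condition == c1 &
                               s$hb == "oxy"], 2, tolerance = 1e-9)
  expect_true(is.na(s$mean_change[s$channel == 7 & s$condition != c1 &
                                    s$hb == "oxy"]))
})

test_that("summary cells without valid blocks are unavailable", {
  design <- make_design_20()
  hb <- constant_hb(1, n_time = floor((design$total_duration + 20) * 10) + 1)
  valid <- matrix(TRUE, 14, 6)
  valid[design$events$condition == "LH", 2] <- FALSE
  ep <- epoch_blocks(hb, design, epoch_window(), block_valid = valid)
  s <- participant_summary(ep)$summary
  expect_true(all(is.na(s$mean_change[s$channel == 7 & s$condition == "LH"])))
  expect_equal(unique(s$n_valid_blocks[s$channel == 7 & s$condition == "LH"]), 0)
  expect_false(anyNA(s$mean_change[s$channel == 7 & s$condition == "HL"]))
})

test_that("condition labels are symmetric: swapping labels swaps outputs", {
  cfg <- quick_config(seed = 23)
  ps <- simulate_participant(cfg, 1)
  pp <- preprocess_scan(ps$scan, preprocess_params(), cfg$extinction)
  ep <- epoch_blocks(pp$hb, ps$scan$design, epoch_window(), pp$block_valid)
  sm1 <- participant_summary(ep)$summary
  ep2 <- ep
  ep2$condition <- ifelse(ep$condition == "HL", "LH", "HL")
  sm2 <- participant_summary(ep2)$summary
  key1 <- paste(sm1$channel, sm1$condition, sm1$hb)
  key2 <- paste(sm2$channel, ifelse(sm2$condition == "HL", "LH", "HL"), sm2$hb)
  expect_equal(sm1$mean_change, sm2$mean_change[match(key1, key2)])
})

# a participant_summary fixture with prescribed valid-block counts
summary_fixture <- function(counts_hl, counts_lh, value = 1) {
  roi <- c(6L, 7L, 9L, 18L, 19L, 21L)
  rows <- list()
  for (j in seq_along(roi)) {
    for (cond in c("HL", "LH")) {
      nb <- if (cond == "HL") counts_hl[j] else counts_lh[j]
      for (hb in c("oxy", "deoxy"))
        rows[[length(rows) + 1]] <- data.frame(
          channel = roi[j], condition = cond, hb = hb,
          mean_change = if (nb > 0) value else NA_real_,
          n_valid_blocks = nb)
    }
  }
  structure(list(summary = do.call(rbind, rows), excl = exclusion_params()),
            class = "participant_summary")
}

test_that("ROI availability needs 3+ valid blocks in each condition", {
  layout <- probe_layout(roi_only = TRUE)
  # channel 6 has 3 HL but only 2 LH blocks -> unavailable
  s <- summary_fixture(counts_hl = c(3, 7, 7, 7, 7, 7),
                       counts_lh = c(2, 7, 7, 7, 7, 7))
  exc <- apply_exclusions(list(s), exclusion_params(), layout)
  row6 <- exc$cohort[exc$cohort$channel == 6, ]
  expect_true(all(!row6$roi_available))
  expect_true(all(exc$cohort$roi_available[exc$cohort$channel != 6]))
  # 5 of 6 ROIs available -> still retained
  expect_true(exc$report$included[1])
})

test_that("participants with fewer than 5 available ROIs are excluded", {
  layout <- probe_layout(roi_only = TRUE)
  ok <- summary_fixture(rep(7, 6), rep(7, 6))
  four <- summary_fixture(c(2, 2, 7, 7, 7, 7), rep(7, 6))   # 4 available
  five <- summary_fixture(c(2, 7, 7, 7, 7, 7), rep(7, 6))   # 5 available
  exc <- apply_exclusions(list(ok, four, five), exclusion_params(), layout)
  expect_equal(exc$report$included, c(TRUE, FALSE, TRUE))
  expect_equal(exc$report$n_available_rois, c(6, 4, 5))
  expect_match(exc$report$reason[2], "fewer than 5")
  # cohort of 10 with one participant forced below threshold on two ROIs
  many <- c(replicate(9, summary_fixture(rep(7, 6), rep(7, 6)),
                      simplify = FALSE),
            list(summary_fixture(c(2, 2, 7, 7, 7, 7), rep(7, 6))))
  exc10 <- apply_exclusions(many, exclusion_params(), layout)
  expect_equal(sum(!exc10$report$included), 1)
  expect_false(exc10$report$included[10])
})

test_that("raising exclusion thresholds never grows the retained cohort", {
  layout <- probe_layout(roi_only = TRUE)
  set.seed(61)
  cohorts <- replicate(12, {
    summary_fixture(sample(0:7, 6, replace = TRUE),
                    sample(0:7, 6, replace = TRUE))
  }, simplify = FALSE)
  retained <- function(mb, mr) {
    exc <- apply_exclusions(cohorts, exclusion_params(mb, mr), layout)
    which(exc$report$included)
  }
  for (mb in 1:3) for (mr in 1:5) {
    base <- retained(mb, mr)
    expect_true(all(retained(mb + 1, mr) %in% base))
    expect_true(all(retained(mb, mr + 1) %in% base))
  }
})
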