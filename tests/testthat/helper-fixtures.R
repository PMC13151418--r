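# Shared fixtures: small, fast configurations and independent oracles.

# direct O(n^2) causal convolution oracle (independent of stats::convolve)
conv_oracle <- function(u, k) {
  n <- length(u)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- seq_len(min(i, length(k)))
    out[i] <- sum(u[i - j + 1] * k[j])
  }
  out
}

# fast simulation setup: 6 ROI channels only, short design
quick_config <- function(n_participants = 1, noise = noise_params(),
                         n_blocks = 7, seed = 11L) {
  simulation_config(
    n_participants = n_participants,
    design = design_params(n_blocks_per_condition = n_blocks),
    layout = probe_layout(roi_only = TRUE),
    noise = noise, seed = seed)
}

# hb_series with a single constant value everywhere
constant_hb <- function(value, n_time, n_ch = 6, fs = 10,
                        channel_ids = c(6, 7, 9, 18, 19, 21)) {
  hb_series(array(value, dim = c(n_time, n_ch, 2)), fs, channel_ids)
}

# exhaustive sign-flip max-|t| reference: all 2^n patterns, plain loops
exhaustive_maxt_p <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  tstat <- function(x) mean(x) / (sd(x) / sqrt(length(x)))
  t_obs <- apply(X, 2, tstat)
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  max_null <- apply(grid, 1, function(s) max(abs(apply(s * X, 2, tstat))))
  vapply(t_obs, function(tt) mean(max_null >= abs(tt)), numeric(1))
}

# build a cohort table row set for one participant from a named matrix of
# mean changes: channels x conditions, one hb type
cohort_rows <- function(participant, channel, hemisphere, condition,
                        hb_type, mean_change, n_valid_blocks = 7,
                        age_group = "5-month", roi_available = TRUE,
                        included = TRUE) {
  data.frame(participant = participant, age_group = age_group,
             channel = channel, hemisphere = hemisphere,
             condition = condition, hb_type = hb_type,
             mean_change = mean_change, n_valid_blocks = n_valid_blocks,
             roi_available = roi_available, included = included)
}

# synthetic summary-level cohort: participants x 6 ROI channels per
# condition, correlated across channels, optional per-channel effect
make_summary_cohort <- function(n = 30, effect = NULL, rho = 0.3,
                                seed = 1, age_group = "5-month") {
  roi <- c(6L, 7L, 9L, 18L, 19L, 21L)
  hemi <- c("right", "right", "right", "left", "left", "left")
  Sigma <- matrix(rho, 6, 6); diag(Sigma) <- 1
  L <- chol(Sigma)
  withr::with_seed(seed, {
    hl <- matrix(rnorm(n * 6), n) %*% L
    lh <- matrix(rnorm(n * 6), n) %*% L
  })
  if (!is.null(effect)) hl <- hl + matrix(effect, n, 6, byrow = TRUE)
  rows <- list()
  for (i in seq_len(n)) {
    for (j in 1:6) {
      for (cond in c("HL", "LH")) {
        val <- if (cond == "HL") hl[i, j] else lh[i, j]
        rows[[length(rows) + 1]] <- cohort_rows(
          sprintf("sub-%02d", i), roi[j], hemi[j], cond, "oxy", val,
          age_group = age_group)
      }
    }
  }
  do.call(rbind, rows)
}
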