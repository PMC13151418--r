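#' Hemoglobin concentration series container
#'
#' @param values Numeric array `time x channel x 2` with the third dimension
#'   named `c("oxy", "deoxy")`, concentration change in uM.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_ids Integer channel ids for the second dimension.
#' @return An `hb_series` object.
#' @export
hb_series <- function(values, sampling_rate, channel_ids) {
  stopifnot(length(dim(values)) == 3, dim(values)[3] == 2,
            dim(values)[2] == length(channel_ids))
  dimnames(values) <- list(NULL, as.character(channel_ids), c("oxy", "deoxy"))
  structure(list(values = values, sampling_rate = sampling_rate,
                 time = seq(0, by = 1 / sampling_rate,
                            length.out = dim(values)[1]),
                 channel_ids = as.integer(channel_ids)),
            class = "hb_series")
}

#' Simulate noiseless + noisy hemoglobin series for one participant
#'
#' Forward model: for each condition the stimulus boxcar train is convolved
#' with the peak-normalised hemodynamic kernel and rescaled so that a single
#' isolated block reaches a peak of exactly 1; the per-channel,
#' per-condition ground-truth amplitude then scales that response. The
#' deoxy-Hb series is `deoxy_ratio` times the noiseless oxy-Hb series.
#' Physiological noise (slow drift, Mayer-wave and respiratory oscillations
#' with per-channel random phases, white noise) is added independently to
#' oxy and deoxy; deoxy noise amplitudes are scaled by `|deoxy_ratio|`.
#'
#' @param design A `block_design` from [make_block_design()].
#' @param config A [simulation_config()] object.
#' @param participant_seed Integer seed for this participant's noise.
#' @return List with `hb` (noisy [hb_series()]) and `truth` (list:
#'   `hb_clean` noiseless `hb_series`, `amplitudes`, `motion_mask` — all
#'   `FALSE` until [inject_motion()] runs).
#' @export
simulate_hb <- function(design, config, participant_seed = config$seed) {
  fs <- config$sampling_rate
  dt <- 1 / fs
  total <- design$total_duration + config$scan_padding
  n <- floor(total * fs) + 1L
  tgrid <- seq(0, by = dt, length.out = n)
  ch <- config$layout$channels
  n_ch <- nrow(ch)

  # condition-wise block response, normalised to unit single-block peak
  k_support <- seq(0, max(30, 2.5 * config$hrf$undershoot_time), by = dt)
  kern <- hrf_kernel(k_support, config$hrf)
  block_len <- max(1L, round(config$design$block_duration * fs))
  single <- .conv_causal(c(rep(1, block_len), rep(0, length(kern))), kern) * dt
  peak_single <- max(single)
  response <- matrix(0, n, 2, dimnames = list(NULL, c("HL", "LH")))
  if (peak_single > 0 && nrow(design$events) > 0) {
    for (cond in c("HL", "LH")) {
      u <- numeric(n)
      ev <- design$events[design$events$condition == cond, , drop = FALSE]
      for (j in seq_len(nrow(ev))) {
        i0 <- floor(ev$onset[j] * fs) + 1L
        i1 <- min(n, i0 + block_len - 1L)
        if (i0 <= n) u[i0:i1] <- 1
      }
      response[, cond] <- .conv_causal(u, kern)[seq_len(n)] * dt / peak_single
    }
  }

  oxy_clean <- response %*% t(config$amplitudes)   # n x n_ch
  deoxy_clean <- config$hrf$deoxy_ratio * oxy_clean
  clean <- array(c(oxy_clean, deoxy_clean), dim = c(n, n_ch, 2))

  nz <- config$noise
  noisy <- withr::with_seed(participant_seed, {
    out <- clean
    for (hb in 1:2) {
      scale <- if (hb == 1) 1 else abs(config$hrf$deoxy_ratio)
      for (c_i in seq_len(n_ch)) {
        comp <- numeric(n)
        if (nz$drift_amplitude > 0 && nz$drift_frequency > 0)
          comp <- comp + nz$drift_amplitude *
            sin(2 * pi * nz$drift_frequency * tgrid + stats::runif(1, 0, 2 * pi))
        if (nrow(nz$oscillations) > 0)
          for (o in seq_len(nrow(nz$oscillations)))
            comp <- comp + nz$oscillations$amplitude[o] *
              sin(2 * pi * nz$oscillations$frequency[o] * tgrid +
                    stats::runif(1, 0, 2 * pi))
        if (nz$white_noise_sd > 0)
          comp <- comp + stats::rnorm(n, sd = nz$white_noise_sd)
        out[, c_i, hb] <- out[, c_i, hb] + scale * comp
      }
    }
    out
  })

  list(hb = hb_series(noisy, fs, ch$id),
       truth = list(hb_clean = hb_series(clean, fs, ch$id),
                    amplitudes = config$amplitudes,
                    motion_mask = matrix(FALSE, n, n_ch)))
}

# causal discrete convolution, first length(u) samples of u * k
.conv_causal <- function(u, k) {
  n <- length(u)
  full <- stats::convolve(u, rev(k), type = "open")
  full[seq_len(n)]
}

#' Forward modified Beer-Lambert projection
#'
#' Maps hemoglobin concentration changes to optical-density changes at each
#' wavelength: `dOD(lambda, t) = d * ppf * (eps_oxy(lambda) * dOxy(t) +
#' eps_deoxy(lambda) * dDeoxy(t))` with `d` the source-detector distance.
#' The exact inverse of [od_to_conc()].
#'
#' @param hb An [hb_series()] object.
#' @param extinction An [extinction_table()] object.
#' @param layout A [probe_layout()] object (provides the distance).
#' @param ppf Partial pathlength factor (default 1).
#' @return Numeric array `time x channel x wavelength` of OD changes, with
#'   wavelength dimnames.
#' @export
forward_beer_lambert <- function(hb, extinction = extinction_table(),
                                 layout = probe_layout(), ppf = 1) {
  E <- extinction$matrix                       # 2 (wl) x 2 (oxy, deoxy)
  d <- layout$source_detector_distance
  v <- hb$values
  n <- dim(v)[1]; n_ch <- dim(v)[2]
  od <- array(0, dim = c(n, n_ch, 2),
              dimnames = list(NULL, dimnames(v)[[2]],
                              as.character(extinction$wavelengths)))
  for (w in 1:2)
    od[, , w] <- d * ppf * (E[w, "oxy"] * v[, , "oxy"] +
                              E[w, "deoxy"] * v[, , "deoxy"])
  od
}

#' Inject motion artifacts into an optical-density series
#'
#' Adds two artifact families at Poisson-distributed event times: brief
#' spikes (half-sine bumps of 0.2-0.8 s) and plateau-like baseline shifts
#' (3-10 s of displaced baseline bounded by two steps; slow persistent
#' drifts are the band-pass filter's job, not the artifact model's). Each
#' event displaces every channel at both wavelengths, with an amplitude
#' drawn per channel from the configured range and a random sign — the
#' spatially-global signature of a head or probe movement. The returned
#' mask flags every contaminated sample per channel.
#'
#' @param od Array `time x channel x wavelength` of OD changes.
#' @param noise A [noise_params()] object (rates and amplitude ranges).
#' @param sampling_rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @return List `od` (contaminated array) and `mask` (logical
#'   `time x channel`).
#' @export
inject_motion <- function(od, noise, sampling_rate, seed = 1L) {
  n <- dim(od)[1]; n_ch <- dim(od)[2]
  mask <- matrix(FALSE, n, n_ch)
  dur_min <- n / sampling_rate / 60
  withr::with_seed(seed, {
    n_spk <- if (noise$motion_spike_rate > 0)
      stats::rpois(1, noise$motion_spike_rate * dur_min) else 0L
    n_shf <- if (noise$baseline_shift_rate > 0)
      stats::rpois(1, noise$baseline_shift_rate * dur_min) else 0L
    for (s in seq_len(n_spk)) {
      i0 <- sample.int(n, 1)
      len <- max(2L, round(stats::runif(1, 0.2, 0.8) * sampling_rate))
      idx <- i0:min(n, i0 + len - 1L)
      bump <- sin(pi * seq_along(idx) / (length(idx) + 1))
      amp <- stats::runif(n_ch, noise$motion_spike_amplitude_range[1],
                          noise$motion_spike_amplitude_range[2]) *
        sample(c(-1, 1), n_ch, replace = TRUE)
      for (w in seq_len(dim(od)[3]))
        od[idx, , w] <- od[idx, , w] + outer(bump, amp)
      mask[idx, ] <- TRUE
    }
    for (s in seq_len(n_shf)) {
      i0 <- sample.int(n, 1)
      len <- max(2L, round(stats::runif(1, 3, 10) * sampling_rate))
      idx <- i0:min(n, i0 + len - 1L)
      amp <- stats::runif(n_ch, noise$baseline_shift_amplitude_range[1],
                          noise$baseline_shift_amplitude_range[2]) *
        sample(c(-1, 1), n_ch, replace = TRUE)
      for (w in seq_len(dim(od)[3]))
        od[idx, , w] <- od[idx, , w] + matrix(amp, length(idx), n_ch,
                                              byrow = TRUE)
      mask[idx, ] <- TRUE
    }
  })
  list(od = od, mask = mask)
}

#' Convert optical density to raw intensities
#'
#' `I(t) = I0 * exp(-dOD(t))`, with optional multiplicative log-normal
#' measurement noise; output is strictly positive. Inverse (up to a
#' per-channel additive OD constant) of [intensity_to_od()].
#'
#' @param od Array `time x channel x wavelength` of OD changes.
#' @param baseline_intensity Scalar or `channel x wavelength` matrix of
#'   baseline intensities (arbitrary units, > 0).
#' @param measurement_noise_sd Standard deviation of the log-intensity
#'   noise (0 disables).
#' @param seed Integer seed for the measurement noise.
#' @return Array `time x channel x wavelength` of positive intensities.
#' @export
od_to_intensity <- function(od, baseline_intensity = 1,
                            measurement_noise_sd = 0, seed = 1L) {
  n <- dim(od)[1]; n_ch <- dim(od)[2]; n_wl <- dim(od)[3]
  if (length(baseline_intensity) == 1)
    baseline_intensity <- matrix(baseline_intensity, n_ch, n_wl)
  if (any(baseline_intensity <= 0))
    stop("baseline_intensity must be strictly positive", call. = FALSE)
  out <- od
  for (w in seq_len(n_wl))
    out[, , w] <- exp(-od[, , w]) *
      matrix(baseline_intensity[, w], n, n_ch, byrow = TRUE)
  if (measurement_noise_sd > 0)
    out <- out * withr::with_seed(seed,
      exp(array(stats::rnorm(length(out), sd = measurement_noise_sd),
                dim = dim(out))))
  out
}

#' Simulate one participant's raw recording
#'
#' Chains the forward model end to end: block design, hemoglobin series
#' with physiological noise, Beer-Lambert projection to OD, motion-artifact
#' injection, and conversion to raw dual-wavelength intensities.
#'
#' @param config A [simulation_config()] object.
#' @param i Participant index (1-based); the participant seed is
#'   `participant_seed(config$seed, i)`.
#' @return A list with `scan` (a `nirs_scan`: `intensity` array
#'   `time x channel x wavelength`, `time`, `sampling_rate`, `wavelengths`,
#'   `layout`, `design`, `participant_id`, `seed`) and `truth` (ground-truth
#'   list: noiseless `hb_clean`, `amplitudes`, motion `mask`).
#' @export
simulate_participant <- function(config, i = 1L) {
  pseed <- participant_seed(config$seed, i)
  design <- make_block_design(config$design, seed = pseed)
  sim <- simulate_hb(design, config, participant_seed = pseed + 1L)
  od <- forward_beer_lambert(sim$hb, config$extinction, config$layout,
                             config$ppf)
  mot <- inject_motion(od, config$noise, config$sampling_rate,
                       seed = pseed + 2L)
  intensity <- od_to_intensity(mot$od, config$baseline_intensity,
                               config$noise$measurement_noise_sd,
                               seed = pseed + 3L)
  scan <- structure(list(intensity = intensity,
                         time = sim$hb$time,
                         sampling_rate = config$sampling_rate,
                         wavelengths = config$extinction$wavelengths,
                         layout = config$layout,
                         design = design,
                         participant_id = sprintf("sub-%02d", i),
                         seed = pseed),
                    class = "nirs_scan")
  truth <- sim$truth
  truth$motion_mask <- mot$mask
  list(scan = scan, truth = truth)
}

#' Simulate a cohort of participants
#'
#' @param config A [simulation_config()] object.
#' @param out_dir Optional directory; when given, each participant is
#'   serialised to `<out_dir>/<participant_id>/` via [write_scan()].
#' @return Invisibly for large cohorts: a list with elements `scans` and
#'   `truths` (each of length `n_participants`).
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  res <- lapply(seq_len(config$n_participants),
                function(i) simulate_participant(config, i))
  scans <- lapply(res, `[[`, "scan")
  truths <- lapply(res, `[[`, "truth")
  if (!is.null(out_dir)) {
    for (i in seq_along(scans)) {
      dir_i <- file.path(out_dir, scans[[i]]$participant_id)
      tryCatch(write_scan(scans[[i]], dir_i, truth = truths[[i]]),
               error = function(e) stop("failed writing scan container at ",
                                        dir_i, ": ", conditionMessage(e),
                                        call. = FALSE))
    }
  }
  list(scans = scans, truths = truths)
}
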