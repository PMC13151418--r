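#' Physiological and instrumental noise parameters
#'
#' Noise model of the simulator. Concentration-domain components (drift,
#' oscillations, white noise) are added to the hemoglobin series in uM;
#' motion artifacts (spikes, step-like baseline shifts) are injected in the
#' optical-density domain; multiplicative measurement noise is applied to
#' the raw intensities.
#'
#' @param drift_amplitude Amplitude of the slow baseline drift, uM
#'   (default 0.3).
#' @param drift_frequency Drift frequency in Hz (default 0.002; the
#'   realistic range is roughly 0.001-0.005 Hz).
#' @param oscillations Data frame with columns `frequency` (Hz) and
#'   `amplitude` (uM); defaults to a Mayer-wave component at 0.1 Hz and a
#'   respiratory component at 0.5 Hz.
#' @param white_noise_sd Per-sample Gaussian noise on each hemoglobin
#'   series, uM (default 0.05).
#' @param motion_spike_rate Motion spike events per minute (default 0.5).
#' @param motion_spike_amplitude_range Length-2 range of spike amplitudes in
#'   OD units (default `c(0.005, 0.05)`, i.e. roughly 3-30 times the evoked
#'   hemodynamic OD change under the package's extinction-table scale).
#' @param baseline_shift_rate Step-like baseline-shift events per minute
#'   (default 0.2).
#' @param baseline_shift_amplitude_range Length-2 range of shift magnitudes
#'   in OD units (default `c(0.01, 0.1)`).
#' @param measurement_noise_sd Standard deviation of the multiplicative
#'   (log-normal) intensity noise (default 5e-4).
#'
#' @return A `noise_params` object.
#' @export
noise_params <- function(drift_amplitude = 0.3,
                         drift_frequency = 0.002,
                         oscillations = data.frame(
                           frequency = c(0.1, 0.5),
                           amplitude = c(0.10, 0.05)),
                         white_noise_sd = 0.05,
                         motion_spike_rate = 0.5,
                         motion_spike_amplitude_range = c(0.005, 0.05),
                         baseline_shift_rate = 0.2,
                         baseline_shift_amplitude_range = c(0.01, 0.1),
                         measurement_noise_sd = 5e-4) {
  vals <- c(drift_amplitude, drift_frequency, oscillations$amplitude,
            oscillations$frequency, white_noise_sd, motion_spike_rate,
            motion_spike_amplitude_range, baseline_shift_rate,
            baseline_shift_amplitude_range, measurement_noise_sd)
  if (any(vals < 0)) stop("noise rates and amplitudes must be >= 0", call. = FALSE)
  structure(list(drift_amplitude = drift_amplitude,
                 drift_frequency = drift_frequency,
                 oscillations = oscillations,
                 white_noise_sd = white_noise_sd,
                 motion_spike_rate = motion_spike_rate,
                 motion_spike_amplitude_range = motion_spike_amplitude_range,
                 baseline_shift_rate = baseline_shift_rate,
                 baseline_shift_amplitude_range = baseline_shift_amplitude_range,
                 measurement_noise_sd = measurement_noise_sd),
            class = "noise_params")
}

#' Quiet noise model
#'
#' All noise components and artifact rates set to zero; useful for
#' ground-truth recovery checks.
#' @return A `noise_params` object with every component 0.
#' @export
noise_params_silent <- function() {
  noise_params(drift_amplitude = 0, drift_frequency = 0,
               oscillations = data.frame(frequency = numeric(0),
                                         amplitude = numeric(0)),
               white_noise_sd = 0, motion_spike_rate = 0,
               motion_spike_amplitude_range = c(0, 0),
               baseline_shift_rate = 0,
               baseline_shift_amplitude_range = c(0, 0),
               measurement_noise_sd = 0)
}

#' Default ground-truth block response amplitudes
#'
#' Per-channel, per-condition peak oxy-Hb amplitudes (uM) used by the
#' simulator: in left-hemisphere ROI channels the HL condition evokes a
#' larger response than LH (the configured ground-truth effect); right ROI
#' channels respond equally to both; non-ROI channels respond weakly.
#'
#' @param layout A [probe_layout()] object.
#' @param hl_left,lh_left Peak amplitudes in left ROI channels (uM).
#' @param roi_right Peak amplitude (both conditions) in right ROI channels.
#' @param non_roi Peak amplitude (both conditions) in non-ROI channels.
#' @return Matrix `channels x conditions` (columns `HL`, `LH`), rownames =
#'   channel ids.
#' @export
default_amplitudes <- function(layout = probe_layout(),
                               hl_left = 0.40, lh_left = 0.15,
                               roi_right = 0.25, non_roi = 0.05) {
  ch <- layout$channels
  amp <- matrix(non_roi, nrow = nrow(ch), ncol = 2,
                dimnames = list(ch$id, c("HL", "LH")))
  amp[ch$is_roi & ch$hemisphere == "left", ] <-
    rep(c(hl_left, lh_left), each = sum(ch$is_roi & ch$hemisphere == "left"))
  amp[ch$is_roi & ch$hemisphere == "right", ] <- roi_right
  amp
}

#' Simulation configuration
#'
#' Bundles everything the cohort simulator needs. All defaults mirror the
#' experimental design this package models: 10 Hz sampling, 14 alternating
#' 15-s blocks with 18/20/22-s jittered baselines, 24 lateral channels with
#' six ROI channels, dual wavelengths 695/830 nm at 3 cm separation.
#'
#' @param n_participants Number of participants to simulate.
#' @param design A [design_params()] object.
#' @param layout A [probe_layout()] object.
#' @param hrf An [hrf_params()] object.
#' @param noise A [noise_params()] object.
#' @param extinction An [extinction_table()] object.
#' @param amplitudes Ground-truth peak amplitude matrix
#'   (channels x conditions) as from [default_amplitudes()]; `NULL` uses the
#'   defaults for `layout`.
#' @param sampling_rate Sampling rate in Hz (default 10).
#' @param ppf Partial pathlength factor used by the forward model
#'   (default 1).
#' @param baseline_intensity Baseline detector intensity (arbitrary units)
#'   per wavelength (default 1).
#' @param scan_padding Seconds of recording appended after the final block
#'   so that the last epoch window fits (default 20).
#' @param seed Master seed; per-participant seeds are derived from it (see
#'   [participant_seed()]).
#'
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_participants = 1,
                              design = design_params(),
                              layout = probe_layout(),
                              hrf = hrf_params(),
                              noise = noise_params(),
                              extinction = extinction_table(),
                              amplitudes = NULL,
                              sampling_rate = 10,
                              ppf = 1,
                              baseline_intensity = 1,
                              scan_padding = 20,
                              seed = 1L) {
  if (sampling_rate <= 0) stop("sampling_rate must be positive", call. = FALSE)
  if (n_participants < 1) stop("n_participants must be >= 1", call. = FALSE)
  if (is.null(amplitudes)) amplitudes <- default_amplitudes(layout)
  stopifnot(nrow(amplitudes) == nrow(layout$channels),
            identical(colnames(amplitudes), c("HL", "LH")))
  structure(list(n_participants = as.integer(n_participants), design = design,
                 layout = layout, hrf = hrf, noise = noise,
                 extinction = extinction, amplitudes = amplitudes,
                 sampling_rate = sampling_rate, ppf = ppf,
                 baseline_intensity = baseline_intensity,
                 scan_padding = scan_padding, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Derive a per-participant seed from the master seed
#'
#' Stable splitting rule `(master + 104729 * i) mod (2^31 - 1)` (104729 is
#' the 10000th prime); documented so that individual participants can be
#' regenerated without simulating the whole cohort.
#'
#' @param master_seed Integer master seed.
#' @param i Participant index (1-based).
#' @return Integer seed.
#' @export
participant_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) + 104729 * as.numeric(i)) %% 2147483647)
}
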