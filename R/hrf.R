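#' Hemodynamic response function parameters
#'
#' Parameters of the canonical double-gamma impulse response used by the
#' simulator. The infant hemodynamic response is not well characterised;
#' these defaults (peak near 5 s, shallow undershoot near 14 s) are a
#' conventional adult-like stand-in and are clearly labelled as such in the
#' package documentation. Any kernel that is 0 at onset, peaks at 1, and
#' decays is admissible.
#'
#' @param peak_time Time to peak in seconds (default 5).
#' @param undershoot_time Time to the undershoot trough in seconds
#'   (default 14).
#' @param undershoot_ratio Depth of the undershoot relative to the peak
#'   (default 0.2; 0 disables the undershoot).
#' @param peak_amplitude Peak concentration change of a single block response
#'   in concentration units (uM under the package convention); used by the
#'   simulator, not by the kernel itself.
#' @param deoxy_ratio Scale mapping the noiseless oxy-Hb response to the
#'   deoxy-Hb response (default -1/3, the typical anticorrelation).
#'
#' @return An `hrf_params` object.
#' @export
hrf_params <- function(peak_time = 5,
                       undershoot_time = 14,
                       undershoot_ratio = 0.2,
                       peak_amplitude = 1,
                       deoxy_ratio = -1/3) {
  if (peak_time <= 0) stop("peak_time must be positive", call. = FALSE)
  if (undershoot_time <= peak_time)
    stop("undershoot_time must exceed peak_time", call. = FALSE)
  if (undershoot_ratio < 0) stop("undershoot_ratio must be >= 0", call. = FALSE)
  structure(list(peak_time = peak_time, undershoot_time = undershoot_time,
                 undershoot_ratio = undershoot_ratio,
                 peak_amplitude = peak_amplitude, deoxy_ratio = deoxy_ratio),
            class = "hrf_params")
}

#' Double-gamma hemodynamic response kernel
#'
#' Evaluates the peak-normalised double-gamma kernel: a gamma-density bump
#' peaking at `peak_time` minus a scaled gamma-density undershoot peaking at
#' `undershoot_time`, rescaled so the kernel's maximum is exactly 1. The
#' kernel is 0 at `t = 0` and decays toward 0 for large `t`.
#'
#' @param t Time in seconds since stimulus onset (vectorised, `t >= 0`).
#' @param params An [hrf_params()] object.
#' @return Unitless kernel values, max 1 at `peak_time`.
#' @export
hrf_kernel <- function(t, params = hrf_params()) {
  stopifnot(all(t >= 0))
  raw <- function(tt) .gamma_bump(tt, params$peak_time) -
    params$undershoot_ratio * .gamma_bump(tt, params$undershoot_time)
  peak <- raw(params$peak_time)
  raw(t) / peak
}

# Gamma-shaped bump with mode at `mode` (shape fixed at 6, rate solved from
# mode = (shape-1)/rate), normalised to 1 at its mode.
.gamma_bump <- function(t, mode, shape = 6) {
  rate <- (shape - 1) / mode
  stats::dgamma(t, shape = shape, rate = rate) /
    stats::dgamma(mode, shape = shape, rate = rate)
}
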