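#' Preprocessing parameters
#'
#' Parameters of the HOMER-style preprocessing cascade. Defaults are the
#' published recommendations for infant data that this package mirrors:
#' SNR threshold 2 for channel pruning; motion detection with a 1.0 s
#' sliding window, 1 s flag margin, amplitude threshold 4 OD and a
#' 15-fold standard-deviation criterion; spline smoothing parameter 0.99;
#' wavelet IQR multiplier 0.5; 0.01-0.09 Hz band-pass; partial pathlength
#' factor 1.
#'
#' @param snr_thresh SNR (mean/sd of raw intensity) below which a channel
#'   is pruned (default 2). A channel exactly at threshold is retained.
#' @param t_motion Motion-detection sliding-window length, seconds
#'   (default 1.0).
#' @param t_mask Margin flagged around each detected window, seconds
#'   (default 1).
#' @param amp_thresh Absolute within-window peak-to-peak OD threshold
#'   (default 4).
#' @param stdev_thresh Multiplier of the robust spread of the channel's
#'   sample-to-sample OD changes (default 15); a window containing a
#'   change larger than `stdev_thresh` times that spread is flagged (see
#'   [detect_motion()]).
#' @param spline_p Smoothing-spline parameter in `[0, 1]`; values near 1
#'   follow the artifact trajectory closely (default 0.99).
#' @param wavelet_iqr IQR multiplier for wavelet detail-coefficient
#'   fences (default 0.5).
#' @param band_low,band_high Band-pass corner frequencies in Hz
#'   (defaults 0.01 and 0.09).
#' @param ppf Partial pathlength factor for the Beer-Lambert inversion
#'   (default 1).
#' @return A `preprocess_params` object.
#' @export
preprocess_params <- function(snr_thresh = 2, t_motion = 1.0, t_mask = 1,
                              amp_thresh = 4, stdev_thresh = 15,
                              spline_p = 0.99, wavelet_iqr = 0.5,
                              band_low = 0.01, band_high = 0.09, ppf = 1) {
  if (spline_p < 0 || spline_p > 1) stop("spline_p must lie in [0, 1]", call. = FALSE)
  if (band_low <= 0 || band_high <= band_low)
    stop("need 0 < band_low < band_high", call. = FALSE)
  if (any(c(snr_thresh, t_motion, t_mask, amp_thresh, stdev_thresh,
            wavelet_iqr, ppf) <= 0))
    stop("thresholds must be positive", call. = FALSE)
  structure(list(snr_thresh = snr_thresh, t_motion = t_motion,
                 t_mask = t_mask, amp_thresh = amp_thresh,
                 stdev_thresh = stdev_thresh, spline_p = spline_p,
                 wavelet_iqr = wavelet_iqr, band_low = band_low,
                 band_high = band_high, ppf = ppf),
            class = "preprocess_params")
}

#' Prune low-SNR channels
#'
#' Computes the signal-to-noise ratio `mean(I) / sd(I)` of the raw
#' intensity per channel and wavelength; a channel is retained only if the
#' SNR is at or above `snr_thresh` at both wavelengths. Constant traces
#' (sd = 0) have infinite SNR and are retained; channels with any
#' non-positive intensity are flagged unavailable with a warning.
#'
#' @param scan A `nirs_scan`.
#' @param params A [preprocess_params()] object.
#' @return Logical vector (one per channel): `TRUE` = retained.
#' @export
prune_channels <- function(scan, params = preprocess_params()) {
  stopifnot(dim(scan$intensity)[1] > 0)
  n_ch <- dim(scan$intensity)[2]
  keep <- rep(TRUE, n_ch)
  for (c_i in seq_len(n_ch)) {
    for (w in seq_len(dim(scan$intensity)[3])) {
      x <- scan$intensity[, c_i, w]
      if (any(x <= 0)) {
        warning(sprintf("channel %s has non-positive intensities; marked unavailable",
                        scan$layout$channels$id[c_i]), call. = FALSE)
        keep[c_i] <- FALSE
        break
      }
      s <- stats::sd(x)
      snr <- if (s == 0) Inf else mean(x) / s
      if (snr < params$snr_thresh) keep[c_i] <- FALSE
    }
  }
  keep
}

#' Convert raw intensities to optical-density changes
#'
#' `dOD(t) = -ln(I(t) / mean_t(I))` per channel and wavelength (natural
#' logarithm — the convention of the reference processing stream this
#' package mirrors; note that a log10 dialect also exists in the field).
#' The temporal mean of each output trace is ~0 by construction.
#'
#' @param scan A `nirs_scan`.
#' @return Array `time x channel x wavelength` of OD changes.
#' @export
intensity_to_od <- function(scan) {
  arr <- scan$intensity
  n_ch <- dim(arr)[2]
  for (c_i in seq_len(n_ch)) {
    for (w in seq_len(dim(arr)[3])) {
      x <- arr[, c_i, w]
      bad <- which(x <= 0)
      if (length(bad) > 0)
        stop(sprintf("non-positive intensity in channel %s at sample %d",
                     scan$layout$channels$id[c_i], bad[1]), call. = FALSE)
      arr[, c_i, w] <- -log(x / mean(x))
    }
  }
  arr
}

#' Detect motion artifacts channel-wise
#'
#' For each channel, each sliding window of length `t_motion` is flagged if
#' its peak-to-peak OD change exceeds `amp_thresh` (absolute criterion) or
#' its largest sample-to-sample OD change exceeds `stdev_thresh` times a
#' trimmed spread estimate of the channel's OD changes (adaptive
#' criterion; the change statistic keeps the threshold insensitive to slow
#' physiological swings, and trimming the top 2% of |changes| keeps sparse
#' artifacts from inflating their own threshold). Detection runs at both
#' wavelengths; a sample is flagged for a channel if either wavelength
#' triggers. Flags are dilated by `t_mask` on both sides of each detected
#' window.
#'
#' @param od Array `time x channel x wavelength` of OD changes.
#' @param params A [preprocess_params()] object.
#' @param sampling_rate Sampling rate in Hz.
#' @return Logical matrix `time x channel`; `TRUE` = motion-contaminated.
#' @export
detect_motion <- function(od, params = preprocess_params(), sampling_rate) {
  stopifnot(all(is.finite(od)))
  n <- dim(od)[1]; n_ch <- dim(od)[2]
  w_len <- round(params$t_motion * sampling_rate)
  if (w_len < 2)
    stop("t_motion must span at least 2 samples at this sampling rate",
         call. = FALSE)
  m_len <- round(params$t_mask * sampling_rate)
  mask <- matrix(FALSE, n, n_ch)
  if (n < w_len) return(mask)
  for (c_i in seq_len(n_ch)) {
    for (w in seq_len(dim(od)[3])) {
      x <- od[, c_i, w]
      dx <- diff(x)
      sigma_diff <- .diff_spread(dx)
      p2p <- zoo::rollmax(x, w_len, align = "left") +
        zoo::rollmax(-x, w_len, align = "left")
      max_diff <- zoo::rollmax(abs(dx), w_len - 1L, align = "left")
      amp_hit <- p2p > params$amp_thresh
      sd_hit <- if (sigma_diff > 0)
        max_diff > params$stdev_thresh * sigma_diff else FALSE
      starts <- which(amp_hit | sd_hit)
      for (s in starts) {
        i0 <- max(1L, s - m_len)
        i1 <- min(n, s + w_len - 1L + m_len)
        mask[i0:i1, c_i] <- TRUE
      }
    }
  }
  mask
}

# Spread of the sample-to-sample change statistic, trimmed of the top 2%
# of |changes| so that artifacts (sparse by assumption) cannot inflate the
# detection threshold that is meant to catch them. A fully robust (MAD)
# estimate is deliberately not used: slope distributions of smooth
# hemodynamic signals are heavy-tailed and a median-based scale fires on
# clean data.
.diff_spread <- function(dx) {
  q <- stats::quantile(abs(dx), 0.98, names = FALSE)
  s <- stats::sd(dx[abs(dx) <= q])
  if (!is.finite(s) || s == 0) s <- stats::sd(dx)
  s
}

# contiguous runs of TRUE in a logical vector -> matrix of (start, end)
.runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Spline-based motion correction
#'
#' Within every flagged segment of every channel, a smoothing spline
#' (parameter `spline_p`; values near 1 track the artifact trajectory) is
#' fitted and subtracted, and the segment is re-anchored to the level of
#' the immediately preceding clean signal (the mean of up to 2 s of clean
#' samples; one-sided anchoring at recording edges). Unflagged samples are
#' never altered.
#'
#' @param od Array `time x channel x wavelength` of OD changes.
#' @param mask Logical `time x channel` motion mask from [detect_motion()].
#' @param params A [preprocess_params()] object.
#' @param sampling_rate Sampling rate in Hz.
#' @return Corrected OD array, same shape.
#' @export
spline_correct <- function(od, mask, params = preprocess_params(),
                           sampling_rate) {
  n <- dim(od)[1]
  stopifnot(nrow(mask) == n, ncol(mask) == dim(od)[2])
  anchor_len <- max(1L, round(2 * sampling_rate))
  for (c_i in seq_len(dim(od)[2])) {
    segs <- .runs(mask[, c_i])
    if (nrow(segs) == 0) next
    for (w in seq_len(dim(od)[3])) {
      x <- od[, c_i, w]
      for (s in seq_len(nrow(segs))) {
        a <- segs[s, "start"]; b <- segs[s, "end"]
        seg <- x[a:b]
        trend <- .spline_trend(seg, params$spline_p)
        # anchor to preceding clean level; one-sided at the start edge
        if (a > 1) {
          lo <- max(1L, a - anchor_len)
          anchor <- mean(x[lo:(a - 1L)])
        } else if (b < n) {
          hi <- min(n, b + anchor_len)
          anchor <- mean(x[(b + 1L):hi])
        } else anchor <- mean(seg)
        x[a:b] <- seg - trend + anchor
      }
      od[, c_i, w] <- x
    }
  }
  od
}

# smooth trajectory of a flagged segment; linear fallback for short runs
.spline_trend <- function(seg, p) {
  m <- length(seg)
  if (m < 8) return(rep(mean(seg), m))
  fit <- tryCatch(
    stats::smooth.spline(seq_len(m), seg, spar = max(0, 1 - p),
                         cv = FALSE, all.knots = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    co <- stats::lm.fit(cbind(1, seq_len(m)), seg)$coefficients
    co[1] + co[2] * seq_len(m)
  } else stats::predict(fit, seq_len(m))$y
}

#' Wavelet-based motion correction
#'
#' Per channel and wavelength the series is decomposed with an orthonormal
#' Daubechies-2 wavelet (periodic boundaries, after symmetric padding to a
#' power of two). At every thresholded detail level, coefficients outside
#' `[Q1 - iqr * IQR, Q3 + iqr * IQR]` of that level's coefficient
#' distribution are set to zero — transient artifacts concentrate in few
#' large coefficients — and the series is reconstructed at its original
#' length. Thresholding stops at the detail level whose passband reaches
#' the analysis band's upper cutoff (`band_high`): motion transients are
#' broadband and dominate the fine scales, while evoked hemodynamic
#' structure lives in the coarse scales, which are left untouched (as is
#' the approximation).
#'
#' @param od Array `time x channel x wavelength` of OD changes.
#' @param params A [preprocess_params()] object (`wavelet_iqr`,
#'   `band_high`).
#' @param sampling_rate Sampling rate in Hz (sets the level/frequency
#'   correspondence).
#' @return Corrected OD array, same shape.
#' @export
wavelet_correct <- function(od, params = preprocess_params(),
                            sampling_rate = 10) {
  n <- dim(od)[1]
  if (n < 8) {
    warning("series too short for wavelet decomposition; passed through",
            call. = FALSE)
    return(od)
  }
  # level j details span [fs / 2^(j+1), fs / 2^j]; threshold only levels
  # strictly above the analysis band
  max_lev <- max(1L, floor(log2(sampling_rate / params$band_high)) - 1L)
  for (c_i in seq_len(dim(od)[2]))
    for (w in seq_len(dim(od)[3]))
      od[, c_i, w] <- .wavelet_despike(od[, c_i, w], params$wavelet_iqr,
                                       max_lev)
  od
}

.wavelet_despike <- function(x, iqr_mult, max_lev = Inf) {
  n <- length(x)
  n2 <- 2^ceiling(log2(n))
  # symmetric (reflection) padding to a power of two
  pad <- n2 - n
  xp <- if (pad > 0) c(x, rev(x)[seq_len(pad)]) else x
  n_levels <- max(1L, min(as.integer(log2(n2)) - 3L, max_lev))
  dec <- .dwt(xp, n_levels)
  for (lev in seq_along(dec$details)) {
    d <- dec$details[[lev]]
    q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
    fence <- c(q[1] - iqr_mult * (q[2] - q[1]),
               q[2] + iqr_mult * (q[2] - q[1]))
    out_of_fence <- d < fence[1] | d > fence[2]
    # coefficients whose support touches the padding junction (end of the
    # real signal) or the periodic wrap carry boundary kinks, not motion;
    # exempt them so edge samples are reconstructed faithfully
    n_d <- length(d)
    j_end <- ceiling(n / 2^lev)
    guard <- unique(pmin(n_d, pmax(1L, c(1:3, (n_d - 2):n_d,
                                         (j_end - 2):(j_end + 3)))))
    out_of_fence[guard] <- FALSE
    d[out_of_fence] <- 0
    dec$details[[lev]] <- d
  }
  .idwt(dec)[seq_len(n)]
}

#' Re-detect residual artifacts and flag invalid blocks
#'
#' Runs [detect_motion()] on the corrected series with the same parameters
#' and marks a block invalid for a channel if its epoch window (`window$start`
#' to `window$end` seconds around onset) overlaps any flagged sample on that
#' channel, or falls outside the recording.
#'
#' @param od Corrected OD array `time x channel x wavelength`.
#' @param params A [preprocess_params()] object.
#' @param design A `block_design`.
#' @param sampling_rate Sampling rate in Hz.
#' @param window An [epoch_window()] (defines the per-block extent).
#' @return Logical matrix `block x channel`; `TRUE` = block valid.
#' @export
redetect_and_flag <- function(od, params = preprocess_params(), design,
                              sampling_rate, window = epoch_window()) {
  mask <- detect_motion(od, params, sampling_rate)
  n <- dim(od)[1]
  n_blocks <- nrow(design$events)
  valid <- matrix(TRUE, n_blocks, dim(od)[2])
  for (b in seq_len(n_blocks)) {
    i0 <- floor(design$events$onset[b] * sampling_rate) +
      round(window$start * sampling_rate) + 1L
    i1 <- floor(design$events$onset[b] * sampling_rate) +
      round(window$end * sampling_rate) + 1L
    if (i0 < 1 || i1 > n) { valid[b, ] <- FALSE; next }
    valid[b, ] <- !apply(mask[i0:i1, , drop = FALSE], 2, any)
  }
  valid
}

#' Zero-phase Butterworth band-pass filter
#'
#' 3rd-order Butterworth band-pass applied forward and backward
#' (zero-phase), per channel and wavelength.
#'
#' @param od Array `time x channel x wavelength` (or a plain matrix /
#'   vector, filtered along the first dimension).
#' @param params A [preprocess_params()] object (`band_low`, `band_high`).
#' @param sampling_rate Sampling rate in Hz.
#' @return Filtered array, same shape.
#' @export
bandpass_filter <- function(od, params = preprocess_params(), sampling_rate) {
  nyq <- sampling_rate / 2
  if (params$band_high >= nyq)
    stop("band_high must be below the Nyquist frequency", call. = FALSE)
  bf <- signal::butter(3, c(params$band_low, params$band_high) / nyq,
                       type = "pass")
  apply_fun <- function(x) signal::filtfilt(bf, x)
  if (is.null(dim(od))) return(apply_fun(od))
  out <- od
  if (length(dim(od)) == 2) {
    for (j in seq_len(ncol(od))) out[, j] <- apply_fun(od[, j])
  } else {
    for (c_i in seq_len(dim(od)[2]))
      for (w in seq_len(dim(od)[3]))
        out[, c_i, w] <- apply_fun(od[, c_i, w])
  }
  out
}

#' Convert optical density to hemoglobin concentration changes
#'
#' Inverts the modified Beer-Lambert law per channel and sample: solves the
#' 2x2 system `dOD(lambda) = d * ppf * (eps_oxy(lambda) dOxy +
#' eps_deoxy(lambda) dDeoxy)`. Exact inverse of [forward_beer_lambert()].
#' Concentrations are in uM under the package's extinction-table and
#' `ppf = 1` conventions; the absolute scale is conventional and cancels
#' in all t statistics.
#'
#' @param od Array `time x channel x wavelength` of OD changes.
#' @param extinction An [extinction_table()] object.
#' @param layout A [probe_layout()] object (distance).
#' @param ppf Partial pathlength factor (default 1).
#' @param sampling_rate Sampling rate in Hz (stored in the result).
#' @return An [hb_series()] object.
#' @export
od_to_conc <- function(od, extinction = extinction_table(),
                       layout = probe_layout(), ppf = 1, sampling_rate) {
  if (dim(od)[3] != 2)
    stop("both wavelengths are required to invert the Beer-Lambert system",
         call. = FALSE)
  Einv <- solve(extinction$matrix) / (layout$source_detector_distance * ppf)
  n <- dim(od)[1]; n_ch <- dim(od)[2]
  hb <- array(0, dim = c(n, n_ch, 2))
  for (c_i in seq_len(n_ch)) {
    conc <- od[, c_i, ] %*% t(Einv)     # n x 2: (oxy, deoxy)
    hb[, c_i, ] <- conc
  }
  hb_series(hb, sampling_rate, layout$channels$id)
}

#' Run the full preprocessing cascade on one scan
#'
#' Fixed stage order: channel pruning, optical-density conversion, motion
#' detection, spline correction, wavelet correction, residual-artifact
#' re-detection with per-block validity flagging, band-pass filtering,
#' Beer-Lambert conversion to concentration. Pruned channels are marked
#' unavailable (their block validity is all-`FALSE` and their concentration
#' traces are `NA`), never zero-filled.
#'
#' @param scan A `nirs_scan`.
#' @param params A [preprocess_params()] object.
#' @param extinction An [extinction_table()] object.
#' @param window An [epoch_window()] for block-validity flagging.
#' @return List: `hb` ([hb_series()], `NA` on pruned channels),
#'   `available` (logical per channel), `block_valid`
#'   (logical `block x channel`), `motion_mask` (first-pass detection),
#'   `log` (per-stage parameter/outcome record).
#' @export
preprocess_scan <- function(scan, params = preprocess_params(),
                            extinction = extinction_table(),
                            window = epoch_window()) {
  available <- prune_channels(scan, params)
  od <- intensity_to_od(scan)
  mask <- detect_motion(od, params, scan$sampling_rate)
  od_spline <- spline_correct(od, mask, params, scan$sampling_rate)
  od_wav <- wavelet_correct(od_spline, params, scan$sampling_rate)
  block_valid <- redetect_and_flag(od_wav, params, scan$design,
                                   scan$sampling_rate, window)
  od_band <- bandpass_filter(od_wav, params, scan$sampling_rate)
  hb <- od_to_conc(od_band, extinction, scan$layout, params$ppf,
                   scan$sampling_rate)
  hb$values[, !available, ] <- NA_real_
  block_valid[, !available] <- FALSE
  list(hb = hb, available = available, block_valid = block_valid,
       motion_mask = mask,
       log = list(order = c("prune", "od", "detect", "spline", "wavelet",
                            "redetect", "bandpass", "concentration"),
                  params = unclass(params),
                  pruned_channels = scan$layout$channels$id[!available],
                  n_flagged_samples = colSums(mask),
                  n_invalid_blocks = colSums(!block_valid)))
}
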