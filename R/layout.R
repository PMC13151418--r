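#' Lateral probe layout
#'
#' Describes the 24 lateral measurement channels (12 per hemisphere) of the
#' probe arrangement, with six region-of-interest (ROI) channels over the
#' superior temporal regions: channels 6, 7 and 9 on the right and 18, 19 and
#' 21 on the left. Channels 1-12 are taken as right-hemisphere, 13-24 as
#' left-hemisphere.
#'
#' @param roi_only If `TRUE`, restrict the layout to the six ROI channels
#'   (a reduced fast mode for simulation-heavy tests).
#' @param source_detector_distance Emitter-detector separation in cm
#'   (default 3).
#'
#' @return A `probe_layout` object: list with `channels` (data.frame
#'   `id`, `hemisphere`, `is_roi`) and `source_detector_distance`.
#' @export
probe_layout <- function(roi_only = FALSE, source_detector_distance = 3) {
  if (source_detector_distance <= 0)
    stop("source_detector_distance must be positive", call. = FALSE)
  roi_right <- c(6L, 7L, 9L)
  roi_left <- c(18L, 19L, 21L)
  channels <- data.frame(
    id = 1:24,
    hemisphere = rep(c("right", "left"), each = 12),
    is_roi = 1:24 %in% c(roi_right, roi_left)
  )
  if (roi_only) channels <- channels[channels$is_roi, , drop = FALSE]
  rownames(channels) <- NULL
  structure(list(channels = channels,
                 source_detector_distance = source_detector_distance),
            class = "probe_layout")
}

#' ROI channel ids
#'
#' @param layout A [probe_layout()] object.
#' @return Integer vector of ROI channel ids present in the layout.
#' @export
roi_channels <- function(layout = probe_layout()) {
  layout$channels$id[layout$channels$is_roi]
}

#' Extinction coefficient table
#'
#' Molar extinction coefficients of oxy- and deoxyhemoglobin at the two
#' measurement wavelengths (695 and 830 nm), interpolated from a standard
#' published compilation of hemoglobin absorption spectra. Units are
#' 1/(uM x cm) so that, with a 3 cm separation and partial pathlength factor
#' 1, micromolar concentration changes map to milli-OD scale optical-density
#' changes. The absolute concentration scale is a convention (t statistics
#' are scale invariant); the table can be overridden wholesale.
#'
#' @param wavelengths Numeric length-2 vector of wavelengths in nm.
#' @param eps_oxy,eps_deoxy Extinction coefficients of oxy-/deoxy-Hb at
#'   `wavelengths`, 1/(uM x cm).
#' @return An `extinction_table` object with fields `wavelengths`, `eps_oxy`,
#'   `eps_deoxy` and the 2x2 `matrix` (rows = wavelengths,
#'   columns = c(oxy, deoxy)).
#' @export
extinction_table <- function(wavelengths = c(695, 830),
                             eps_oxy = c(0.000310, 0.000974),
                             eps_deoxy = c(0.001820, 0.000693)) {
  if (length(wavelengths) != 2 || wavelengths[1] == wavelengths[2])
    stop("exactly two distinct wavelengths are required", call. = FALSE)
  m <- cbind(oxy = eps_oxy, deoxy = eps_deoxy)
  rownames(m) <- as.character(wavelengths)
  if (rcond(m) < 1e-12)
    stop("extinction matrix is singular; oxy and deoxy spectra must differ",
         call. = FALSE)
  structure(list(wavelengths = wavelengths, eps_oxy = eps_oxy,
                 eps_deoxy = eps_deoxy, matrix = m),
            class = "extinction_table")
}
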