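#' Write a scan container
#'
#' Serialises one participant's recording to a directory holding
#' `intensity.csv` (long format: `time_s`, `channel_id`, `wavelength_nm`,
#' `intensity`) and `meta.json` (design events, layout, sampling rate, seed
#' and, for synthetic scans, the ground-truth block amplitudes).
#'
#' @param scan A `nirs_scan` from [simulate_participant()].
#' @param dir Output directory (created if needed).
#' @param truth Optional ground-truth list; its `amplitudes` are stored in
#'   the metadata sidecar.
#' @return `dir`, invisibly.
#' @export
write_scan <- function(scan, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(scan$intensity)[1]
  ch <- scan$layout$channels$id
  long <- data.table::data.table(
    time_s = rep(scan$time, times = length(ch) * 2),
    channel_id = rep(rep(ch, each = n), times = 2),
    wavelength_nm = rep(scan$wavelengths, each = n * length(ch)),
    intensity = as.vector(scan$intensity)
  )
  data.table::fwrite(long, file.path(dir, "intensity.csv"))
  meta <- list(
    participant_id = scan$participant_id,
    sampling_rate = scan$sampling_rate,
    wavelengths = scan$wavelengths,
    seed = scan$seed,
    source_detector_distance = scan$layout$source_detector_distance,
    channels = scan$layout$channels,
    design_events = scan$design$events,
    design_total_duration = scan$design$total_duration
  )
  if (!is.null(truth))
    meta$truth_amplitudes <- list(channel_id = as.integer(rownames(truth$amplitudes)),
                                  HL = unname(truth$amplitudes[, "HL"]),
                                  LH = unname(truth$amplitudes[, "LH"]))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a scan container
#'
#' Inverse of [write_scan()]; reconstructs the `nirs_scan` object from the
#' long-format CSV and its JSON sidecar.
#'
#' @param dir Directory written by [write_scan()].
#' @return A `nirs_scan` object.
#' @export
read_scan <- function(dir) {
  csv <- file.path(dir, "intensity.csv")
  js <- file.path(dir, "meta.json")
  if (!file.exists(csv) || !file.exists(js))
    stop("not a scan container (missing intensity.csv or meta.json): ", dir,
         call. = FALSE)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  long <- data.table::fread(csv)
  ch <- as.integer(meta$channels$id)
  wl <- as.numeric(meta$wavelengths)
  tgrid <- sort(unique(long$time_s))
  n <- length(tgrid)
  arr <- array(NA_real_, dim = c(n, length(ch), 2))
  data.table::setorder(long, wavelength_nm, channel_id, time_s)
  arr[] <- long$intensity
  layout <- structure(list(
    channels = data.frame(id = ch, hemisphere = meta$channels$hemisphere,
                          is_roi = meta$channels$is_roi),
    source_detector_distance = meta$source_detector_distance
  ), class = "probe_layout")
  design <- structure(list(
    events = data.frame(condition = meta$design_events$condition,
                        onset = meta$design_events$onset,
                        duration = meta$design_events$duration),
    total_duration = meta$design_total_duration
  ), class = "block_design")
  structure(list(intensity = arr, time = tgrid,
                 sampling_rate = meta$sampling_rate, wavelengths = wl,
                 layout = layout, design = design,
                 participant_id = meta$participant_id, seed = meta$seed),
            class = "nirs_scan")
}
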