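#' Epoch window definition
#'
#' The analysis window around each block onset: epochs run from `start`
#' (pre-onset, negative) to `end` seconds with inclusive endpoints — at
#' 10 Hz the default window \[-3, 30\] s has 331 samples. The baseline
#' interval \[`start`, 0) (half-open, so the onset sample belongs to the
#' response) is used only for baseline correction; the statistic interval
#' \[0, `end`\] yields the per-block mean.
#'
#' @param start Window start relative to onset, seconds (default -3).
#' @param end Window end, seconds (default 30).
#' @return An `epoch_window` object.
#' @export
epoch_window <- function(start = -3, end = 30) {
  if (!(start < 0 && 0 <= end)) stop("need start < 0 <= end", call. = FALSE)
  structure(list(start = start, end = end), class = "epoch_window")
}

#' Exclusion-rule parameters
#'
#' @param min_valid_blocks_per_condition Minimum valid blocks per condition
#'   for a channel (ROI) to count as available (default 3).
#' @param min_available_rois Minimum available ROI channels for a
#'   participant to be retained (default 5 of the 6).
#' @return An `exclusion_params` object.
#' @export
exclusion_params <- function(min_valid_blocks_per_condition = 3,
                             min_available_rois = 5) {
  if (min_valid_blocks_per_condition < 1 || min_available_rois < 1)
    stop("exclusion thresholds must be >= 1", call. = FALSE)
  structure(list(min_valid_blocks_per_condition = min_valid_blocks_per_condition,
                 min_available_rois = min_available_rois),
            class = "exclusion_params")
}

#' Epoch a concentration series around block onsets
#'
#' Cuts one epoch per block on a shared relative-time grid (inclusive
#' endpoints at `window$start` and `window$end`) and subtracts each
#' epoch's pre-onset baseline (mean over \[`start`, 0)) per channel and
#' hemoglobin species. Blocks whose window leaves the recording are marked
#' invalid with a warning.
#'
#' @param hb An [hb_series()].
#' @param design A `block_design`.
#' @param window An [epoch_window()].
#' @param block_valid Optional logical `block x channel` validity matrix
#'   (from [redetect_and_flag()]); defaults to all valid.
#' @return An `epoch_set`: list with `epochs` (array
#'   `block x time x channel x 2`), `rel_time`, `condition` (per block),
#'   `valid` (`block x channel`), `channel_ids`.
#' @export
epoch_blocks <- function(hb, design, window = epoch_window(),
                         block_valid = NULL) {
  fs <- hb$sampling_rate
  offsets <- round(window$start * fs):round(window$end * fs)
  rel_time <- offsets / fs
  n_blocks <- nrow(design$events)
  n_ch <- length(hb$channel_ids)
  n <- dim(hb$values)[1]
  if (is.null(block_valid)) block_valid <- matrix(TRUE, n_blocks, n_ch)
  epochs <- array(NA_real_, dim = c(n_blocks, length(offsets), n_ch, 2))
  for (b in seq_len(n_blocks)) {
    i_on <- floor(design$events$onset[b] * fs) + 1L
    idx <- i_on + offsets
    if (idx[1] < 1 || idx[length(idx)] > n) {
      warning(sprintf("block %d epoch window leaves the recording; marked invalid", b),
              call. = FALSE)
      block_valid[b, ] <- FALSE
      next
    }
    e <- hb$values[idx, , , drop = FALSE]
    base_idx <- which(rel_time < 0)
    for (c_i in seq_len(n_ch))
      for (h in 1:2)
        e[, c_i, h] <- e[, c_i, h] - mean(e[base_idx, c_i, h])
    epochs[b, , , ] <- e
  }
  structure(list(epochs = epochs, rel_time = rel_time,
                 condition = design$events$condition,
                 valid = block_valid, channel_ids = hb$channel_ids),
            class = "epoch_set")
}

#' Per-participant summary statistics
#'
#' Averages valid epochs within each condition per channel and hemoglobin
#' species, then takes the mean over the statistic interval \[0, `end`\] s
#' — the windowed mean concentration change that feeds the group tests.
#' Cells with zero valid blocks are `NA`.
#'
#' @param epochs An `epoch_set` from [epoch_blocks()].
#' @param window The [epoch_window()] used for epoching.
#' @param excl An [exclusion_params()] object (recorded for availability).
#' @return A `participant_summary`: list with `summary` (data.frame:
#'   `channel`, `condition`, `hb`, `mean_change`, `n_valid_blocks`) and
#'   `roi_available` placeholder filled by [apply_exclusions()].
#' @export
participant_summary <- function(epochs, window = epoch_window(),
                                excl = exclusion_params()) {
  stat_idx <- which(epochs$rel_time >= 0)
  conds <- c("HL", "LH")
  hbs <- c("oxy", "deoxy")
  rows <- list()
  for (c_i in seq_along(epochs$channel_ids)) {
    for (cond in conds) {
      sel <- which(epochs$condition == cond & epochs$valid[, c_i])
      for (h in seq_along(hbs)) {
        mean_change <- if (length(sel) == 0) NA_real_ else {
          m <- epochs$epochs[sel, , c_i, h, drop = FALSE]
          dim(m) <- c(length(sel), length(epochs$rel_time))
          mean(colMeans(m)[stat_idx])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          channel = epochs$channel_ids[c_i], condition = cond, hb = hbs[h],
          mean_change = mean_change, n_valid_blocks = length(sel))
      }
    }
  }
  structure(list(summary = do.call(rbind, rows), excl = excl),
            class = "participant_summary")
}

#' Apply the cohort exclusion rules
#'
#' An ROI channel is available for a participant iff both conditions have
#' at least `min_valid_blocks_per_condition` valid blocks on it; a
#' participant is retained iff at least `min_available_rois` of the six ROI
#' channels are available. Produces the tidy cohort table consumed by the
#' inference module and a per-participant exclusion report.
#'
#' @param summaries List of `participant_summary` objects.
#' @param excl An [exclusion_params()] object.
#' @param layout A [probe_layout()] object (defines the ROI set).
#' @param participant_ids Character ids (default `sub-01`, ...).
#' @param age_group Label attached to every row (default `"5-month"`).
#' @return List: `cohort` (data.frame `participant`, `age_group`,
#'   `channel`, `hemisphere`, `condition`, `hb_type`, `mean_change`,
#'   `n_valid_blocks`, `roi_available`, `included`) and `report`
#'   (data.frame `participant`, `n_available_rois`, `included`, `reason`).
#' @export
apply_exclusions <- function(summaries, excl = exclusion_params(),
                             layout = probe_layout(),
                             participant_ids = NULL,
                             age_group = "5-month") {
  if (is.null(participant_ids))
    participant_ids <- sprintf("sub-%02d", seq_along(summaries))
  roi <- roi_channels(layout)
  hemi <- stats::setNames(layout$channels$hemisphere, layout$channels$id)
  cohort <- list(); report <- list()
  for (i in seq_along(summaries)) {
    s <- summaries[[i]]$summary
    # availability per channel: both conditions meet the valid-block minimum
    counts <- unique(s[s$hb == "oxy", c("channel", "condition", "n_valid_blocks")])
    avail <- vapply(unique(s$channel), function(ch) {
      cc <- counts[counts$channel == ch, ]
      nrow(cc) == 2 &&
        all(cc$n_valid_blocks >= excl$min_valid_blocks_per_condition)
    }, logical(1))
    names(avail) <- unique(s$channel)
    n_roi_avail <- sum(avail[as.character(roi)], na.rm = TRUE)
    included <- n_roi_avail >= excl$min_available_rois
    report[[i]] <- data.frame(
      participant = participant_ids[i], n_available_rois = n_roi_avail,
      included = included,
      reason = if (included) "" else
        sprintf("fewer than %d available ROIs (%d): ROI requires >= %d valid blocks per condition",
                excl$min_available_rois, n_roi_avail,
                excl$min_valid_blocks_per_condition))
    cohort[[i]] <- data.frame(
      participant = participant_ids[i], age_group = age_group,
      channel = s$channel, hemisphere = unname(hemi[as.character(s$channel)]),
      condition = s$condition, hb_type = s$hb, mean_change = s$mean_change,
      n_valid_blocks = s$n_valid_blocks,
      roi_available = s$channel %in% roi & avail[as.character(s$channel)],
      included = included)
  }
  list(cohort = do.call(rbind, cohort), report = do.call(rbind, report))
}
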