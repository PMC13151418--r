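#' Experimental design parameters
#'
#' Parameters of the alternating two-condition block design: `HL` (heavy-light)
#' and `LH` (light-heavy) stimulus blocks separated by silent baselines whose
#' durations are drawn from a small set of jittered values.
#'
#' @param n_blocks_per_condition Number of blocks per condition (default 7,
#'   i.e. 14 blocks in total).
#' @param block_duration Block duration in seconds (default 15).
#' @param soa Stimulus-onset asynchrony within a block in seconds (default 1.5).
#' @param stimuli_per_block Number of stimuli per block (default 10). Must
#'   satisfy `block_duration == stimuli_per_block * soa`.
#' @param baseline_choices Numeric vector of admissible silent-baseline
#'   durations in seconds (default `c(18, 20, 22)`).
#' @param first_condition_policy One of `"randomized"`, `"fixed_HL"`,
#'   `"fixed_LH"`: which condition the first block belongs to.
#'
#' @return An object of class `design_params`.
#' @export
design_params <- function(n_blocks_per_condition = 7,
                          block_duration = 15,
                          soa = 1.5,
                          stimuli_per_block = 10,
                          baseline_choices = c(18, 20, 22),
                          first_condition_policy = c("randomized", "fixed_HL", "fixed_LH")) {
  first_condition_policy <- match.arg(first_condition_policy)
  if (n_blocks_per_condition < 0 || n_blocks_per_condition != round(n_blocks_per_condition))
    stop("n_blocks_per_condition must be a non-negative integer", call. = FALSE)
  if (!isTRUE(all.equal(block_duration, stimuli_per_block * soa)))
    stop("block_duration must equal stimuli_per_block * soa", call. = FALSE)
  if (length(baseline_choices) == 0 || any(baseline_choices <= 0))
    stop("baseline_choices must be a non-empty set of positive durations", call. = FALSE)
  structure(list(
    n_blocks_per_condition = as.integer(n_blocks_per_condition),
    block_duration = block_duration,
    soa = soa,
    stimuli_per_block = as.integer(stimuli_per_block),
    baseline_choices = baseline_choices,
    first_condition_policy = first_condition_policy
  ), class = "design_params")
}

#' Generate a block design schedule
#'
#' Lays out `2 * n_blocks_per_condition` stimulus blocks in strictly
#' alternating condition order. Every block is preceded by a silent baseline
#' drawn uniformly (and independently) from `baseline_choices`. The schedule
#' is a pure function of `params` and `seed`.
#'
#' @param params A [design_params()] object.
#' @param seed Integer seed controlling baseline jitter and (under the
#'   `"randomized"` policy) the first condition.
#'
#' @return A `block_design` object: a list with `events` (data.frame with
#'   columns `condition`, `onset`, `duration`, seconds from recording start)
#'   and `total_duration` (end of the last block, seconds).
#' @export
make_block_design <- function(params, seed = 1L) {
  stopifnot(inherits(params, "design_params"))
  n_total <- 2L * params$n_blocks_per_condition
  if (n_total == 0L) {
    return(structure(list(
      events = data.frame(condition = character(0), onset = numeric(0),
                          duration = numeric(0)),
      total_duration = 0
    ), class = "block_design"))
  }
  withr::with_seed(seed, {
    first <- switch(params$first_condition_policy,
                    fixed_HL = "HL",
                    fixed_LH = "LH",
                    randomized = sample(c("HL", "LH"), 1L))
    gaps <- if (length(params$baseline_choices) == 1L) {
      rep(params$baseline_choices, n_total)
    } else {
      sample(params$baseline_choices, n_total, replace = TRUE)
    }
  })
  conditions <- rep(c(first, setdiff(c("HL", "LH"), first)), length.out = n_total)
  onsets <- cumsum(gaps + c(0, rep(params$block_duration, n_total - 1L)))
  events <- data.frame(condition = conditions,
                       onset = onsets,
                       duration = rep(params$block_duration, n_total))
  structure(list(events = events,
                 total_duration = onsets[n_total] + params$block_duration),
            class = "block_design")
}

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf("Block design: %d blocks (%s), total scheduled duration %.1f s\n",
              nrow(x$events),
              paste(sprintf("%d %s", table(x$events$condition),
                            names(table(x$events$condition))), collapse = ", "),
              x$total_duration))
  invisible(x)
}
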