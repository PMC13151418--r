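#' Run configuration for the full pipeline
#'
#' Bundles the per-stage parameter objects for a single reproducible run.
#' With all defaults the run mirrors the published processing stream this
#' package models: SNR-threshold pruning, OD conversion, motion
#' detection/correction, 0.01-0.09 Hz band-pass, Beer-Lambert inversion,
#' \[-3, 30\] s block averaging with the 3-valid-blocks / 5-available-ROIs
#' exclusion rules, and 10,000-repetition max-|t| permutation correction.
#'
#' @param simulation A [simulation_config()] (or `NULL` to analyse scans
#'   read from `scan_dir`).
#' @param scan_dir Directory of scan containers when `simulation` is `NULL`.
#' @param preprocess A [preprocess_params()] object.
#' @param window An [epoch_window()] object.
#' @param exclusion An [exclusion_params()] object.
#' @param inference An [inference_params()] object.
#' @param age_group Cohort label carried through the tables.
#' @param seed Master seed; overrides the seeds inside `simulation` and
#'   `inference` when not `NULL`.
#' @return A `run_config` object.
#' @export
run_config <- function(simulation = simulation_config(n_participants = 12),
                       scan_dir = NULL,
                       preprocess = preprocess_params(),
                       window = epoch_window(),
                       exclusion = exclusion_params(),
                       inference = inference_params(),
                       age_group = "5-month",
                       seed = NULL) {
  if (is.null(simulation) && is.null(scan_dir))
    stop("either a simulation config or a scan directory is required",
         call. = FALSE)
  if (!is.null(seed)) {
    if (!is.null(simulation)) simulation$seed <- as.integer(seed)
    inference$seed <- as.integer(seed)
  }
  structure(list(simulation = simulation, scan_dir = scan_dir,
                 preprocess = preprocess, window = window,
                 exclusion = exclusion, inference = inference,
                 age_group = age_group),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> preprocess -> block-average -> exclusions
#' -> channel-wise permutation-corrected tests in fixed order, optionally
#' writing the cohort table, results table and a JSON run manifest.
#'
#' @param config A [run_config()] object.
#' @param out_dir Optional output directory for `cohort.csv`,
#'   `results.csv`, `exclusions.csv` and `manifest.json`.
#' @return List: `cohort`, `results`, `exclusions`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  stage <- "simulate"
  res <- tryCatch({
    if (!is.null(config$simulation)) {
      sim <- simulate_cohort(config$simulation)
      scans <- sim$scans
    } else {
      dirs <- list.dirs(config$scan_dir, recursive = FALSE)
      scans <- lapply(dirs, read_scan)
    }
    extinction <- if (!is.null(config$simulation))
      config$simulation$extinction else extinction_table()

    stage <- "preprocess"
    summaries <- vector("list", length(scans))
    for (i in seq_along(scans)) {
      pp <- preprocess_scan(scans[[i]], config$preprocess, extinction,
                            config$window)
      stage <- "blockavg"
      ep <- epoch_blocks(pp$hb, scans[[i]]$design, config$window,
                         pp$block_valid)
      summaries[[i]] <- participant_summary(ep, config$window,
                                            config$exclusion)
      stage <- "preprocess"
    }

    stage <- "exclusions"
    layout <- scans[[1]]$layout
    exc <- apply_exclusions(summaries, config$exclusion, layout,
                            participant_ids = vapply(scans, `[[`, "",
                                                     "participant_id"),
                            age_group = config$age_group)

    stage <- "inference"
    results <- run_family_tests(exc$cohort, config$inference)
    list(scans = scans, cohort = exc$cohort, exclusions = exc$report,
         results = results)
  }, error = function(e) {
    stop(sprintf("pipeline failed in stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("nirsblock")),
    seed_simulation = if (!is.null(config$simulation)) config$simulation$seed,
    seed_inference = config$inference$seed,
    n_participants = length(res$scans),
    n_included = sum(res$exclusions$included),
    params = list(preprocess = unclass(config$preprocess),
                  window = unclass(config$window),
                  exclusion = unclass(config$exclusion),
                  inference = unclass(config$inference)),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$cohort, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    utils::write.csv(res$results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(res$exclusions, file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE)
    manifest$checksums <- as.list(tools::md5sum(
      file.path(out_dir, c("cohort.csv", "results.csv", "exclusions.csv"))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(cohort = res$cohort, results = res$results,
       exclusions = res$exclusions, manifest = manifest)
}

#' Render a plain-text results report
#'
#' Formats the channel-wise test results grouped by hemoglobin species,
#' age group and family, flagging corrected p values at the significance
#' level, with the conventional footnote that negative t values indicate a
#' decrease (or, for paired families, lower HL than LH concentration).
#'
#' @param results A `group_test_result` from [run_family_tests()].
#' @param manifest Optional manifest from [run_pipeline()] (adds a header).
#' @param alpha Highlighting level (default 0.05).
#' @param file Optional path; when given the report is also written there.
#' @return Character vector of report lines, invisibly when `file` is set.
#' @export
render_report <- function(results, manifest = NULL, alpha = 0.05,
                          file = NULL) {
  lines <- c("Channel-wise t-tests with max-|t| permutation correction",
             strrep("=", 56))
  if (!is.null(manifest))
    lines <- c(lines,
               sprintf("participants: %d (%d included), seed %s, package %s",
                       manifest$n_participants, manifest$n_included,
                       manifest$seed_inference, manifest$package_version))
  if (is.null(results) || nrow(results) == 0) {
    lines <- c(lines, "", "no families tested")
  } else {
    fam_label <- function(f) if (f == "HL-LH") "HL vs LH" else
      paste(f, "vs baseline")
    for (hb in unique(results$hb_type)) {
      lines <- c(lines, "", sprintf("%s-Hb", toupper(substr(hb, 1, 1)) |>
                                      paste0(substr(hb, 2, nchar(hb)))))
      for (ag in unique(results$age_group)) {
        for (fam in unique(results$family)) {
          sub <- results[results$hb_type == hb & results$age_group == ag &
                           results$family == fam, , drop = FALSE]
          if (nrow(sub) == 0) next
          lines <- c(lines, sprintf("  %s, %s:", ag, fam_label(fam)))
          sub <- sub[order(-abs(sub$t)), ]
          for (r in seq_len(nrow(sub))) {
            star <- if (sub$p_corrected[r] <= alpha) " *" else ""
            lines <- c(lines, sprintf(
              "    CH%-2d (%s)  t(%d) = %6.2f  d = %5.2f  p_unc = %.4f  p_corr = %.4f%s",
              sub$channel[r], sub$hemisphere[r], sub$df[r], sub$t[r],
              sub$d[r], sub$p_uncorrected[r], sub$p_corrected[r], star))
          }
        }
      }
    }
    lines <- c(lines, "",
               sprintf("* corrected p <= %g (max-|t| permutation null)", alpha),
               "Note: negative t values indicate a decrease relative to baseline",
               "(for HL vs LH families: lower concentration in HL than in LH).")
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
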