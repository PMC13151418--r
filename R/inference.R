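#' Inference parameters
#'
#' @param n_permutations Number of permutation repetitions for the max-|t|
#'   null (default 10000).
#' @param alpha Significance level used for reporting (default 0.05).
#' @param roi_channels Integer ids of the ROI channels the tests run over
#'   (default the six superior-temporal channels).
#' @param seed Master seed; each test family draws its own seed from it.
#' @return An `inference_params` object.
#' @export
inference_params <- function(n_permutations = 10000, alpha = 0.05,
                             roi_channels = c(6L, 7L, 9L, 18L, 19L, 21L),
                             seed = 1L) {
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  structure(list(n_permutations = as.integer(n_permutations), alpha = alpha,
                 roi_channels = as.integer(roi_channels),
                 seed = as.integer(seed)),
            class = "inference_params")
}

#' One-sample t-test against zero
#'
#' @param values Numeric vector of per-participant summary means.
#' @return List `t`, `df`, `p` (two-tailed).
#' @export
one_sample_t <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("zero variance: t statistic undefined", call. = FALSE)
  ht <- stats::t.test(values, mu = 0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Paired t-test between two conditions
#'
#' One-sample t-test on the within-participant differences `a - b`.
#'
#' @param cond_a,cond_b Matched per-participant summary means.
#' @return List `t`, `df`, `p` (two-tailed).
#' @export
paired_t <- function(cond_a, cond_b) {
  if (length(cond_a) != length(cond_b))
    stop("conditions must be matched per participant; lengths differ (",
         length(cond_a), " vs ", length(cond_b), ")", call. = FALSE)
  one_sample_t(cond_a - cond_b)
}

#' Cohen's d for one-sample / paired designs
#'
#' `d = mean / sd` of the values (or paired differences); equals
#' `t / sqrt(n)` and shares the sign of the t statistic.
#'
#' @param values Numeric vector of values or paired differences.
#' @return Numeric effect size.
#' @export
cohens_d <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 observations", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("zero variance: effect size undefined", call. = FALSE)
  mean(values) / s
}

# Vectorised channel-wise one-sample t statistics under a sign-flip matrix.
# X: participants x channels (NA = participant unavailable on a channel);
# S: permutations x participants of +/-1. Sign flips leave x^2 invariant,
# so per-permutation variances follow from the flipped means alone.
.flip_t_matrix <- function(X, S) {
  A <- !is.na(X)
  X0 <- ifelse(A, X, 0)
  n_j <- colSums(A)
  sumsq <- colSums(X0^2)
  M <- (S %*% X0) %*% diag(1 / n_j, length(n_j))        # perm x channel means
  varj <- sweep(-sweep(M^2, 2, n_j, `*`), 2, sumsq, `+`) # sumsq - n*M^2
  varj <- sweep(varj, 2, pmax(n_j - 1, 1), `/`)
  Tt <- M / sqrt(sweep(varj, 2, n_j, `/`))
  Tt[, n_j < 2] <- NA
  Tt
}

#' Max-|t| permutation null for one-sample families
#'
#' For each of `n_permutations` repetitions one Rademacher sign per
#' participant is applied jointly to all that participant's channels
#' (preserving the spatial correlation structure), channel-wise one-sample
#' t statistics are recomputed on the available participants, and the
#' maximum |t| over channels with at least 2 contributors is recorded.
#'
#' @param X Numeric matrix `participants x channels` of summary means
#'   (`NA` where a participant lacks the channel).
#' @param params An [inference_params()] object.
#' @param seed Seed for this family's sign stream (default `params$seed`).
#' @return A `permutation_null`: list `max_t` (length `n_permutations`),
#'   `n_permutations`, `seed`, `channels_used`.
#' @export
maxt_null_one_sample <- function(X, params = inference_params(),
                                 seed = params$seed) {
  X <- as.matrix(X)
  n_j <- colSums(!is.na(X))
  usable <- n_j >= 2
  if (any(!usable))
    warning("dropping ", sum(!usable),
            " channel(s) with < 2 contributing participants from the max",
            call. = FALSE)
  if (!any(usable)) stop("no channel has >= 2 participants", call. = FALSE)
  m <- params$n_permutations
  S <- withr::with_seed(seed,
    matrix(sample(c(-1, 1), m * nrow(X), replace = TRUE), m, nrow(X)))
  Tt <- .flip_t_matrix(X[, usable, drop = FALSE], S)
  structure(list(max_t = apply(abs(Tt), 1, max),
                 n_permutations = m, seed = seed,
                 channels_used = which(usable)),
            class = "permutation_null")
}

#' Max-|t| permutation null for paired families
#'
#' Random condition-label swaps per participant, applied jointly across
#' channels, are algebraically sign flips of the paired differences; the
#' null is therefore built by [maxt_null_one_sample()] on the difference
#' matrix, with the identical sign stream for a given seed.
#'
#' @param Xa,Xb Matched `participants x channels` matrices for the two
#'   conditions.
#' @param params An [inference_params()] object.
#' @param seed Seed for this family's swap stream.
#' @return A `permutation_null` (see [maxt_null_one_sample()]).
#' @export
maxt_null_paired <- function(Xa, Xb, params = inference_params(),
                             seed = params$seed) {
  if (!all(dim(Xa) == dim(Xb)))
    stop("condition matrices must be matched participant-for-participant",
         call. = FALSE)
  maxt_null_one_sample(Xa - Xb, params, seed)
}

#' Permutation-corrected p value
#'
#' Add-one smoothed tail proportion
#' `p = (1 + #\{null >= |t|\}) / (1 + n_permutations)`: monotone
#' non-increasing in |t| and never exactly zero.
#'
#' @param observed_t Observed t statistic (sign ignored).
#' @param null A `permutation_null`.
#' @return Corrected p value in (0, 1].
#' @export
corrected_p <- function(observed_t, null) {
  stopifnot(inherits(null, "permutation_null"), length(null$max_t) >= 1)
  (1 + sum(null$max_t >= abs(observed_t))) / (1 + null$n_permutations)
}

# family seed: stable offset per family index from the master seed
.family_seed <- function(master, idx) {
  as.integer((as.numeric(master) + 7907 * as.numeric(idx)) %% 2147483647)
}

#' Run all channel-wise test families on a cohort table
#'
#' For every family — age group x \{HL vs baseline, LH vs baseline,
#' HL vs LH\} x \{oxy, deoxy\} — computes channel-wise t statistics over
#' the ROI channels (one-sample against zero, or paired on HL - LH
#' differences), Cohen's d, two-tailed uncorrected p, and the corrected p
#' from that family's own max-|t| permutation null. Only participants with
#' `included = TRUE` and rows with `roi_available = TRUE` contribute.
#'
#' @param cohort Tidy cohort table from [apply_exclusions()].
#' @param params An [inference_params()] object.
#' @return A `group_test_result` data.frame: `hb_type`, `age_group`,
#'   `family`, `hemisphere`, `channel`, `n`, `t`, `df`, `d`,
#'   `p_uncorrected`, `p_corrected`.
#' @export
run_family_tests <- function(cohort, params = inference_params()) {
  cohort <- cohort[cohort$included, , drop = FALSE]
  families <- expand.grid(hb = c("oxy", "deoxy"),
                          contrast = c("HL", "LH", "HL-LH"),
                          age_group = unique(cohort$age_group),
                          stringsAsFactors = FALSE)
  out <- list()
  for (f in seq_len(nrow(families))) {
    hb <- families$hb[f]; contrast <- families$contrast[f]
    ag <- families$age_group[f]
    sub <- cohort[cohort$hb_type == hb & cohort$age_group == ag &
                    cohort$channel %in% params$roi_channels &
                    cohort$roi_available, , drop = FALSE]
    if (nrow(sub) == 0) { warning("empty family skipped: ",
                                  paste(ag, contrast, hb), call. = FALSE); next }
    X <- if (contrast == "HL-LH") {
      .cohort_matrix(sub, "HL", params$roi_channels) -
        .cohort_matrix(sub, "LH", params$roi_channels)
    } else .cohort_matrix(sub, contrast, params$roi_channels)
    n_j <- colSums(!is.na(X))
    if (!any(n_j >= 2)) { warning("family has no testable channel: ",
                                  paste(ag, contrast, hb), call. = FALSE); next }
    null <- maxt_null_one_sample(X, params,
                                 seed = .family_seed(params$seed, f))
    hemi <- stats::setNames(sub$hemisphere, sub$channel)
    for (j in seq_len(ncol(X))) {
      if (n_j[j] < 2) next
      x <- X[!is.na(X[, j]), j]
      tt <- one_sample_t(x)
      out[[length(out) + 1L]] <- data.frame(
        hb_type = hb, age_group = ag, family = contrast,
        hemisphere = unname(hemi[colnames(X)[j]]),
        channel = as.integer(colnames(X)[j]), n = n_j[j],
        t = tt$t, df = tt$df, d = cohens_d(x),
        p_uncorrected = tt$p, p_corrected = corrected_p(tt$t, null))
    }
  }
  res <- if (length(out) == 0) {
    data.frame(hb_type = character(0), age_group = character(0),
               family = character(0), hemisphere = character(0),
               channel = integer(0), n = integer(0), t = numeric(0),
               df = numeric(0), d = numeric(0), p_uncorrected = numeric(0),
               p_corrected = numeric(0))
  } else do.call(rbind, out)
  class(res) <- c("group_test_result", class(res))
  res
}

# participants x ROI-channel matrix of mean_change for one condition
.cohort_matrix <- function(sub, condition, roi) {
  sc <- sub[sub$condition == condition, , drop = FALSE]
  parts <- sort(unique(sub$participant))
  X <- matrix(NA_real_, length(parts), length(roi),
              dimnames = list(parts, as.character(roi)))
  idx <- cbind(match(sc$participant, parts), match(sc$channel, roi))
  X[idx] <- sc$mean_change
  X
}
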