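test_that("one-sample t matches the closed form and is antisymmetric", {
  r <- one_sample_t(c(1, 2, 3))
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  expect_equal(one_sample_t(-c(1, 2, 3))$t, -2 * sqrt(3), tolerance = 1e-12)
  expect_error(one_sample_t(c(0, 0, 0)), "variance")
  expect_error(one_sample_t(1), "at least 2")
})

test_that("paired t is the one-sample t on differences and swaps sign", {
  r <- paired_t(c(2, 1, 3), c(1, 1, 1))
  expect_equal(r$t, sqrt(3), tolerance = 1e-12)   # differences (1, 0, 2)
  expect_equal(r$df, 2)
  expect_equal(paired_t(c(1, 1, 1), c(2, 1, 3))$t, -sqrt(3),
               tolerance = 1e-12)
  expect_error(paired_t(c(1, 2), c(1, 2, 3)), "matched")
  expect_error(paired_t(c(1, 2), c(1, 2)), "variance")
})

test_that("Cohen's d is mean/sd and satisfies d = t/sqrt(n)", {
  expect_equal(cohens_d(c(1, 2, 3)), 2)
  expect_equal(cohens_d(c(1, 0, 2)), 1)
  set.seed(71)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1))
    expect_equal(cohens_d(x), one_sample_t(x)$t / sqrt(length(x)),
                 tolerance = 1e-12)
  }
})

test_that("corrected p follows the add-one counting convention", {
  null <- structure(list(max_t = as.numeric(1:10), n_permutations = 10L,
                         seed = 1L), class = "permutation_null")
  expect_equal(corrected_p(5.5, null), 6 / 11)
  expect_equal(corrected_p(-5.5, null), 6 / 11)    # two-tailed: |t|
  expect_equal(corrected_p(0, null), 1)
  expect_equal(corrected_p(100, null), 1 / 11)
  big <- structure(list(max_t = rep(0.5, 10000), n_permutations = 10000L,
                        seed = 1L), class = "permutation_null")
  expect_equal(corrected_p(3, big), 1 / 10001)
  # monotone non-increasing in |t|
  ts <- seq(0, 12, by = 0.5)
  ps <- vapply(ts, corrected_p, numeric(1), null = null)
  expect_true(all(diff(ps) <= 0))
})

test_that("the null has the configured length and the identity flip returns the observed t", {
  set.seed(72)
  X <- matrix(rnorm(8 * 6), 8, 6)
  null <- maxt_null_one_sample(X, inference_params(n_permutations = 500),
                               seed = 3)
  expect_length(null$max_t, 500)
  expect_true(all(null$max_t >= 0))
  expect_equal(maxt_null_one_sample(X, inference_params(), seed = 4)$n_permutations,
               10000)
  # all-positive signs reproduce the observed channel-wise t vector
  S <- matrix(1, 1, 8)
  t_obs <- vapply(1:6, function(j) one_sample_t(X[, j])$t, numeric(1))
  expect_equal(as.vector(nirsblock:::.flip_t_matrix(X, S)), t_obs,
               tolerance = 1e-12)
})

test_that("vectorised flip statistics agree with per-permutation t.test calls", {
  set.seed(73)
  X <- matrix(rnorm(7 * 3), 7, 3)
  X[c(2, 9)] <- NA                       # unbalanced availability
  S <- matrix(sample(c(-1, 1), 20 * 7, replace = TRUE), 20, 7)
  Tt <- nirsblock:::.flip_t_matrix(X, S)
  for (p in 1:20) for (j in 1:3) {
    x <- S[p, ] * X[, j]
    expect_equal(Tt[p, j], unname(t.test(x[!is.na(x)])$statistic),
                 tolerance = 1e-10)
  }
})

test_that("label-swap and sign-flip nulls are identical for the same seed", {
  set.seed(74)
  Xa <- matrix(rnorm(10 * 6), 10, 6)
  Xb <- matrix(rnorm(10 * 6), 10, 6)
  p <- inference_params(n_permutations = 200)
  n1 <- maxt_null_paired(Xa, Xb, p, seed = 9)
  n2 <- maxt_null_one_sample(Xa - Xb, p, seed = 9)
  expect_identical(n1$max_t, n2$max_t)
})

test_that("permutation nulls are deterministic in the seed", {
  set.seed(75)
  X <- matrix(rnorm(12 * 6), 12, 6)
  p <- inference_params(n_permutations = 300)
  expect_identical(maxt_null_one_sample(X, p, seed = 5)$max_t,
                   maxt_null_one_sample(X, p, seed = 5)$max_t)
  expect_false(identical(maxt_null_one_sample(X, p, seed = 5)$max_t,
                         maxt_null_one_sample(X, p, seed = 6)$max_t))
})

test_that("sampled corrected p matches exhaustive sign-flip enumeration", {
  # n small enough to enumerate all 2^n sign patterns exactly
  set.seed(76)
  cases <- list(matrix(rnorm(5), 5, 1),
                matrix(rnorm(10 * 2), 10, 2) + 0.4,
                matrix(rnorm(6 * 3), 6, 3))
  for (X in cases) {
    p_ex <- exhaustive_maxt_p(X)
    params <- inference_params(n_permutations = 10000)
    null <- maxt_null_one_sample(X, params, seed = 8)
    for (j in seq_len(ncol(X))) {
      t_obs <- one_sample_t(X[, j])$t
      p_mc <- corrected_p(t_obs, null)
      se <- sqrt(p_ex[j] * (1 - p_ex[j]) / 10000)
      expect_lt(abs(p_mc - p_ex[j]), 3 * se + 2 / 10001)
    }
  }
})

test_that("channels with too few contributors are dropped from the max", {
  set.seed(77)
  X <- cbind(rnorm(6), c(1.5, rep(NA, 5)))
  expect_warning(null <- maxt_null_one_sample(
    X, inference_params(n_permutations = 50), seed = 2), "dropping")
  expect_equal(null$channels_used, 1)
  X_bad <- matrix(c(1, NA, NA, 2), 2, 2)
  expect_error(suppressWarnings(
    maxt_null_one_sample(X_bad, inference_params(n_permutations = 10))),
    "no channel")
})

test_that("family tests produce the full factorial table on a two-group cohort", {
  cohort <- rbind(make_summary_cohort(n = 12, seed = 81, age_group = "5-month"),
                  make_summary_cohort(n = 12, seed = 82, age_group = "9-month"))
  deoxy <- cohort
  deoxy$hb_type <- "deoxy"
  deoxy$mean_change <- -0.3 * deoxy$mean_change
  cohort <- rbind(cohort, deoxy)
  res <- run_family_tests(cohort, inference_params(n_permutations = 200,
                                                   seed = 4))
  # 2 ages x 2 hb x (2 one-sample + 1 paired) families x 6 channels
  expect_equal(nrow(res), 2 * 2 * 3 * 6)
  one_sample <- res[res$family %in% c("HL", "LH"), ]
  expect_equal(nrow(one_sample), 8 * 6)
  expect_true(all(res$df == 11))
  expect_true(all(res$p_corrected > 0 & res$p_corrected <= 1))
  # corrected p never undercuts uncorrected p beyond Monte Carlo slack
  expect_true(all(res$p_corrected >= res$p_uncorrected - 0.1))
  # d = t / sqrt(n) algebra carried through the table
  expect_equal(res$d, res$t / sqrt(res$n), tolerance = 1e-10)
  # determinism of the full table
  res2 <- run_family_tests(cohort, inference_params(n_permutations = 200,
                                                    seed = 4))
  expect_identical(res$p_corrected, res2$p_corrected)
})

test_that("excluded participants and unavailable ROIs never reach the tests", {
  cohort <- make_summary_cohort(n = 10, seed = 83)
  cohort$included[cohort$participant == "sub-01"] <- FALSE
  cohort$roi_available[cohort$participant == "sub-02" &
                         cohort$channel == 6] <- FALSE
  # deoxy families are absent from this fixture and are skipped with a note
  suppressWarnings(
    res <- run_family_tests(cohort, inference_params(n_permutations = 100,
                                                     seed = 1)))
  expect_true(all(res$n[res$channel == 6] == 8))
  expect_true(all(res$n[res$channel != 6] == 9))
})
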