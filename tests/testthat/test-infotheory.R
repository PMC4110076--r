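test_that("equipopulated binning balances counts and degrades under
           ties", {
  set.seed(1)
  v <- runif(600)
  e <- equipopulated_bins(v, 6)
  counts <- tabulate(findInterval(v, e, left.open = TRUE) + 1, nbins = 6)
  expect_true(max(counts) - min(counts) <= 1)

  e1 <- equipopulated_bins(v, 1)
  expect_length(e1, 0)
  expect_warning(et <- equipopulated_bins(rep(3, 50), 6), "ties")
  expect_equal(attr(et, "n_bins_effective"), 1L)
})

test_that("plug-in MI is zero for identical response distributions and
           log2(S) for disjoint deterministic responses", {
  set.seed(2)
  shared <- rnorm(300)
  same <- list(shared, shared, shared)
  expect_equal(as.numeric(plugin_mi(same, n_bins = 6)), 0, tolerance = 1e-12)

  # seven equiprobable stimuli mapped to disjoint response ranges
  disjoint <- lapply(1:7, function(s) runif(42, s, s + 0.5))
  I <- plugin_mi(disjoint, n_bins = 7)
  expect_equal(as.numeric(I), log2(7), tolerance = 1e-12)
  expect_error(plugin_mi(list(1:5, numeric(0))), "empty")
})

test_that("plug-in MI matches direct summation over an explicit joint
           table", {
  # small discrete dataset with known counts per (stimulus, bin)
  responses <- list(
    c(0.1, 0.2, 0.8, 0.9, 1.4, 0.15),
    c(0.85, 1.3, 1.5, 0.18, 1.45, 1.35)
  )
  edges <- equipopulated_bins(unlist(responses), 3)
  counts <- vapply(responses, function(r) {
    tabulate(findInterval(r, edges, left.open = TRUE) + 1, nbins = 3)
  }, numeric(3))
  expect_equal(as.numeric(plugin_mi(responses, edges = edges)),
               brute_force_mi(counts), tolerance = 1e-12)
})

test_that("MI is bounded and invariant under monotone transforms", {
  set.seed(3)
  resp <- lapply(1:5, function(s) rnorm(40, mean = 0.3 * s))
  I <- as.numeric(plugin_mi(resp, n_bins = 6))
  expect_gte(I, 0)
  expect_lte(I, log2(5))
  # rank-based binning: any strictly monotone transform leaves MI unchanged
  I_exp <- as.numeric(plugin_mi(lapply(resp, exp), n_bins = 6))
  expect_equal(I, I_exp, tolerance = 1e-12)
})

test_that("analytic + bootstrap correction drives null information to
           zero while raw stays positive", {
  set.seed(4)
  # stimulus-independent responses: true MI = 0
  null_resp <- lapply(1:7, function(s) rnorm(50))
  bc <- bias_correct(null_resp, n_bins = 6, n_bootstrap = 150, seed = 9)
  expect_gt(bc$I_raw, 0)
  expect_lt(abs(bc$I_corrected_raw), 2 * bc$null_sd + 1e-3)
  expect_false(bc$undersampled)

  # analytic bias formula agrees with the occupied-bin count expression
  expect_equal(bc$bias_analytic,
               (7 * (6 - 1) - (6 - 1)) / (2 * 350 * log(2)),
               tolerance = 1e-9)
})

test_that("shuffled pairing of an informative dataset has (corrected)
           zero information", {
  set.seed(5)
  resp <- lapply(1:5, function(s) rnorm(40, mean = 0.5 * s))
  pooled <- unlist(resp)
  lab <- sample(rep(1:5, each = 40))
  shuffled <- split(pooled, lab)
  bc <- bias_correct(shuffled, n_bins = 6, n_bootstrap = 150, seed = 10)
  expect_lt(abs(bc$I_corrected_raw), 2.5 * bc$null_sd + 1e-3)
})

test_that("corrected and raw MI converge to the analytic channel MI for
           large samples", {
  effect <- 0.8
  noise <- 1
  exact <- surrogate_channel_mi(5, effect, noise, n_bins = 6)
  set.seed(6)
  resp <- lapply(1:5, function(s) exp(rnorm(2000, effect * (s - 1), noise)))
  bc <- bias_correct(resp, n_bins = 6, n_bootstrap = 60, seed = 11)
  expect_equal(bc$I_raw, exact, tolerance = 0.02)
  expect_equal(bc$I_corrected, exact, tolerance = 0.02)
})

test_that("mi_spectrum flags information only at the informative
           frequency", {
  effect_profile <- c(0, 0, 1.6, 0, 0)
  set.seed(7)
  ps <- surrogate_power_channel(4, effect_profile, noise = 0.6,
                                n_trials = 60, seed = 12)
  ms <- mi_spectrum(ps, n_bins = 6, n_bootstrap = 120, seed = 13)
  expect_true(ms$significant[3])
  expect_equal(which.max(ms$I_corrected), 3)
  # uninformative frequencies: corrected MI near zero
  expect_lt(max(ms$I_corrected[-3]), ms$I_corrected[3] / 4)
})

test_that("a stimulus-independent spectrum yields few false positives", {
  set.seed(8)
  ps <- surrogate_power_channel(5, rep(0, 12), noise = 1, n_trials = 30,
                                seed = 14)
  ms <- mi_spectrum(ps, n_bins = 6, n_bootstrap = 120, seed = 15)
  expect_lte(sum(ms$significant), 2) # ~5% of 12 frequencies
})

test_that("the sample-set container enforces its preconditions", {
  expect_error(power_sample_set(list(matrix(1:4, 2), matrix(1:6, 2)),
                                freqs = 1:2), "frequency grids")
  expect_error(power_sample_set(list(matrix(1:3, 1), matrix(1:3, 1)),
                                freqs = 1:3), "2 trials")
})
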