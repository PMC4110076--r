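test_that("Welch PSD localises a pure sinusoid and conserves variance", {
  fs <- 1000
  t <- (0:(4 * fs - 1)) / fs
  x <- sin(2 * pi * 60 * t)
  psd <- welch_psd(x, fs = fs, nperseg = 1000)
  expect_equal(psd$freqs[which.max(psd$power)], 60)
  # Parseval: integral of the one-sided density ~ signal variance
  expect_equal(sum(psd$power) * (psd$freqs[2] - psd$freqs[1]), var(x),
               tolerance = 0.05)
})

test_that("white-noise PSD is flat within sampling error", {
  set.seed(42)
  x <- rnorm(60000)
  psd <- welch_psd(x, fs = 1000, nperseg = 500)
  sel <- psd$freqs > 10 & psd$freqs < 480
  p <- psd$power[sel]
  # chi^2 sampling spread of an n_segments average; flat to 3 s.e.
  rel_se <- 1 / sqrt(psd$n_segments)
  expect_lt(abs(mean(p) - 2 * var(x) / 1000) / (2 * var(x) / 1000), 0.05)
  expect_lt(max(abs(p - mean(p))) / mean(p), 5 * rel_se)
  expect_error(welch_psd(x[1:100], fs = 1000, nperseg = 500), "shorter")
})

test_that("phase coherence of identical signals is 1 with zero phase", {
  set.seed(1)
  x <- rnorm(4000)
  co <- phase_coherence(x, x, fs = 1000, nperseg = 500)
  expect_true(all(abs(co$coherence - 1) < 1e-10))
  expect_true(all(abs(co$phase) < 1e-8))
  expect_gte(co$K, 2)
})

test_that("a pure delay appears as a phase ramp and the matching time
           shift", {
  fs <- 1000
  t <- (0:(8 * fs - 1)) / fs
  set.seed(2)
  # narrowband test signal centred at 40 Hz
  x <- as.numeric(stats::filter(rnorm(length(t) + 400), rep(1, 25),
                                sides = 1))[-(1:400)]
  x <- x * sin(2 * pi * 40 * t)
  d_samples <- 5 # 5 ms delay
  y <- c(rep(0, d_samples), x[1:(length(x) - d_samples)])
  co <- phase_coherence(x, y, fs = fs, nperseg = 1000)
  i40 <- which(co$freqs == 40)
  expect_gt(co$coherence[i40], 0.98)
  # x leads y by 5 ms: positive shift, phase 2*pi*f*d
  expect_equal(co$time_shift[i40], 5, tolerance = 0.15)
  expect_equal(co$phase[i40], 2 * pi * 40 * 5e-3, tolerance = 0.1)
})

test_that("implementation matches the brute-force per-segment DFT oracle
           to 1e-10", {
  set.seed(3)
  for (rep in 1:3) {
    x <- rnorm(600)
    y <- rnorm(600)
    co <- phase_coherence(x, y, fs = 100, nperseg = 200)
    bf <- brute_force_coherence(x, y, fs = 100, nperseg = 200)
    expect_lt(max(abs(co$coherence - bf$coherence)), 1e-10)
    resid <- Arg(exp(1i * (co$phase - bf$phase)))
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("chance-level coherence of independent noise matches
           sqrt(pi)/(2 sqrt(K))", {
  # Monte-Carlo oracle for the resultant length of K uniform phasors
  set.seed(4)
  K <- 40
  mc <- replicate(4000, Mod(mean(exp(2i * pi * runif(K)))))
  expect_equal(mean(mc), sqrt(pi) / (2 * sqrt(K)), tolerance = 0.02)

  # estimator on independent white noise at the same K
  cohs <- vapply(1:12, function(k) {
    set.seed(100 + k)
    # 20500 samples give 40 segments of 1000 at 50% overlap
    co <- phase_coherence(rnorm(20500), rnorm(20500), fs = 1000,
                          nperseg = 1000)
    stopifnot(co$K == K)
    mean(co$coherence[co$freqs > 20 & co$freqs < 450])
  }, numeric(1))
  expect_equal(mean(cohs), sqrt(pi) / (2 * sqrt(K)), tolerance = 0.12)
})

test_that("coherence is invariant to positive rescaling of either
           signal", {
  set.seed(5)
  x <- rnorm(3000)
  y <- rnorm(3000) + 0.5 * x
  a <- phase_coherence(x, y, fs = 1000, nperseg = 500)
  b <- phase_coherence(7.3 * x, y * 0.02, fs = 1000, nperseg = 500)
  expect_equal(a$coherence, b$coherence, tolerance = 1e-12)
  expect_equal(a$phase, b$phase, tolerance = 1e-10)
})

test_that("time shift conversion wraps phase to (-pi, pi]", {
  expect_equal(time_shift(0, 50), 0)
  # anti-phase at f: half the period
  expect_equal(time_shift(pi, 50), 1000 / (2 * 50))
  # just above pi wraps to a negative shift of equal magnitude
  eps <- 1e-6
  expect_equal(time_shift(pi + eps, 50), -time_shift(pi - eps, 50),
               tolerance = 1e-3)
  expect_true(is.na(time_shift(1, 0)))
})

test_that("significance threshold is four times the baseline mean", {
  base <- structure(list(freqs = seq(0, 100, by = 2),
                         coherence = rep(0.025, 51)),
                    class = "coherence_result")
  expect_equal(coherence_threshold(base, band = c(10, 100)), 0.1)
  expect_error(coherence_threshold(NULL), "baseline")
})

test_that("track_peaks finds constructed maxima in order and respects the
           threshold", {
  freqs <- seq(0, 100, by = 1)
  psd <- structure(list(freqs = freqs,
                        power = dnorm(freqs, 42, 4)),
                   class = "psd_result")
  two_bump <- 0.3 * dnorm(freqs, 38, 3) + 0.25 * dnorm(freqs, 64, 3)
  coh <- structure(list(freqs = freqs, coherence = two_bump / max(two_bump),
                        phase = rep(0.3, length(freqs)),
                        time_shift = time_shift(rep(0.3, length(freqs)),
                                                freqs)),
                   class = "coherence_result")
  pk <- track_peaks(psd, coh, band = c(30, 80), threshold = 0.2)
  expect_equal(pk$f_LFP, 42)
  expect_equal(pk$f_C, c(38, 64))
  expect_length(pk$extents, 2)
  # all-subthreshold coherence gives an empty peak list (valid result)
  pk2 <- track_peaks(psd, coh, band = c(30, 80), threshold = 2)
  expect_length(pk2$f_C, 0)
})

test_that("phase classification splits the cycle into in-phase,
           anti-phase and intermediate", {
  f <- 40 # T = 25 ms
  expect_equal(classify_phase(0.5, f), "in-phase")
  expect_equal(classify_phase(12.4, f), "anti-phase")
  expect_equal(classify_phase(-12, f), "anti-phase")
  expect_equal(classify_phase(6.3, f), "intermediate")
})
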