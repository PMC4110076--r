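#' Surrogate specification for coherent signal pairs
#'
#' @param f0 dominant frequency (Hz), inside (0, fs/2)
#' @param phase_lag mean phase of signal 1 relative to signal 2 (rad)
#' @param coherence_level expected phase coherence at `f0`, in `[0, 1]`
#' @param noise_floor standard deviation of the independent broadband noise
#' @param n_trials number of trial pairs
#' @param fs sampling rate (Hz)
#' @param duration per-trial duration (s)
#' @param phase_diffusion OU diffusion coefficient of the common phase
#'   (rad^2/s); mimics the finite self-coherence of network gamma
#' @return a `surrogate_spec` list
#' @export
surrogate_spec <- function(f0 = 50, phase_lag = 0, coherence_level = 1,
                           noise_floor = 1, n_trials = 10, fs = 1000,
                           duration = 2, phase_diffusion = 5) {
  stopifnot(f0 > 0, f0 < fs / 2, coherence_level >= 0,
            coherence_level <= 1, n_trials >= 1)
  structure(list(f0 = f0, phase_lag = phase_lag,
                 coherence_level = coherence_level,
                 noise_floor = noise_floor, n_trials = n_trials, fs = fs,
                 duration = duration, phase_diffusion = phase_diffusion),
            class = "surrogate_spec")
}

#' Generate a coherent pair of oscillatory surrogate signals
#'
#' Each trial contains narrowband oscillations at `f0` whose phase
#' diffuses slowly (Wiener process on the phase, mimicking the finite
#' self-coherence of network gamma) plus white noise. Trials come in two
#' kinds: exactly `round(coherence_level * n_trials)` trials (positions
#' drawn at random) are *locked*: there both signals observe the same
#' oscillation,
#' signal 1 advanced by `phase_lag`; in an unlocked trial the two signals
#' carry independent oscillations. The per-segment unit cross-spectrum
#' phasor at `f0` is therefore `exp(i*phase_lag)` (up to the small
#' white-noise jitter) in locked trials and uniformly distributed in
#' unlocked ones, so the expected phasor resultant equals the locked
#' fraction -- `coherence_level` up to the rounding of the trial count --
#' for any diffusion rate; the stratified (rather than binomial) locking
#' count keeps the across-seed mean tight. `coherence_level =
#' 0` yields independent signals whose estimated coherence sits at the
#' K-segment chance level; finite K adds the usual upward chance-level
#' bias to the estimate.
#'
#' @param spec a [surrogate_spec()]
#' @param seed RNG seed
#' @return list with elements `x`, `y` (lists of `n_trials` signal
#'   traces) and `locked` (logical per-trial locking indicators)
#' @export
surrogate_coherent_pair <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "surrogate_spec"))
  set.seed(seed)
  n <- round(spec$duration * spec$fs)
  t <- (seq_len(n) - 1) / spec$fs
  n_locked <- round(spec$coherence_level * spec$n_trials)
  locked <- rep(FALSE, spec$n_trials)
  locked[sample.int(spec$n_trials, n_locked)] <- TRUE
  xs <- vector("list", spec$n_trials)
  ys <- vector("list", spec$n_trials)
  for (k in seq_len(spec$n_trials)) {
    # oscillation phase: 2*pi*f0*t plus a Wiener process
    dphi <- stats::rnorm(n, 0, sqrt(spec$phase_diffusion / spec$fs))
    phi <- 2 * pi * spec$f0 * t + cumsum(dphi) +
      stats::runif(1, 0, 2 * pi)
    osc1 <- cos(phi + spec$phase_lag)
    osc2 <- if (locked[k]) cos(phi) else
      ind_osc(n, spec, seed * 1000 + k)
    xs[[k]] <- signal_trace(osc1 + stats::rnorm(n, 0, spec$noise_floor),
                            spec$fs, "LFP", 1)
    ys[[k]] <- signal_trace(osc2 + stats::rnorm(n, 0, spec$noise_floor),
                            spec$fs, "LFP", 2)
  }
  list(x = xs, y = ys, locked = locked)
}

# independent phase-diffusing oscillation at f0 (same marginal spectrum as
# the common component)
ind_osc <- function(n, spec, seed) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / spec$fs
  dphi <- stats::rnorm(n, 0, sqrt(spec$phase_diffusion / spec$fs))
  cos(2 * pi * spec$f0 * t + cumsum(dphi) + stats::runif(1, 0, 2 * pi))
}

#' Surrogate per-stimulus power samples with known information content
#'
#' Log-normal single-trial power values whose location parameter at each
#' frequency shifts linearly with the stimulus index:
#' `log P ~ Normal(mu0 + effect_profile(f) * (s - 1), noise^2)`. The exact
#' mutual information of the binned construction is computable by
#' integrating the known densities ([surrogate_channel_mi()]).
#'
#' @param n_stimuli number of stimuli (>= 2)
#' @param effect_profile numeric vector over frequencies: per-stimulus-step
#'   shift of log-power at each frequency (0 = no information)
#' @param noise standard deviation of log-power
#' @param n_trials trials per stimulus
#' @param freqs frequency grid (Hz); default `seq_along(effect_profile)`
#' @param seed RNG seed
#' @return a [power_sample_set()]
#' @export
surrogate_power_channel <- function(n_stimuli, effect_profile, noise = 1,
                                    n_trials = 50, freqs = NULL, seed = 1) {
  stopifnot(n_stimuli >= 2, n_trials >= 2)
  if (is.null(freqs)) freqs <- seq_along(effect_profile)
  stopifnot(length(freqs) == length(effect_profile))
  set.seed(seed)
  samples <- lapply(seq_len(n_stimuli), function(s) {
    mu <- effect_profile * (s - 1)
    m <- vapply(seq_along(freqs), function(fi) {
      exp(stats::rnorm(n_trials, mu[fi], noise))
    }, numeric(n_trials))
    matrix(m, nrow = n_trials)
  })
  power_sample_set(samples, freqs)
}

#' Exact mutual information of the binned log-normal channel
#'
#' Numerical-integration oracle for [surrogate_power_channel()]: given bin
#' edges in power space, the probability of each bin under stimulus s is
#' a difference of normal CDFs in log space, and the mutual information of
#' the discretised channel follows by direct summation. With `edges =
#' NULL` the population equipopulated edges (quantiles of the stimulus
#' mixture) are computed by numerically inverting the mixture CDF.
#'
#' @param n_stimuli number of stimuli
#' @param effect per-stimulus-step shift of log-power at the analysed
#'   frequency
#' @param noise standard deviation of log-power
#' @param n_bins number of equipopulated bins (used when `edges` is NULL)
#' @param edges optional interior bin edges in power space
#' @return exact mutual information (bits) of the binned channel
#' @export
surrogate_channel_mi <- function(n_stimuli, effect, noise, n_bins = 6,
                                 edges = NULL) {
  mus <- effect * (seq_len(n_stimuli) - 1)
  mix_cdf <- function(x) mean(stats::pnorm(x, mus, noise))
  if (is.null(edges)) {
    probs <- seq_len(n_bins - 1) / n_bins
    log_edges <- vapply(probs, function(p) {
      stats::uniroot(function(x) mix_cdf(x) - p,
                     lower = min(mus) - 10 * noise,
                     upper = max(mus) + 10 * noise,
                     tol = 1e-12)$root
    }, numeric(1))
  } else {
    log_edges <- log(edges)
    n_bins <- length(edges) + 1L
  }
  cuts <- c(-Inf, log_edges, Inf)
  Prs <- vapply(seq_len(n_stimuli), function(s) {
    diff(stats::pnorm(cuts, mus[s], noise))
  }, numeric(n_bins))
  Ps <- 1 / n_stimuli
  Pr <- rowMeans(Prs)
  terms <- Prs * log2(Prs / Pr)
  sum(Ps * terms[is.finite(terms)])
}

#' Reduced two-population fixture configurations
#'
#' Scaled-down versions of the reference two-population model used by the
#' test-suite and the worked examples: `tiny` (2 x 100 neurons, 1 s) for
#' smoke tests and `small` (2 x 400 neurons, 2 s) for regime tests. The
#' intra-population degree is N/10 (denser, in relative terms, than the
#' reference network, which stabilises the collective rhythm at small N)
#' and per-edge conductances scale inversely with the degree so each
#' neuron's summed synaptic conductance matches the reference network;
#' long-range out-degrees scale with population size.
#'
#' @param scale `"tiny"` or `"small"`
#' @param overrides optional profile overrides applied after scaling
#' @param coupling optional [coupling_spec()] (default: reference coupling)
#' @param protocol optional [stimulus_protocol()]
#' @return a [sim_config()]
#' @export
fixture_network <- function(scale = c("small", "tiny"), overrides = list(),
                            coupling = NULL, protocol = NULL) {
  scale <- match.arg(scale)
  ref <- default_profile()
  N <- if (scale == "tiny") 100 else 400
  dur <- if (scale == "tiny") 1 else 2
  k <- N / ref$network$N # size ratio vs reference
  deg <- max(4, round(N / 20) * 2) # N/10, even
  g_scale <- ref$network$mean_degree / deg # preserve summed conductance
  prof <- default_profile(list(
    network = list(N = N, mean_degree = deg),
    syn_ampa = list(g_max = ref$syn_ampa$g_max * g_scale),
    syn_gaba = list(g_max = ref$syn_gaba$g_max * g_scale),
    sim = list(duration = dur)
  ))
  prof <- modifyList(prof, overrides, keep.null = TRUE)
  if (is.null(coupling)) {
    coupling <- coupling_spec(degree_per_source = max(2, round(10 * k)))
  }
  # the stimulus protocol is not scaled down: the stimulated set is
  # clipped to the available long-range emitters at run time

  sim_config(profile = prof, coupling = coupling, protocol = protocol)
}
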