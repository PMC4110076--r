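#' Ornstein-Uhlenbeck rate-trace parameters
#'
#' The background drive to each neuron is an inhomogeneous Poisson train of
#' excitatory presynaptic events whose instantaneous rate follows an
#' Ornstein-Uhlenbeck (OU) process with stationary mean `nu0`, stationary
#' standard deviation `sigma`, and correlation time `tau_ou`; its power
#' spectrum is flat up to the cut-off frequency `1/(2*pi*tau_ou)` (in kHz
#' when `tau_ou` is in ms) and falls as a Lorentzian above it.
#'
#' @param nu0 mean rate (spikes/s), > 0
#' @param sigma stationary standard deviation of the rate (spikes/s), >= 0
#' @param tau_ou correlation time (ms), > 0
#' @param clip_at_zero clip negative rate excursions to zero (rates cannot
#'   be negative); clip events are counted on the returned trace
#' @return an `ou_params` list
#' @export
ou_params <- function(nu0 = 1500, sigma = 400, tau_ou = 16,
                      clip_at_zero = TRUE) {
  stopifnot(nu0 > 0, sigma >= 0, tau_ou > 0)
  structure(list(nu0 = nu0, sigma = sigma, tau_ou = tau_ou,
                 clip_at_zero = clip_at_zero),
            class = "ou_params")
}

#' Generate an OU rate trace
#'
#' Exact discretisation of the stationary OU process on a grid of step `dt`:
#' `nu[t+dt] = nu0 + a*(nu[t] - nu0) + sigma*sqrt(1-a^2)*z`, with
#' `a = exp(-dt/tau_ou)` and `z` standard normal. The initial value is drawn
#' from the stationary distribution, so the whole trace is stationary.
#'
#' @param p an [ou_params()] object
#' @param dt time step (ms)
#' @param T duration (s)
#' @param seed integer seed
#' @return numeric vector of rates (spikes/s), length `round(T*1000/dt)`,
#'   with attributes `dt`, `n_clipped`
#' @export
ou_rate_trace <- function(p, dt, T, seed = 1) {
  stopifnot(T > 0, dt > 0)
  n <- round(T * 1000 / dt)
  set.seed(seed)
  if (p$sigma == 0) {
    out <- rep(p$nu0, n)
    attr(out, "dt") <- dt
    attr(out, "n_clipped") <- 0L
    return(out)
  }
  a <- exp(-dt / p$tau_ou)
  s <- p$sigma * sqrt(1 - a^2)
  z <- stats::rnorm(n)
  x <- numeric(n)
  x[1] <- p$nu0 + p$sigma * z[1]
  for (i in 2:n) x[i] <- p$nu0 + a * (x[i - 1] - p$nu0) + s * z[i]
  n_clipped <- 0L
  if (p$clip_at_zero) {
    n_clipped <- sum(x < 0)
    x[x < 0] <- 0
  }
  attr(x, "dt") <- dt
  attr(x, "n_clipped") <- n_clipped
  x
}

#' Inhomogeneous Poisson spike train by per-bin thinning
#'
#' Draws one spike per bin with probability `rate * dt` (rate in spikes/s,
#' dt in ms). Requires `rate * dt < 1` everywhere; the default model step
#' keeps the probability below 0.1 so the thinning approximation is
#' accurate.
#'
#' @param rate_trace non-negative rate vector (spikes/s) with bin width `dt`
#' @param dt bin width (ms)
#' @param seed integer seed
#' @return spike times (ms)
#' @export
poisson_spikes <- function(rate_trace, dt, seed = 1) {
  stopifnot(all(rate_trace >= 0))
  prob <- rate_trace * dt / 1000
  if (any(prob >= 1)) {
    stop("poisson_spikes: rate * dt >= 1 in some bin; decrease dt")
  }
  set.seed(seed)
  hit <- stats::runif(length(prob)) < prob
  (which(hit) - 0.5) * dt
}

#' Stimulus protocol
#'
#' A set of external firing-rate increments applied, one per stimulus, to a
#' fixed subset of the emitter population's long-range projecting excitatory
#' neurons during a time window. The stimulated neurons receive background
#' rate `nu0 + rate_increments[s]` inside the window.
#'
#' @param rate_increments distinct, non-negative extra rates (spikes/s),
#'   one per stimulus; default seven increments uniformly spaced from 0 to
#'   `max_increment`
#' @param n_target_neurons number of emitter long-range excitatory neurons
#'   stimulated
#' @param window `(t_on, t_off)` in seconds
#' @param max_increment used only when `rate_increments` is `NULL`
#' @return a `stimulus_protocol` list
#' @export
stimulus_protocol <- function(rate_increments = NULL, n_target_neurons = 300,
                              window = c(0.2, 1.2), max_increment = 600) {
  if (is.null(rate_increments)) {
    rate_increments <- seq(0, max_increment, length.out = 7)
  }
  if (anyDuplicated(rate_increments) || any(rate_increments < 0)) {
    stop("stimulus_protocol: increments must be distinct and >= 0")
  }
  stopifnot(length(window) == 2, window[2] > window[1])
  structure(list(rate_increments = rate_increments,
                 n_target_neurons = as.integer(n_target_neurons),
                 window = window),
            class = "stimulus_protocol")
}

#' Apply a stimulus to a per-neuron rate schedule
#'
#' Takes the baseline per-neuron rate description and adds
#' `rate_increments[s]` to the selected target neurons inside the window.
#' The target set must be a subset of the emitter's long-range projecting
#' excitatory neurons.
#'
#' @param base_rate baseline rate trace (spikes/s) as from [ou_rate_trace()]
#' @param proto a [stimulus_protocol()]
#' @param s stimulus index (1-based into `rate_increments`)
#' @param dt trace step (ms)
#' @param T trace duration (s)
#' @return the modified rate trace for a stimulated neuron (unstimulated
#'   neurons keep `base_rate`)
#' @export
apply_stimulus <- function(base_rate, proto, s, dt, T) {
  stopifnot(s >= 1, s <= length(proto$rate_increments))
  inc <- proto$rate_increments[s]
  if (inc == 0) return(base_rate)
  n <- length(base_rate)
  i_on <- max(1L, floor(proto$window[1] * 1000 / dt) + 1L)
  i_off <- min(n, ceiling(proto$window[2] * 1000 / dt))
  if (i_on > n || i_off < 1 || i_on > i_off) return(base_rate)
  out <- base_rate
  out[i_on:i_off] <- out[i_on:i_off] + inc
  attributes(out) <- attributes(base_rate)
  out
}
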