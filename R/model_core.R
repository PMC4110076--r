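#' Voltage-dependent gating transition rates
#'
#' Wang-Buzsaki-type transition rates (1/ms) for the potassium activation
#' `n`, sodium activation `m` and sodium inactivation `h` gates, with the
#' temperature factor phi = 5 folded into the n and h rates. This kinetics
#' family is formulated with the fast sodium activation replaced by its
#' steady state (see [m_inf()]), and remains stable under explicit
#' integration at the default 0.05 ms step. Expressions of the form
#' `a*x / (1 - exp(-x/b))` have removable singularities which are evaluated
#' by their analytic limit (`a*b`), so the rates are finite and smooth at
#' every voltage.
#'
#' @param V membrane voltage (mV); finite, vectorised
#' @return a list with numeric components `alpha_n`, `beta_n`, `alpha_m`,
#'   `beta_m`, `alpha_h`, `beta_h`, each the same length as `V`
#' @export
gating_rates <- function(V) {
  if (!all(is.finite(V))) stop("gating_rates: V must be finite")
  list(
    alpha_n = vtrap(0.05, V + 34, 10),
    beta_n  = 0.625 * exp(-(V + 44) / 80),
    alpha_m = vtrap(0.1, V + 35, 10),
    beta_m  = 4 * exp(-(V + 60) / 18),
    alpha_h = 0.35 * exp(-(V + 58) / 20),
    beta_h  = 5 / (1 + exp(-(V + 28) / 10))
  )
}

# a * x / (1 - exp(-x/b)) with the removable singularity at x = 0 patched by
# its limit a*b; series expansion used in a narrow band for smoothness
vtrap <- function(a, x, b) {
  u <- x / b
  out <- numeric(length(x))
  small <- abs(u) < 1e-6
  out[small] <- a * b * (1 + u[small] / 2)
  out[!small] <- a * x[!small] / (1 - exp(-u[!small]))
  out
}

#' Steady-state activation of the sodium m-gate
#'
#' The fast sodium activation gate is replaced by its voltage-dependent
#' steady state `alpha_m/(alpha_m + beta_m)`, a sigmoid increasing in V.
#'
#' @inheritParams gating_rates
#' @return `m_inf(V)` in `[0, 1]`
#' @export
m_inf <- function(V) {
  r <- gating_rates(V)
  r$alpha_m / (r$alpha_m + r$beta_m)
}

#' Gating steady states and resting state
#'
#' @inheritParams gating_rates
#' @return `gating_inf`: list with `n`, `h` steady states.
#' @export
gating_inf <- function(V) {
  r <- gating_rates(V)
  list(n = r$alpha_n / (r$alpha_n + r$beta_n),
       h = r$alpha_h / (r$alpha_h + r$beta_h))
}

#' Resting membrane voltage
#'
#' Solves for the zero-current fixed point of the membrane equation with all
#' gates at steady state.
#'
#' @param p a [neuron_params()] object
#' @return resting voltage (mV)
#' @export
resting_voltage <- function(p) {
  f <- function(V) {
    g <- gating_inf(V)
    m <- m_inf(V)
    -p$g_Na * m^3 * g$h * (V - p$E_Na) - p$g_K * g$n^4 * (V - p$E_K) -
      p$g_L * (V - p$E_L)
  }
  # the membrane equation can have several fixed points (rest, threshold,
  # depolarised); take the most hyperpolarised one, i.e. the first
  # downward sign change of the steady-state current scanning from E_K
  grid <- seq(p$E_K + 1, p$E_Na - 1, by = 0.5)
  fv <- vapply(grid, f, numeric(1))
  i <- which(fv[-length(fv)] > 0 & fv[-1] <= 0)[1]
  if (is.na(i)) stop("resting_voltage: no stable fixed point found")
  stats::uniroot(f, lower = grid[i], upper = grid[i + 1], tol = 1e-10)$root
}

#' Membrane state derivative
#'
#' Right-hand side of the membrane equations with the sodium activation gate
#' at steady state:
#' `C_m dV/dt = -g_Na m_inf(V)^3 h (V - E_Na) - g_K n^4 (V - E_K)
#'  - g_L (V - E_L) + I_syn + I_ext`,
#' with first-order alpha/beta kinetics for `n` and `h`.
#'
#' @param state list with `V` (mV), `n`, `h` (both in `[0,1]`)
#' @param I_syn,I_ext synaptic and external currents (uA/cm^2), depolarising
#'   when positive
#' @param p a [neuron_params()] object
#' @return list with `dV`, `dn`, `dh` (per ms)
#' @export
membrane_derivative <- function(state, I_syn, I_ext, p) {
  stopifnot(is.finite(state$V), is.finite(I_syn), is.finite(I_ext))
  if (any(state$n < -1e-3) || any(state$n > 1 + 1e-3) ||
      any(state$h < -1e-3) || any(state$h > 1 + 1e-3)) {
    stop("membrane_derivative: gating variables must lie in [0, 1]")
  }
  r <- gating_rates(state$V)
  m <- r$alpha_m / (r$alpha_m + r$beta_m)
  I_ion <- -p$g_Na * m^3 * state$h * (state$V - p$E_Na) -
    p$g_K * state$n^4 * (state$V - p$E_K) -
    p$g_L * (state$V - p$E_L)
  list(
    dV = (I_ion + I_syn + I_ext) / p$C_m,
    dn = r$alpha_n * (1 - state$n) - r$beta_n * state$n,
    dh = r$alpha_h * (1 - state$h) - r$beta_h * state$h
  )
}

#' Synaptic conductance kernel
#'
#' Conductance time course after a presynaptic spike:
#' `g(t) = g_max * norm_c * (exp(-t/tau_d) - exp(-t/tau_r))`, zero at the
#' spike time and decaying back to zero.
#'
#' @param t_since_spike time since the presynaptic spike (ms), `>= 0`
#' @param sp a [synapse_params()] object
#' @return conductance (mS/cm^2)
#' @export
synaptic_kernel <- function(t_since_spike, sp) {
  stopifnot(all(t_since_spike >= 0))
  sp$g_max * sp$norm_c *
    (exp(-t_since_spike / sp$tau_d) - exp(-t_since_spike / sp$tau_r))
}

#' Synaptic current from a conductance
#'
#' `I = g * (E_syn - V)`: positive (depolarising) when the membrane sits
#' below the synaptic reversal potential.
#'
#' @param g conductance (mS/cm^2), `>= 0`
#' @param V membrane voltage (mV)
#' @param E_syn synaptic reversal potential (mV)
#' @return current (uA/cm^2)
#' @export
synaptic_current <- function(g, V, E_syn) {
  stopifnot(all(g >= 0))
  g * (E_syn - V)
}

#' Heun (stochastic predictor-corrector) integration step
#'
#' One trapezoidal predictor-corrector step for `dx/dt = f(t, x)` plus an
#' additive noise increment: the Euler predictor and the corrector both
#' receive the same noise increment, which is the Heun scheme for
#' Ornstein-Uhlenbeck-type additive noise. For smooth deterministic drift the
#' scheme is second-order accurate (one-step error O(dt^3)).
#'
#' @param x numeric state vector
#' @param t current time
#' @param dt step size (> 0)
#' @param drift function `(t, x) -> dx/dt`
#' @param noise additive noise increment vector (already scaled by its
#'   sqrt(dt) factor); default zero
#' @return the state vector after one step
#' @export
heun_step <- function(x, t, dt, drift, noise = 0) {
  stopifnot(dt > 0)
  f1 <- drift(t, x)
  x_pred <- x + dt * f1 + noise
  f2 <- drift(t + dt, x_pred)
  x_new <- x + dt * (f1 + f2) / 2 + noise
  if (any(!is.finite(x_new))) {
    bad <- which(!is.finite(x_new))[1]
    stop(sprintf("heun_step: non-finite state (component %d) at t = %g",
                 bad, t + dt))
  }
  x_new
}

#' Integrate an ODE with the Heun scheme
#'
#' Convenience driver used by the single-neuron tools and the convergence
#' tests; the network simulator uses the same scheme in compiled code.
#'
#' @inheritParams heun_step
#' @param x0 initial state
#' @param times increasing time grid (uniform spacing)
#' @return matrix with one row per time point
#' @export
heun_integrate <- function(x0, times, drift) {
  dt <- diff(times)
  out <- matrix(NA_real_, length(times), length(x0))
  out[1, ] <- x0
  x <- x0
  for (i in seq_along(dt)) {
    x <- heun_step(x, times[i], dt[i], drift)
    out[i + 1, ] <- x
  }
  out
}

#' Simulate one isolated neuron
#'
#' Integrates the single-neuron membrane equations under a constant external
#' current (optionally plus a user-supplied synaptic conductance trace), using
#' the same Heun scheme as the network simulator. Used for f-I curves and
#' calibration.
#'
#' @param p a [neuron_params()] object
#' @param I_ext constant external current (uA/cm^2) or a function of time
#' @param T duration (ms)
#' @param dt step (ms)
#' @param V0 initial voltage; default the resting voltage
#' @return list with `t`, `V`, `spikes` (upward 0 mV crossing times, 2 ms
#'   lockout)
#' @export
simulate_single_neuron <- function(p, I_ext = 0, T = 500, dt = 0.05,
                                   V0 = NULL) {
  if (is.null(V0)) V0 <- resting_voltage(p)
  g0 <- gating_inf(V0)
  Ifun <- if (is.function(I_ext)) I_ext else function(t) I_ext
  drift <- function(t, x) {
    d <- membrane_derivative(list(V = x[1], n = clamp01(x[2]),
                                  h = clamp01(x[3])),
                             I_syn = 0, I_ext = Ifun(t), p)
    c(d$dV, d$dn, d$dh)
  }
  times <- seq(0, T, by = dt)
  tr <- heun_integrate(c(V0, g0$n, g0$h), times, drift)
  V <- tr[, 1]
  spikes <- detect_spikes(V, times, thresh = 0, refractory = 2)
  list(t = times, V = V, n = tr[, 2], h = tr[, 3], spikes = spikes)
}

# upward threshold crossings with a refractory lockout (ms)
detect_spikes <- function(V, times, thresh = 0, refractory = 2) {
  up <- which(V[-1] >= thresh & V[-length(V)] < thresh) + 1
  if (length(up) == 0) return(numeric(0))
  keep <- c(TRUE, diff(times[up]) > refractory)
  # enforce lockout sequentially
  out <- numeric(0)
  last <- -Inf
  for (tt in times[up]) {
    if (tt - last > refractory) {
      out <- c(out, tt)
      last <- tt
    }
  }
  out
}

#' Calibrate the synaptic normalisation constant to a PSP target
#'
#' Scales `norm_c` so that a single presynaptic spike arriving at rest
#' deflects the postsynaptic membrane by `target_mv` (absolute peak
#' deflection, mV). Used to keep unitary postsynaptic potentials within
#' physiological range when the conductance scale is varied.
#'
#' @param sp a [synapse_params()] object
#' @param p postsynaptic [neuron_params()]
#' @param target_mv target absolute PSP amplitude (mV)
#' @param dt,T integration step and horizon (ms)
#' @return a new `synapse_params` with rescaled `norm_c`
#' @export
calibrate_norm_c <- function(sp, p, target_mv = 0.5, dt = 0.05, T = 60,
                             n_iter = 3) {
  for (k in seq_len(n_iter)) { # fixed-point iteration; PSP is mildly
    amp <- abs(psp_amplitude(sp, p, dt = dt, T = T)) # nonlinear in g
    if (amp <= 0) stop("calibrate_norm_c: zero PSP amplitude")
    sp$norm_c <- sp$norm_c * target_mv / amp
  }
  sp
}

#' Unitary PSP amplitude at rest
#'
#' Peak membrane deflection (signed, mV) produced by a single presynaptic
#' spike arriving at t = 0 on a neuron at rest.
#'
#' @inheritParams calibrate_norm_c
#' @return signed peak deflection (mV)
#' @export
psp_amplitude <- function(sp, p, dt = 0.05, T = 60) {
  Vr <- resting_voltage(p)
  g0 <- gating_inf(Vr)
  drift <- function(t, x) {
    g <- synaptic_kernel(t, sp)
    d <- membrane_derivative(list(V = x[1], n = clamp01(x[2]),
                                  h = clamp01(x[3])),
                             I_syn = synaptic_current(g, x[1], sp$E_syn),
                             I_ext = 0, p)
    c(d$dV, d$dn, d$dh)
  }
  times <- seq(0, T, by = dt)
  tr <- heun_integrate(c(Vr, g0$n, g0$h), times, drift)
  dev <- tr[, 1] - Vr
  dev[which.max(abs(dev))]
}

clamp01 <- function(x) pmin(1, pmax(0, x))
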