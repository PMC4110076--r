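test_that("gating rates are finite at singular points and match a
           high-precision evaluation", {
  # removable singularities: alpha_n at V = -34, alpha_m at V = -35 have
  # limits a*b
  r <- gating_rates(c(-34, -35))
  expect_equal(r$alpha_n[1], 0.05 * 10, tolerance = 1e-6)
  expect_equal(r$alpha_m[2], 0.1 * 10, tolerance = 1e-6)
  expect_true(all(is.finite(unlist(r))))

  # frozen values from an independent 30-digit symbolic evaluation of the
  # closed forms at V = -65 mV
  r65 <- gating_rates(-65)
  expect_equal(r65$alpha_n, 0.0731202737198945, tolerance = 1e-12)
  expect_equal(r65$beta_n, 0.812610292605307, tolerance = 1e-12)
  expect_equal(r65$alpha_m, 0.157187089473768, tolerance = 1e-12)
  expect_equal(r65$beta_m, 5.28077115373648, tolerance = 1e-12)
  expect_equal(r65$alpha_h, 0.496673642007640, tolerance = 1e-12)
  expect_equal(r65$beta_h, 0.120635107088346, tolerance = 1e-12)

  expect_error(gating_rates(NaN), "finite")
})

test_that("m_inf is a non-decreasing sigmoid bounded in [0, 1]", {
  V <- seq(-100, 40, by = 0.5)
  m <- m_inf(V)
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(diff(m) >= -1e-12))
  # all six rates non-negative over the physiological range
  r <- gating_rates(V)
  expect_true(all(unlist(r) >= 0))
})

test_that("membrane equation reduces to a leaky integrator when active
           conductances vanish", {
  p <- neuron_params(g_Na = 0, g_K = 0, g_L = 0.1, C_m = 1)
  tau <- p$C_m / p$g_L
  V0 <- p$E_L + 12
  drift <- function(t, x) {
    membrane_derivative(list(V = x[1], n = 0.3, h = 0.6), 0, 0, p)$dV
  }
  times <- seq(0, 40, by = 0.05)
  out <- heun_integrate(V0, times, function(t, x) drift(t, x))
  expect_equal(out[, 1], p$E_L + (V0 - p$E_L) * exp(-times / tau),
               tolerance = 1e-5)
})

test_that("derivatives vanish at the resting fixed point", {
  p <- neuron_params()
  Vr <- resting_voltage(p)
  g <- gating_inf(Vr)
  d <- membrane_derivative(list(V = Vr, n = g$n, h = g$h), 0, 0, p)
  expect_equal(d$dV, 0, tolerance = 1e-8)
  expect_equal(d$dn, 0, tolerance = 1e-10)
  expect_equal(d$dh, 0, tolerance = 1e-10)
})

test_that("f-I curve is monotone over a suprathreshold range", {
  p <- neuron_params()
  rates <- vapply(c(0.3, 0.6, 1.2, 2.4), function(I) {
    length(simulate_single_neuron(p, I_ext = I, T = 800)$spikes)
  }, numeric(1))
  expect_true(all(rates > 0))
  expect_true(all(diff(rates) > 0))
})

test_that("synaptic kernel has the documented shape", {
  sp <- synapse_params(tau_d = 5, tau_r = 0.7, g_max = 0.02, E_syn = 0)
  expect_equal(synaptic_kernel(0, sp), 0)
  # peak time: closed form vs numeric maximisation
  t_pk <- synaptic_kernel_peak_time(sp)
  opt <- optimize(function(t) synaptic_kernel(t, sp), c(0, 50),
                  maximum = TRUE)
  expect_equal(t_pk, sp$tau_r * sp$tau_d / (sp$tau_d - sp$tau_r) *
                 log(sp$tau_d / sp$tau_r))
  expect_equal(opt$maximum, t_pk, tolerance = 1e-4)
  # peak normalisation: kernel maximum equals g_max
  expect_equal(synaptic_kernel(t_pk, sp), sp$g_max, tolerance = 1e-10)
  # analytic integral
  num <- integrate(function(t) synaptic_kernel(t, sp), 0, Inf,
                   rel.tol = 1e-10)$value
  expect_equal(num, sp$g_max * sp$norm_c * (sp$tau_d - sp$tau_r),
               tolerance = 1e-8)
  # kernel decays to zero
  expect_lt(synaptic_kernel(200, sp), 1e-12)
  expect_error(synapse_params(tau_d = 0.5, tau_r = 2, g_max = 1,
                              E_syn = 0), "tau_d > tau_r")
})

test_that("synaptic current follows the conductance sign convention", {
  expect_equal(synaptic_current(0.5, -65, -65), 0)
  expect_gt(synaptic_current(0.5, -65, 0), 0)   # AMPA depolarising
  expect_lt(synaptic_current(0.5, -65, -80), 0) # GABA below rest
  expect_error(synaptic_current(-1, -65, 0))
})

test_that("conductances superpose linearly across presynaptic spikes", {
  sp <- synapse_params(tau_d = 2, tau_r = 0.5, g_max = 0.01, E_syn = 0)
  t <- seq(0, 20, by = 0.05)
  g1 <- synaptic_kernel(t, sp)
  g2 <- ifelse(t >= 3, synaptic_kernel(pmax(t - 3, 0), sp), 0)
  V <- -65
  expect_equal(synaptic_current(g1 + g2, V, sp$E_syn),
               synaptic_current(g1, V, sp$E_syn) +
                 synaptic_current(g2, V, sp$E_syn))
})

test_that("Heun scheme is exact on zero drift and second-order on
           dx/dt = -x", {
  expect_equal(heun_step(c(1, 2), 0, 0.1, function(t, x) 0 * x), c(1, 2))

  endpoint_err <- function(dt) {
    times <- seq(0, 2, by = dt)
    out <- heun_integrate(1, times, function(t, x) -x)
    abs(out[length(times), 1] - exp(-2))
  }
  e1 <- endpoint_err(0.05)
  e2 <- endpoint_err(0.025)
  expect_gt(e1 / e2, 3.5) # halving dt reduces error about 4x
  expect_lt(e1 / e2, 4.5)
})

test_that("Heun endpoint matches a matrix-exponential oracle on a linear
           system", {
  A <- matrix(c(0, 1, -4, -0.5), 2, 2, byrow = TRUE)
  x0 <- c(1, 0)
  Tend <- 3
  out <- heun_integrate(x0, seq(0, Tend, by = 0.01),
                        function(t, x) as.numeric(A %*% x))
  # closed form via eigendecomposition
  ev <- eigen(A)
  xT <- Re(ev$vectors %*% diag(exp(ev$values * Tend)) %*%
             solve(ev$vectors) %*% x0)
  expect_equal(out[nrow(out), ], as.numeric(xT), tolerance = 2e-3)
})

test_that("heun_step flags non-finite states with the failing component", {
  expect_error(
    heun_step(1, 0, 0.1, function(t, x) ifelse(t > 0, Inf, 1)),
    "non-finite state"
  )
})

test_that("PSP calibration hits the requested amplitude", {
  p <- neuron_params()
  sp <- synapse_params(tau_d = 2, tau_r = 0.5, g_max = 0.01, E_syn = 0)
  cal <- calibrate_norm_c(sp, p, target_mv = 0.5)
  expect_equal(abs(psp_amplitude(cal, p)), 0.5, tolerance = 1e-3)
})
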