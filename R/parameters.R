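#' Single-neuron membrane parameters
#'
#' Hodgkin-Huxley membrane parameters for one cell class. The default profile
#' uses Wang-Buzsaki-type sodium/potassium kinetics (see [gating_rates()]);
#' inhibitory cells are fast spiking, modelled with a smaller membrane
#' capacitance than excitatory cells.
#'
#' @param C_m membrane capacitance (uF/cm^2)
#' @param g_Na,g_K,g_L maximal conductances of the sodium, potassium and leak
#'   channels (mS/cm^2)
#' @param E_Na,E_K,E_L reversal potentials (mV); must satisfy
#'   `E_Na > E_L > E_K`
#' @return a `neuron_params` list
#' @export
neuron_params <- function(C_m = 1, g_Na = 35, g_K = 9, g_L = 0.1,
                          E_Na = 55, E_K = -90, E_L = -65) {
  stopifnot(C_m > 0, g_Na >= 0, g_K >= 0, g_L > 0)
  if (!(E_Na > E_L && E_L > E_K)) {
    stop("reversal potentials must satisfy E_Na > E_L > E_K")
  }
  structure(list(C_m = C_m, g_Na = g_Na, g_K = g_K, g_L = g_L,
                 E_Na = E_Na, E_K = E_K, E_L = E_L),
            class = "neuron_params")
}

#' Synapse kinetic parameters
#'
#' Difference-of-exponentials conductance kernel
#' `g(t) = g_max * norm_c * (exp(-t/tau_d) - exp(-t/tau_r))`.
#' `norm_c` is a dimensionless normalisation; [calibrate_norm_c()] sets it so
#' the kernel peak equals `g_max`.
#'
#' @param tau_d decay time constant (ms), must exceed `tau_r`
#' @param tau_r rise time constant (ms)
#' @param g_max peak conductance scale (mS/cm^2)
#' @param E_syn synaptic reversal potential (mV); 0 for AMPA (depolarising
#'   near rest), about -80 for GABA_A (hyperpolarising)
#' @param norm_c normalisation constant (dimensionless); `NULL` means
#'   peak-normalise so that `max_t g(t) = g_max`
#' @return a `synapse_params` list
#' @export
synapse_params <- function(tau_d, tau_r, g_max, E_syn, norm_c = NULL) {
  if (!(tau_d > tau_r && tau_r > 0)) {
    stop("synapse time constants must satisfy tau_d > tau_r > 0")
  }
  stopifnot(g_max >= 0)
  if (is.null(norm_c)) norm_c <- kernel_peak_norm(tau_d, tau_r)
  structure(list(tau_d = tau_d, tau_r = tau_r, g_max = g_max,
                 E_syn = E_syn, norm_c = norm_c),
            class = "synapse_params")
}

# normalisation that makes the double-exponential kernel peak at 1
kernel_peak_norm <- function(tau_d, tau_r) {
  t_pk <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  1 / (exp(-t_pk / tau_d) - exp(-t_pk / tau_r))
}

#' Time of the synaptic kernel maximum
#'
#' Closed form `tau_r*tau_d/(tau_d - tau_r) * log(tau_d/tau_r)` for the
#' difference-of-exponentials kernel.
#'
#' @param sp a [synapse_params()] object
#' @return peak time (ms)
#' @export
synaptic_kernel_peak_time <- function(sp) {
  sp$tau_r * sp$tau_d / (sp$tau_d - sp$tau_r) * log(sp$tau_d / sp$tau_r)
}

#' Default model profile
#'
#' The named parameter profile used throughout the package: Wang-Buzsaki HH
#' kinetics, AMPA and GABA_A difference-of-exponentials synapses, an
#' Ornstein-Uhlenbeck-modulated Poisson background drive, and the network
#' geometry defaults (small-world intra-population graph, excitatory
#' long-range projections). Conductance scales were calibrated once so that a
#' reduced two-population network sits in the balanced, sub-threshold
#' fluctuation regime with a gamma-band LFP peak whose period tracks the GABA
#' decay constant; the methods vignette documents the calibration.
#'
#' All values can be overridden via `overrides` (a named list, possibly
#' nested) or by editing a YAML copy (see [write_profile()] /
#' [read_profile()]).
#'
#' @param overrides named list merged over the defaults (nested lists merge
#'   recursively)
#' @return a nested list with elements `neuron_exc`, `neuron_inh`, `syn_ampa`,
#'   `syn_gaba`, `syn_ext`, `drive`, `network`, `coupling`, `sim`
#' @export
default_profile <- function(overrides = list()) {
  prof <- list(
    neuron_exc = list(C_m = 1, g_Na = 35, g_K = 9, g_L = 0.1,
                      E_Na = 55, E_K = -90, E_L = -65),
    neuron_inh = list(C_m = 0.5, g_Na = 35, g_K = 9, g_L = 0.1,
                      E_Na = 55, E_K = -90, E_L = -65),
    # recurrent + inter-areal AMPA
    syn_ampa = list(tau_d = 2, tau_r = 0.5, g_max = 0.0135, E_syn = 0),
    # GABA_A; stronger than AMPA so recurrent inhibition balances excitation
    syn_gaba = list(tau_d = 4.5, tau_r = 0.5, g_max = 0.055, E_syn = -80),
    # external Poisson drive synapse (AMPA kinetics)
    syn_ext  = list(tau_d = 2, tau_r = 0.5, g_max = 0.0060, E_syn = 0),
    drive = list(nu0 = 1500, sigma = 400, tau_ou = 16, clip_at_zero = TRUE,
                 shared_ou = TRUE, inh_drive_gain = 1.2),
    network = list(N = 2000, frac_exc = 0.8, mean_degree = 100,
                   rewiring_p = 0.3),
    coupling = list(frac_source_exc = 0.9, frac_target = 0.25,
                    tau_inter = 0, delay_mode = "gamma",
                    unidirectional = FALSE),
    sim = list(dt = 0.05, duration = 2, warmup = 0.2, fs_record = 1000,
               v_thresh = 0, refractory = 2)
  )
  modifyList(prof, overrides, keep.null = TRUE)
}

#' Write / read a model profile as YAML
#'
#' @param profile a profile list as returned by [default_profile()]
#' @param path file path
#' @return `read_profile` returns the profile list; `write_profile` returns
#'   `path` invisibly
#' @export
write_profile <- function(profile, path) {
  yaml::write_yaml(profile, path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  default_profile(yaml::read_yaml(path))
}

as_neuron_params <- function(x) do.call(neuron_params, x[names(x) %in%
  c("C_m", "g_Na", "g_K", "g_L", "E_Na", "E_K", "E_L")])

as_synapse_params <- function(x) do.call(synapse_params, x[names(x) %in%
  c("tau_d", "tau_r", "g_max", "E_syn", "norm_c")])
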