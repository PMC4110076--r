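# Shared heavy fixture experiments for the regime tests. Everything is
# memoised in the session cache (helper-cache.R) so several test files can
# reuse one set of simulations.

fx_coupled <- function(tau, dps = 6, overrides = list()) {
  fixture_network("small", overrides = overrides,
                  coupling = coupling_spec(tau_inter = tau,
                                           degree_per_source = dps))
}

# pooled LFP-LFP coherence of a record list
lfp_coherence <- function(recs, nperseg = 500) {
  phase_coherence(lapply(recs, compute_lfp, population = 1),
                  lapply(recs, compute_lfp, population = 2),
                  nperseg = nperseg)
}

# uncoupled baseline records (threshold definition), 10 trials
acc_baseline <- function() cached("acc_baseline", {
  cfg <- fx_coupled(0)
  cfg$coupling$degree_per_source <- 0
  suppressMessages(run_experiment(cfg, tau_grid = 0, n_trials = 10,
                                  master_seed = 9901))
})

# coupled pair at zero delay, 10 trials (in-phase regime; first trials
# also serve the gamma-emergence and locking tests)
acc_tau0 <- function() cached("acc_tau0", {
  suppressMessages(run_experiment(fx_coupled(0), tau_grid = 0,
                                  n_trials = 10, master_seed = 55))
})

# coupled pair near half a gamma period
acc_tau_half <- function() cached("acc_tau_half", {
  suppressMessages(run_experiment(fx_coupled(16), tau_grid = 16,
                                  n_trials = 10, master_seed = 55))
})

# GABA-decay variants for the rhythm-mechanism test (5 trials each)
acc_decay <- function(tau_d) cached(paste0("acc_decay_", tau_d), {
  cfg <- fx_coupled(0, overrides = list(syn_gaba = list(tau_d = tau_d)))
  suppressMessages(run_experiment(cfg, tau_grid = 0, n_trials = 5,
                                  master_seed = 100))
})

acc_threshold <- function() cached("acc_threshold", {
  coherence_threshold(lfp_coherence(acc_baseline()), band = c(10, 100))
})

# trial-averaged LFP PSD of a record list
lfp_avg_psd <- function(recs, population = 2, nperseg = 500) {
  psds <- lapply(recs, function(r) {
    welch_psd(compute_lfp(r, population), nperseg = nperseg)
  })
  out <- psds[[1]]
  out$power <- rowMeans(vapply(psds, `[[`, numeric(length(out$freqs)),
                               "power"))
  out
}
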