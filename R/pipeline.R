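#' Delay-sweep experiment: coherence and time shift over (f, tau)
#'
#' Runs `n_trials` paired-population simulations at every inter-areal delay
#' in `tau_grid`, plus uncoupled baseline trials defining the significance
#' threshold, and assembles the frequency-by-delay coherence and time-shift
#' matrices together with the per-delay peak classification.
#'
#' @param cfg a [sim_config()] for the coupled pair (its `tau_inter` is
#'   swept)
#' @param tau_grid inter-areal mean delays (ms)
#' @param n_trials trials per delay
#' @param n_baseline uncoupled trials for the significance threshold;
#'   defaults to `n_trials` so the baseline chance level is estimated at
#'   the same number of pooled segments K as the coupled estimates (the
#'   expected coherence of independent signals scales as 1/sqrt(K))
#' @param master_seed base seed
#' @param band gamma band for peak search (Hz)
#' @param nperseg Welch segment length (samples)
#' @param out_dir optional persistence directory passed to
#'   [run_experiment()]
#' @return a `tau_sweep` list: `freqs`, `tau_grid`, `coherence` and
#'   `time_shift` matrices (f x tau), `power` (f x tau, receiver LFP),
#'   `threshold`, `peaks` (per-tau [track_peaks()] results), `records`
#'   invisible-by-size (not stored), `table` tidy data.frame
#' @export
sweep_tau <- function(cfg, tau_grid, n_trials = 5, n_baseline = n_trials,
                      master_seed = 1, band = c(30, 80), nperseg = NULL,
                      out_dir = NULL) {
  # baseline: coupling off (no inter edges) -> chance-level coherence
  base_recs <- run_experiment(uncoupled_config(cfg), tau_grid = 0,
                              n_trials = n_baseline,
                              master_seed = master_seed + 7777,
                              out_dir = if (is.null(out_dir)) NULL else
                                file.path(out_dir, "baseline"))
  base_coh <- coherence_of_records(base_recs, nperseg = nperseg)
  threshold <- coherence_threshold(base_coh, band = c(10, 100))

  per_tau <- lapply(seq_along(tau_grid), function(ti) {
    recs <- run_experiment(cfg, tau_grid = tau_grid[ti],
                           n_trials = n_trials, master_seed = master_seed,
                           out_dir = out_dir)
    coh <- coherence_of_records(recs, nperseg = nperseg)
    psd <- average_psd(recs, population = 2, nperseg = nperseg)
    peaks <- track_peaks(psd, coh, band = band, threshold = threshold)
    list(coh = coh, psd = psd, peaks = peaks)
  })

  freqs <- per_tau[[1]]$coh$freqs
  coh_mat <- vapply(per_tau, function(p) p$coh$coherence, numeric(length(freqs)))
  ts_mat <- vapply(per_tau, function(p) p$coh$time_shift, numeric(length(freqs)))
  pw_mat <- vapply(per_tau, function(p) p$psd$power, numeric(length(freqs)))
  tab <- do.call(rbind, lapply(seq_along(tau_grid), function(ti) {
    p <- per_tau[[ti]]
    data.frame(tau = tau_grid[ti], f = freqs, power = p$psd$power,
               coherence = p$coh$coherence, phase = p$coh$phase,
               time_shift = p$coh$time_shift,
               significant = p$coh$coherence > threshold)
  }))
  structure(list(freqs = freqs, tau_grid = tau_grid, coherence = coh_mat,
                 time_shift = ts_mat, power = pw_mat,
                 threshold = threshold,
                 peaks = lapply(per_tau, `[[`, "peaks"), table = tab),
            class = "tau_sweep")
}

# coupling-off copy of a config (used for coherence baselines)
uncoupled_config <- function(cfg) {
  out <- cfg
  out$coupling$degree_per_source <- 0
  out
}

# pooled-trial phase coherence between the two populations' LFPs
coherence_of_records <- function(records, nperseg = NULL) {
  x <- lapply(records, compute_lfp, population = 1)
  y <- lapply(records, compute_lfp, population = 2)
  phase_coherence(x, y, nperseg = nperseg)
}

# trial-averaged Welch PSD of one population's LFP
average_psd <- function(records, population = 1, nperseg = NULL,
                        kind = c("LFP", "MUA")) {
  kind <- match.arg(kind)
  psds <- lapply(records, function(rec) {
    tr <- if (kind == "LFP") compute_lfp(rec, population) else
      compute_mua(rec, population)
    welch_psd(tr, nperseg = nperseg)
  })
  out <- psds[[1]]
  out$power <- rowMeans(vapply(psds, `[[`, numeric(length(out$freqs)),
                               "power"))
  out$n_segments <- sum(vapply(psds, `[[`, integer(1), "n_segments"))
  out
}

#' Stimulus-sweep experiment: mutual information spectra
#'
#' Runs the full stimulus protocol (every increment, `n_trials` trials
#' each) at each delay in `tau_grid` and computes the bias-corrected MI
#' spectrum of the receiver's LFP and MUA power.
#'
#' @param cfg a [sim_config()] whose `protocol` is set
#' @param tau_grid inter-areal delays (ms)
#' @param n_trials trials per (tau, stimulus)
#' @param master_seed base seed
#' @param n_bins,n_bootstrap MI estimator settings
#' @param receiver receiving population id
#' @param fmax analysis frequency cut-off (Hz)
#' @param out_dir optional persistence directory
#' @return a `stimulus_sweep` list: per-tau list with `mi_lfp`, `mi_mua`
#'   ([mi_spectrum()] frames) and a combined tidy `table`
#' @export
sweep_stimulus <- function(cfg, tau_grid, n_trials = 10, master_seed = 1,
                           n_bins = 6, n_bootstrap = 200, receiver = 2,
                           fmax = 120, out_dir = NULL) {
  if (is.null(cfg$protocol)) stop("sweep_stimulus: config has no protocol")
  S <- length(cfg$protocol$rate_increments)
  per_tau <- lapply(seq_along(tau_grid), function(ti) {
    recs <- run_experiment(cfg, tau_grid = tau_grid[ti],
                           stimulus_set = seq_len(S), n_trials = n_trials,
                           master_seed = master_seed, out_dir = out_dir)
    win <- cfg$protocol$window
    mi_l <- mi_spectrum(power_samples_from_records(
      recs, population = receiver, kind = "LFP", window = win,
      fmax = fmax), n_bins = n_bins, n_bootstrap = n_bootstrap,
      seed = master_seed + 31 * ti)
    mi_m <- mi_spectrum(power_samples_from_records(
      recs, population = receiver, kind = "MUA", window = win,
      fmax = fmax), n_bins = n_bins, n_bootstrap = n_bootstrap,
      seed = master_seed + 31 * ti + 1)
    list(mi_lfp = mi_l, mi_mua = mi_m)
  })
  tab <- do.call(rbind, lapply(seq_along(tau_grid), function(ti) {
    rbind(
      cbind(tau = tau_grid[ti], kind = "LFP", per_tau[[ti]]$mi_lfp),
      cbind(tau = tau_grid[ti], kind = "MUA", per_tau[[ti]]$mi_mua)
    )
  }))
  structure(list(tau_grid = tau_grid, per_tau = per_tau, table = tab),
            class = "stimulus_sweep")
}

#' Report a sweep as tidy CSV tables
#'
#' Writes the tidy (tau, f) tables of a [sweep_tau()] or [sweep_stimulus()]
#' result, with the in-phase/anti-phase classification column for coherence
#' sweeps. Rerunning on the same object writes byte-identical files.
#'
#' @param sweep a `tau_sweep` or `stimulus_sweep`
#' @param dir output directory (created if needed)
#' @return invisible character vector of files written
#' @export
report_sweep <- function(sweep, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  if (inherits(sweep, "tau_sweep")) {
    tab <- sweep$table
    tab$classification <- "n.s."
    for (ti in seq_along(sweep$tau_grid)) {
      pk <- sweep$peaks[[ti]]
      for (j in seq_along(pk$f_C)) {
        sel <- tab$tau == sweep$tau_grid[ti] & tab$f == pk$f_C[j]
        tab$classification[sel] <- classify_phase(pk$time_shift_at_peaks[j],
                                                  pk$f_C[j])
      }
    }
    f <- file.path(dir, "coherence_sweep.csv")
    write_csv_canonical(tab, f)
    files <- c(files, f)
    pk_tab <- do.call(rbind, lapply(seq_along(sweep$tau_grid), function(ti) {
      pk <- sweep$peaks[[ti]]
      if (length(pk$f_C) == 0) {
        return(data.frame(tau = sweep$tau_grid[ti], f_LFP = pk$f_LFP,
                          f_C = NA_real_, coherence = NA_real_,
                          time_shift = NA_real_,
                          classification = "n.s."))
      }
      data.frame(tau = sweep$tau_grid[ti], f_LFP = pk$f_LFP, f_C = pk$f_C,
                 coherence = pk$coherence_at_peaks,
                 time_shift = pk$time_shift_at_peaks,
                 classification = vapply(seq_along(pk$f_C), function(j)
                   classify_phase(pk$time_shift_at_peaks[j], pk$f_C[j]),
                   character(1)))
    }))
    f2 <- file.path(dir, "coherence_peaks.csv")
    write_csv_canonical(pk_tab, f2)
    files <- c(files, f2)
  } else if (inherits(sweep, "stimulus_sweep")) {
    f <- file.path(dir, "mi_sweep.csv")
    write_csv_canonical(sweep$table, f)
    files <- c(files, f)
  } else {
    stop("report_sweep: unknown sweep object")
  }
  invisible(files)
}

# deterministic CSV writer (fixed significant digits, no row names)
write_csv_canonical <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  utils::write.csv(df, path, row.names = FALSE)
}
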