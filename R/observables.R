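#' Signal trace container
#'
#' @param values sampled signal
#' @param fs sampling rate (Hz)
#' @param kind `"LFP"` or `"MUA"`
#' @param population population id (1 or 2)
#' @return a `signal_trace` numeric vector with attributes
#' @export
signal_trace <- function(values, fs, kind = c("LFP", "MUA"), population = 1) {
  kind <- match.arg(kind)
  stopifnot(all(is.finite(values)), fs > 0)
  structure(as.numeric(values), fs = fs, kind = kind,
            population = population, class = "signal_trace")
}

#' Local field potential from a simulation record
#'
#' The LFP proxy is the electrode resistance times the average, over the
#' population's excitatory neurons, of the absolute excitatory plus absolute
#' inhibitory synaptic current: `LFP(t) = R_e * <|I_exc| + |I_inh|>_E`. The
#' excitatory term includes both the external Poisson drive and the
#' recurrent (plus inter-areal) AMPA current; the inhibitory term is the
#' recurrent GABA current. `R_e` only scales the amplitude and cancels in
#' coherence and information measures.
#'
#' @param rec a `simulation_record` from [run_trial()]
#' @param population 1 or 2
#' @param R_e electrode resistance (MOhm); with currents in uA/cm^2 the LFP
#'   is reported in arbitrary units proportional to mV
#' @return a `signal_trace` of kind `"LFP"` sampled at `rec$fs`
#' @export
compute_lfp <- function(rec, population = 1, R_e = 1) {
  if (is.null(rec$I_exc_abs) || is.null(rec$I_inh_abs)) {
    stop("compute_lfp: record does not contain current traces")
  }
  p <- population
  vals <- R_e * (rec$I_exc_abs[, p] + rec$I_inh_abs[, p]) / rec$n_exc[p]
  signal_trace(vals, rec$fs, "LFP", p)
}

#' Multi-unit activity from a simulation record
#'
#' Total number of spikes per unit time across all neurons of the
#' population, in spikes/s, on a regular grid of bin width `bin` ms.
#'
#' @param rec a `simulation_record`
#' @param population 1 or 2
#' @param bin bin width (ms), at least the integration step
#' @return a `signal_trace` of kind `"MUA"` sampled at `1000/bin` Hz
#' @export
compute_mua <- function(rec, population = 1, bin = 1) {
  stopifnot(bin >= rec$dt)
  idx <- which(rec$pop_of == population - 1)
  spikes <- unlist(rec$spikes[idx], use.names = FALSE)
  T_ms <- rec$duration * 1000
  breaks <- seq(0, T_ms, by = bin)
  if (breaks[length(breaks)] < T_ms) breaks <- c(breaks, T_ms)
  counts <- if (length(spikes)) {
    tabulate(findInterval(spikes, breaks, left.open = TRUE,
                          rightmost.closed = TRUE),
             nbins = length(breaks) - 1)
  } else {
    integer(length(breaks) - 1)
  }
  signal_trace(counts / (bin / 1000), 1000 / bin, "MUA", population)
}

#' Per-neuron firing rates
#'
#' @param rec a `simulation_record`
#' @param population 1, 2 or `NULL` for all neurons
#' @return numeric vector of rates (spikes/s)
#' @export
firing_rates <- function(rec, population = NULL) {
  idx <- if (is.null(population)) seq_along(rec$spikes) else
    which(rec$pop_of == population - 1)
  vapply(rec$spikes[idx], length, integer(1)) / rec$duration
}

#' Coefficient of variation of inter-spike intervals
#'
#' Pooled per-neuron ISI CV for neurons with at least `min_spikes` spikes.
#' In the balanced sub-threshold fluctuation regime single neurons fire
#' irregularly (CV above 0.5) even while the population oscillates.
#'
#' @param rec a `simulation_record`
#' @param population 1, 2 or `NULL`
#' @param min_spikes minimum spikes per neuron to compute a CV
#' @return named list: `per_neuron` CVs and their `median`
#' @export
isi_cv <- function(rec, population = NULL, min_spikes = 5) {
  idx <- if (is.null(population)) seq_along(rec$spikes) else
    which(rec$pop_of == population - 1)
  cvs <- vapply(rec$spikes[idx], function(s) {
    if (length(s) < min_spikes) return(NA_real_)
    isi <- diff(s)
    stats::sd(isi) / mean(isi)
  }, numeric(1))
  cvs <- cvs[is.finite(cvs)]
  list(per_neuron = cvs,
       median = if (length(cvs)) stats::median(cvs) else NA_real_)
}

#' Spike density around band-passed LFP troughs
#'
#' Band-passes the LFP (zero-phase, second-order Butterworth applied
#' forwards and backwards), finds its local minima inside the band period
#' range, and histograms spike times relative to the nearest trough in units
#' of the oscillation phase. Returns the modulation depth of the trough-
#' locked spike histogram together with a shuffle-based null: in the gamma
#' regime firing concentrates at a reliable phase of the cycle, so the
#' modulation exceeds the null. Note the sign convention of this LFP
#' proxy: it sums absolute synaptic currents, so strong synaptic drive
#' appears as a *maximum*, whereas in recorded extracellular potentials
#' current influx deflects the signal negative; population spikes
#' therefore sit just before the proxy's maxima, the counterpart of
#' spiking near the troughs of a recorded LFP.
#'
#' @param rec a `simulation_record`
#' @param population 1 or 2
#' @param band gamma band (Hz)
#' @param n_bins phase histogram bins
#' @param n_shuffle circular-shift shuffles for the null
#' @param seed RNG seed for the shuffles
#' @return list: `hist` (density per bin), `bin_centers` (fraction of the
#'   trough-to-trough cycle, trough at 0.5), `modulation` (max/min - 1),
#'   `null_mean`, `null_sd`, `z`
#' @export
trough_locked_spikes <- function(rec, population = 1, band = c(30, 80),
                                 n_bins = 12, n_shuffle = 100, seed = 1) {
  lfp <- compute_lfp(rec, population)
  fs <- attr(lfp, "fs")
  x <- bandpass(as.numeric(lfp), fs, band)
  # troughs: local minima of the band-passed LFP
  tr <- which(diff(sign(diff(x))) > 0) + 1
  if (length(tr) < 3) stop("trough_locked_spikes: too few troughs")
  tr_ms <- (tr - 0.5) / fs * 1000
  idx <- which(rec$pop_of == population - 1)
  spikes <- unlist(rec$spikes[idx], use.names = FALSE)
  spikes <- spikes[spikes > tr_ms[1] & spikes < tr_ms[length(tr_ms)]]
  if (length(spikes) < 10) stop("trough_locked_spikes: too few spikes")

  phase_of <- function(sp) {
    i <- findInterval(sp, tr_ms)
    ph <- (sp - tr_ms[i]) / (tr_ms[i + 1] - tr_ms[i])
    # phase 0 at a trough; recentre so the trough sits at 0.5
    (ph + 0.5) %% 1
  }
  hist_of <- function(sp) {
    ph <- phase_of(sp)
    tabulate(pmin(n_bins, floor(ph * n_bins) + 1), nbins = n_bins) /
      length(ph)
  }
  h <- hist_of(spikes)
  modulation <- function(hh) (max(hh) - min(hh)) / mean(hh)
  obs <- modulation(h)
  set.seed(seed)
  span <- rec$duration * 1000
  null <- vapply(seq_len(n_shuffle), function(k) {
    sh <- (spikes + stats::runif(1, 0, span)) %% span
    sh <- sh[sh > tr_ms[1] & sh < tr_ms[length(tr_ms)]]
    modulation(hist_of(sh))
  }, numeric(1))
  list(hist = h, bin_centers = (seq_len(n_bins) - 0.5) / n_bins,
       modulation = obs, null_mean = mean(null), null_sd = stats::sd(null),
       z = (obs - mean(null)) / stats::sd(null))
}

# zero-phase band-pass: 2nd-order Butterworth applied forwards and
# backwards, with mirror padding to suppress edge transients
bandpass <- function(x, fs, band) {
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  n <- length(x)
  y <- signal::filtfilt(bf, c(rev(x), x, rev(x)))
  y[(n + 1):(2 * n)]
}
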