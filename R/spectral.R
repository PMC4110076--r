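#' Welch power spectral density
#'
#' Splits the signal into `nperseg`-point segments with the given overlap,
#' windows each with a Hamming window, and averages the modified
#' periodograms. Power is one-sided density in signal-units^2/Hz, normalised
#' so that the integral over frequency equals the (window-corrected) signal
#' variance.
#'
#' @param x a `signal_trace` or numeric vector
#' @param fs sampling rate (Hz); taken from the trace attribute when present
#' @param nperseg segment length (samples); default 1 s of signal
#' @param overlap fractional overlap between segments, default 0.5
#' @param demean subtract each segment's mean before windowing
#' @return a `psd_result` list: `freqs`, `power`, `n_segments`, `fs`,
#'   `nperseg`, `window = "hamming"`
#' @export
welch_psd <- function(x, fs = NULL, nperseg = NULL, overlap = 0.5,
                      demean = TRUE) {
  if (is.null(fs)) fs <- attr(x, "fs")
  if (is.null(fs)) stop("welch_psd: sampling rate unknown")
  x <- as.numeric(x)
  if (is.null(nperseg)) nperseg <- min(length(x), round(fs))
  if (length(x) < nperseg) stop("welch_psd: signal shorter than nperseg")
  segs <- segment_matrix(x, nperseg, overlap, demean)
  w <- hamming_window(nperseg)
  U <- sum(w^2) # window power normalisation
  X <- stats::mvfft(segs * w)
  nf <- floor(nperseg / 2) + 1
  P <- Mod(X[seq_len(nf), , drop = FALSE])^2 / (fs * U)
  # one-sided: double all bins except DC and (for even nperseg) Nyquist
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (nperseg %% 2 == 0) dbl[nf] <- 1
  power <- rowMeans(P) * dbl
  structure(list(freqs = (seq_len(nf) - 1) * fs / nperseg, power = power,
                 n_segments = ncol(segs), fs = fs, nperseg = nperseg,
                 window = "hamming"),
            class = "psd_result")
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# matrix of (possibly overlapping) signal segments, one per column
segment_matrix <- function(x, nperseg, overlap, demean = TRUE) {
  step <- max(1, round(nperseg * (1 - overlap)))
  starts <- seq(1, length(x) - nperseg + 1, by = step)
  segs <- vapply(starts, function(s) x[s:(s + nperseg - 1)],
                 numeric(nperseg))
  segs <- matrix(segs, nrow = nperseg)
  if (demean) segs <- sweep(segs, 2, colMeans(segs))
  segs
}

#' Frequency-resolved phase coherence between two signals
#'
#' For every data segment k the cross-spectrum `S_xy,k(f)` between the two
#' Hamming-windowed segments is normalised to a unit phasor
#' `S_xy,k/|S_xy,k|`, whose angle is the phase lag between the signals at
#' frequency f in that segment. The coherence is the resultant length of
#' these phasors averaged over all K segments (1 = perfectly reliable phase
#' relation; chance level for independent signals shrinks as
#' `sqrt(pi)/(2 sqrt(K))`), and the mean phase is the resultant angle,
#' wrapped to (-pi, pi]. The mean phase is further converted into a time
#' shift by dividing by `2*pi*f`; a positive shift means the first signal
#' leads.
#'
#' Inputs may be single traces (segmented as in [welch_psd()]) or lists of
#' per-trial traces, in which case phasors are pooled across the segments of
#' all trials.
#'
#' @param x,y `signal_trace`s or numeric vectors, or lists of them (paired
#'   by position)
#' @param fs sampling rate (Hz), from trace attributes when absent
#' @param nperseg,overlap segmentation as in [welch_psd()]
#' @return a `coherence_result` list: `freqs`, `coherence` in `[0,1]`,
#'   `phase` (rad, (-pi, pi]), `time_shift` (ms), `K` (number of phasors
#'   averaged), `n_dropped` (zero cross-spectrum phasors excluded)
#' @export
phase_coherence <- function(x, y, fs = NULL, nperseg = NULL, overlap = 0.5) {
  xs <- if (is.list(x) && !inherits(x, "signal_trace")) x else list(x)
  ys <- if (is.list(y) && !inherits(y, "signal_trace")) y else list(y)
  if (length(xs) != length(ys)) {
    stop("phase_coherence: x and y must have the same number of trials")
  }
  if (is.null(fs)) fs <- attr(xs[[1]], "fs")
  if (is.null(fs)) stop("phase_coherence: sampling rate unknown")
  if (is.null(nperseg)) nperseg <- min(length(xs[[1]]), round(fs))
  w <- hamming_window(nperseg)
  nf <- floor(nperseg / 2) + 1

  sum_phasor <- complex(real = numeric(nf), imaginary = numeric(nf))
  K <- 0L
  n_dropped <- 0L
  for (tr in seq_along(xs)) {
    sx <- segment_matrix(as.numeric(xs[[tr]]), nperseg, overlap)
    sy <- segment_matrix(as.numeric(ys[[tr]]), nperseg, overlap)
    if (ncol(sx) != ncol(sy)) {
      stop("phase_coherence: x and y segmentation differs")
    }
    X <- stats::mvfft(sx * w)[seq_len(nf), , drop = FALSE]
    Y <- stats::mvfft(sy * w)[seq_len(nf), , drop = FALSE]
    Sxy <- X * Conj(Y)
    mod <- Mod(Sxy)
    ph <- Sxy
    nonzero <- mod > 0
    ph[nonzero] <- Sxy[nonzero] / mod[nonzero]
    ph[!nonzero] <- 0
    n_dropped <- n_dropped + sum(!nonzero)
    sum_phasor <- sum_phasor + rowSums(ph)
    K <- K + ncol(sx)
  }
  if (K < 2) stop("phase_coherence: need at least 2 segments")
  if (n_dropped > 0) {
    message(sprintf("phase_coherence: %d zero cross-spectrum phasors excluded",
                    n_dropped))
  }
  mean_phasor <- sum_phasor / K
  freqs <- (seq_len(nf) - 1) * fs / nperseg
  phase <- Arg(mean_phasor)
  structure(list(freqs = freqs, coherence = Mod(mean_phasor),
                 phase = phase,
                 time_shift = time_shift(phase, freqs),
                 K = K, n_dropped = n_dropped, fs = fs,
                 nperseg = nperseg),
            class = "coherence_result")
}

#' Convert a phase lag into a time shift
#'
#' `delta_tau = delta_phi / (2*pi*f)` in ms (f in Hz), with the phase
#' wrapped to (-pi, pi] first. Positive shift = the first signal leads. At
#' `f = 0` the shift is undefined and reported as `NA`.
#'
#' @param phase phase lag (rad)
#' @param f frequency (Hz)
#' @return time shift (ms)
#' @export
time_shift <- function(phase, f) {
  wrapped <- wrap_phase(phase)
  out <- ifelse(f > 0, wrapped / (2 * pi * f) * 1000, NA_real_)
  out
}

# wrap angles to (-pi, pi]
wrap_phase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  out[out <= -pi] <- pi
  out
}

#' Significance threshold from uncoupled baseline runs
#'
#' The normative rule: the threshold is four times the average phase
#' coherence of the uncoupled configuration over the analysis band.
#'
#' @param baseline a `coherence_result` from uncoupled runs, or a list of
#'   them (averaged)
#' @param band frequency band (Hz) over which the baseline is averaged
#' @return threshold (scalar)
#' @export
coherence_threshold <- function(baseline, band = c(10, 100)) {
  if (is.null(baseline)) stop("coherence_threshold: baseline missing")
  if (inherits(baseline, "coherence_result")) baseline <- list(baseline)
  means <- vapply(baseline, function(b) {
    sel <- b$freqs >= band[1] & b$freqs <= band[2]
    mean(b$coherence[sel])
  }, numeric(1))
  4 * mean(means)
}

#' Locate spectral and coherence peaks
#'
#' `f_LFP` is the frequency of maximal power inside the band. `f_C` lists
#' the frequencies of all local coherence maxima inside the band that
#' exceed the significance threshold, in increasing frequency order; the
#' extent of each is the contiguous region above half its prominence.
#'
#' @param psd a `psd_result`
#' @param coh a `coherence_result` (or `NULL` to report only `f_LFP`)
#' @param band search band (Hz)
#' @param threshold coherence significance threshold, see
#'   [coherence_threshold()]
#' @return a `peak_summary` list: `f_LFP`, `f_C` (possibly empty),
#'   `coherence_at_peaks`, `time_shift_at_peaks`, `extents` (list of
#'   c(lo, hi) Hz), `band`, `threshold`
#' @export
track_peaks <- function(psd, coh = NULL, band = c(30, 80), threshold = 0) {
  sel <- psd$freqs >= band[1] & psd$freqs <= band[2]
  if (!any(sel)) stop("track_peaks: band outside analysed range")
  f_band <- psd$freqs[sel]
  f_LFP <- f_band[which.max(psd$power[sel])]

  f_C <- numeric(0)
  coh_at <- numeric(0)
  ts_at <- numeric(0)
  extents <- list()
  if (!is.null(coh)) {
    cs <- coh$freqs >= band[1] & coh$freqs <= band[2]
    fc <- coh$freqs[cs]
    cc <- coh$coherence[cs]
    tt <- coh$time_shift[cs]
    if (length(cc) >= 3) {
      im <- which(diff(sign(diff(cc))) < 0) + 1
      # include band-edge maxima
      if (length(cc) >= 2 && cc[1] > cc[2]) im <- c(1, im)
      if (cc[length(cc)] > cc[length(cc) - 1]) im <- c(im, length(cc))
      im <- im[cc[im] > threshold]
      if (length(im)) {
        ord <- order(fc[im])
        im <- im[ord]
        f_C <- fc[im]
        coh_at <- cc[im]
        ts_at <- tt[im]
        extents <- lapply(im, function(i) {
          half <- cc[i] - (cc[i] - min(cc)) / 2
          lo <- i
          while (lo > 1 && cc[lo - 1] >= half) lo <- lo - 1
          hi <- i
          while (hi < length(cc) && cc[hi + 1] >= half) hi <- hi + 1
          c(fc[lo], fc[hi])
        })
      }
    }
  }
  structure(list(f_LFP = f_LFP, f_C = f_C, coherence_at_peaks = coh_at,
                 time_shift_at_peaks = ts_at, extents = extents,
                 band = band, threshold = threshold),
            class = "peak_summary")
}

#' Classify a time shift as in-phase or anti-phase
#'
#' At a coherence peak frequency `f_C` with period `T_C = 1000/f_C` ms, a
#' shift within `T_C/8` of zero is in-phase, within `T_C/8` of half a
#' period (either sign) anti-phase, otherwise intermediate.
#'
#' @param delta_tau time shift (ms)
#' @param f_C peak frequency (Hz)
#' @return `"in-phase"`, `"anti-phase"` or `"intermediate"`
#' @export
classify_phase <- function(delta_tau, f_C) {
  T_C <- 1000 / f_C
  d <- abs(delta_tau)
  if (d <= T_C / 8) "in-phase"
  else if (abs(d - T_C / 2) <= T_C / 8) "anti-phase"
  else "intermediate"
}
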