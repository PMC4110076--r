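#' Equipopulated (quantile) bin edges
#'
#' Edges that split `values` into `n_bins` bins of equal occupancy (within
#' one element), with ties broken by stable rank. If ties make fewer
#' distinct edges possible the binning degrades to the feasible number of
#' bins with a warning.
#'
#' @param values numeric vector, length at least `n_bins`
#' @param n_bins requested number of bins
#' @return numeric vector of interior edges (length `n_bins - 1`), with
#'   attribute `n_bins_effective`
#' @export
equipopulated_bins <- function(values, n_bins) {
  stopifnot(n_bins >= 1, length(values) >= n_bins)
  if (n_bins == 1) {
    out <- numeric(0)
    attr(out, "n_bins_effective") <- 1L
    return(out)
  }
  qs <- stats::quantile(values, probs = seq_len(n_bins - 1) / n_bins,
                        type = 1, names = FALSE)
  # an edge at the sample maximum would leave an empty top bin
  edges <- unique(qs[qs < max(values)])
  if (length(edges) < n_bins - 1) {
    warning(sprintf(
      "equipopulated_bins: ties reduce %d requested bins to %d",
      n_bins, length(edges) + 1L))
  }
  attr(edges, "n_bins_effective") <- length(edges) + 1L
  edges
}

# assign values to bins given interior edges (bin 1 = lowest)
bin_assign <- function(values, edges) {
  findInterval(values, edges, left.open = TRUE) + 1L
}

#' Plug-in (direct) mutual information
#'
#' `I(S;R) = sum_s P(s) sum_r P(r|s) log2[P(r|s)/P(r)]` with uniform
#' stimulus probabilities `P(s) = 1/n_stimuli` and the response alphabet
#' fixed across stimuli (bin edges computed on the pooled responses).
#'
#' @param responses list of numeric vectors, one per stimulus (single-trial
#'   response values, e.g. power at one frequency)
#' @param n_bins number of equipopulated response bins
#' @param edges optional precomputed interior edges; default from the
#'   pooled responses
#' @return information (bits), with attribute `n_bins_effective`
#' @export
plugin_mi <- function(responses, n_bins = 6, edges = NULL) {
  stopifnot(is.list(responses), length(responses) >= 2)
  if (any(vapply(responses, length, integer(1)) == 0)) {
    stop("plugin_mi: empty stimulus class")
  }
  pooled <- unlist(responses, use.names = FALSE)
  if (is.null(edges)) {
    edges <- suppressWarnings(equipopulated_bins(pooled, n_bins))
  }
  nb <- length(edges) + 1L
  S <- length(responses)
  Ps <- 1 / S
  counts <- vapply(responses,
                   function(r) tabulate(bin_assign(r, edges), nbins = nb),
                   numeric(nb))
  counts <- matrix(counts, nrow = nb) # r x s
  Prs <- sweep(counts, 2, colSums(counts), "/") # P(r|s)
  Pr <- rowSums(sweep(Prs, 2, Ps, "*")) # P(r)
  terms <- Prs * log2(sweep(Prs, 1, Pr, "/"))
  I <- sum(Ps * terms[is.finite(terms)])
  attr(I, "n_bins_effective") <- nb
  I
}

#' Analytic limited-sampling bias of the plug-in estimator
#'
#' First-order (Panzeri-Treves-type) bias:
#' `bias = [sum_s (B_s - 1) - (B - 1)] / (2 N ln 2)` bits, where `B_s` is
#' the number of response bins occupied under stimulus s, `B` the number
#' occupied overall, and `N` the total trial count. Subtracting it from the
#' raw plug-in value removes the leading overestimation caused by finite
#' sampling.
#'
#' @inheritParams plugin_mi
#' @return bias estimate (bits)
#' @export
mi_bias_pt <- function(responses, n_bins = 6, edges = NULL) {
  pooled <- unlist(responses, use.names = FALSE)
  if (is.null(edges)) {
    edges <- suppressWarnings(equipopulated_bins(pooled, n_bins))
  }
  nb <- length(edges) + 1L
  N <- length(pooled)
  occ_s <- vapply(responses, function(r) {
    sum(tabulate(bin_assign(r, edges), nbins = nb) > 0)
  }, numeric(1))
  occ_all <- sum(tabulate(bin_assign(pooled, edges), nbins = nb) > 0)
  (sum(occ_s - 1) - (occ_all - 1)) / (2 * N * log(2))
}

#' Bias-corrected mutual information with a bootstrap null
#'
#' Subtracts the analytic first-order bias ([mi_bias_pt()]) and then the
#' mean of a bootstrap null in which stimulus labels are shuffled across
#' trials (any residual positive information under shuffling is sampling
#' bias and is removed). The null spread also provides the significance
#' level: corrected information above the null's upper percentile is
#' flagged significant.
#'
#' @inheritParams plugin_mi
#' @param n_bootstrap number of label shuffles
#' @param seed RNG seed for the shuffles
#' @param alpha significance level (upper percentile of the null)
#' @return list: `I_raw`, `bias_analytic`, `null_mean`, `null_sd`,
#'   `null_q` (1-alpha quantile of the shuffled, analytic-corrected MI),
#'   `I_corrected` (raw - analytic bias - residual null mean, floored at 0
#'   with the unfloored value in `I_corrected_raw`), `significant`,
#'   `undersampled` (TRUE when `N < 4 * n_bins * n_stimuli`)
#' @export
bias_correct <- function(responses, n_bins = 6, n_bootstrap = 200, seed = 1,
                         alpha = 0.05) {
  pooled <- unlist(responses, use.names = FALSE)
  edges <- suppressWarnings(equipopulated_bins(pooled, n_bins))
  nb <- length(edges) + 1L
  I_raw <- as.numeric(plugin_mi(responses, edges = edges))
  bias <- mi_bias_pt(responses, edges = edges)
  ns <- vapply(responses, length, integer(1))
  lab <- rep(seq_along(responses), ns)
  set.seed(seed)
  null <- vapply(seq_len(n_bootstrap), function(k) {
    sh <- sample(lab)
    resp_sh <- split(pooled, sh)
    as.numeric(plugin_mi(resp_sh, edges = edges)) -
      mi_bias_pt(resp_sh, edges = edges)
  }, numeric(1))
  null_mean <- mean(null)
  I_corr_raw <- I_raw - bias - null_mean
  list(I_raw = I_raw, bias_analytic = bias, null_mean = null_mean,
       null_sd = stats::sd(null),
       null_q = stats::quantile(null, 1 - alpha, names = FALSE),
       I_corrected_raw = I_corr_raw, I_corrected = max(0, I_corr_raw),
       significant = I_corr_raw > stats::quantile(null, 1 - alpha,
                                                  names = FALSE),
       undersampled = length(pooled) < 4 * nb * length(responses))
}

#' Per-stimulus power samples across frequencies
#'
#' Container for single-trial power values: a list with one matrix per
#' stimulus (trials x frequencies) on a common frequency grid.
#'
#' @param samples list of trials x frequencies matrices, one per stimulus
#' @param freqs frequency grid (Hz)
#' @return a `power_sample_set`
#' @export
power_sample_set <- function(samples, freqs) {
  stopifnot(is.list(samples), length(samples) >= 2)
  nf <- vapply(samples, ncol, integer(1))
  if (length(unique(nf)) != 1 || nf[1] != length(freqs)) {
    stop("power_sample_set: inconsistent frequency grids")
  }
  if (any(vapply(samples, nrow, integer(1)) < 2)) {
    stop("power_sample_set: need at least 2 trials per stimulus")
  }
  structure(list(samples = samples, freqs = freqs,
                 n_stimuli = length(samples),
                 n_trials = vapply(samples, nrow, integer(1))),
            class = "power_sample_set")
}

#' Frequency-resolved mutual information spectrum
#'
#' Computes, at every frequency, the plug-in and bias-corrected mutual
#' information between the stimulus set and the single-trial power, with
#' the bootstrap null level and significance flag from [bias_correct()].
#'
#' @param set a [power_sample_set()]
#' @param n_bins equipopulated response bins
#' @param n_bootstrap bootstrap shuffles per frequency
#' @param seed RNG seed
#' @param alpha significance level
#' @return an `mi_spectrum` data.frame: `freq`, `I_raw`, `I_corrected`,
#'   `null_mean`, `null_sd`, `null_q`, `significant`, `undersampled`
#' @export
mi_spectrum <- function(set, n_bins = 6, n_bootstrap = 200, seed = 1,
                        alpha = 0.05) {
  stopifnot(inherits(set, "power_sample_set"))
  rows <- lapply(seq_along(set$freqs), function(fi) {
    responses <- lapply(set$samples, function(m) m[, fi])
    bc <- bias_correct(responses, n_bins = n_bins,
                       n_bootstrap = n_bootstrap, seed = seed + fi,
                       alpha = alpha)
    data.frame(freq = set$freqs[fi], I_raw = bc$I_raw,
               I_corrected = bc$I_corrected,
               null_mean = bc$null_mean, null_sd = bc$null_sd,
               null_q = bc$null_q, significant = bc$significant,
               undersampled = bc$undersampled)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mi_spectrum", "data.frame")
  out
}

#' Single-trial power samples from trial records
#'
#' Builds the [power_sample_set()] for an MI analysis from sweep records:
#' one Welch power spectrum per trial of the chosen signal on the receiver
#' population.
#'
#' @param records list of `simulation_record`s carrying `stimulus`
#'   attributes (as from [run_experiment()])
#' @param population receiver population (1 or 2)
#' @param kind `"LFP"` or `"MUA"`
#' @param window optional `(t_on, t_off)` seconds restricting the analysed
#'   samples (e.g. the stimulus window)
#' @param nperseg Welch segment length; default 0.5 s for windowed data
#' @param fmax truncate the frequency grid (Hz)
#' @return a `power_sample_set`
#' @export
power_samples_from_records <- function(records, population = 2,
                                       kind = c("LFP", "MUA"),
                                       window = NULL, nperseg = NULL,
                                       fmax = 120) {
  kind <- match.arg(kind)
  stims <- vapply(records, function(r) {
    s <- attr(r, "stimulus")
    if (is.null(s)) NA_integer_ else as.integer(s)
  }, integer(1))
  if (any(is.na(stims))) {
    stop("power_samples_from_records: records lack stimulus labels")
  }
  spectra <- lapply(records, function(rec) {
    tr <- if (kind == "LFP") compute_lfp(rec, population) else
      compute_mua(rec, population)
    fs <- attr(tr, "fs")
    v <- as.numeric(tr)
    if (!is.null(window)) {
      i0 <- max(1L, floor(window[1] * fs) + 1L)
      i1 <- min(length(v), ceiling(window[2] * fs))
      v <- v[i0:i1]
    }
    np <- if (is.null(nperseg)) min(length(v), round(fs / 2)) else nperseg
    welch_psd(v, fs = fs, nperseg = np)
  })
  freqs <- spectra[[1]]$freqs
  keep <- freqs <= fmax
  by_stim <- split(seq_along(records), stims)
  samples <- lapply(by_stim, function(ix) {
    do.call(rbind, lapply(spectra[ix], function(p) p$power[keep]))
  })
  power_sample_set(samples, freqs[keep])
}
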