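# Brute-force phase-coherence oracle: per-segment DFTs computed directly
# from the definition, no shared code with phase_coherence().
brute_force_coherence <- function(x, y, fs, nperseg, overlap = 0.5) {
  step <- max(1, round(nperseg * (1 - overlap)))
  starts <- seq(1, length(x) - nperseg + 1, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(nperseg) - 1) / (nperseg - 1))
  nf <- floor(nperseg / 2) + 1
  acc <- complex(real = numeric(nf), imaginary = numeric(nf))
  for (s0 in starts) {
    xs <- x[s0:(s0 + nperseg - 1)]
    ys <- y[s0:(s0 + nperseg - 1)]
    xs <- (xs - mean(xs)) * w
    ys <- (ys - mean(ys)) * w
    for (fi in seq_len(nf)) {
      k <- fi - 1
      e <- exp(-2i * pi * k * (seq_len(nperseg) - 1) / nperseg)
      X <- sum(xs * e)
      Y <- sum(ys * e)
      S <- X * Conj(Y)
      if (Mod(S) > 0) acc[fi] <- acc[fi] + S / Mod(S)
    }
  }
  list(freqs = (seq_len(nf) - 1) * fs / nperseg,
       coherence = Mod(acc) / length(starts),
       phase = Arg(acc))
}

# Direct-summation MI oracle over an explicit joint count table
# (rows = response bins, cols = stimuli), uniform stimulus priors.
brute_force_mi <- function(counts) {
  S <- ncol(counts)
  Ps <- 1 / S
  I <- 0
  Pr <- rowSums(sweep(counts, 2, colSums(counts), "/")) * Ps
  for (s in seq_len(S)) {
    prs <- counts[, s] / sum(counts[, s])
    for (r in seq_along(prs)) {
      if (prs[r] > 0) I <- I + Ps * prs[r] * log2(prs[r] / Pr[r])
    }
  }
  I
}
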