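# Independent oracles, written from definitions and sharing no code with the
# package implementation.

# Definitional Welch PSD: explicit DFT matrix, loop over segments.
oracle_welch <- function(x, fs = 250, window_sec = 1, overlap = 0.5,
                         nfft = 256, freqs = 1:100) {
  nwin <- round(window_sec * fs)
  nfft <- max(nfft, nwin)
  step <- round(nwin * (1 - overlap))
  k <- 0:(nwin - 1)
  w <- 0.54 - 0.46 * cos(2 * pi * k / (nwin - 1))  # symmetric hamming
  # DFT matrix for the one-sided bins
  nh <- nfft %/% 2 + 1
  m <- outer(0:(nh - 1), 0:(nfft - 1),
             function(r, c) exp(-2i * pi * r * c / nfft))
  starts <- seq(1, length(x) - nwin + 1, by = step)
  acc <- numeric(nh)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1)]
    seg <- (seg - mean(seg)) * w
    seg <- c(seg, rep(0, nfft - nwin))
    X <- as.vector(m %*% seg)
    p <- Mod(X)^2 / (fs * sum(w^2))
    p[2:(nh - 1)] <- 2 * p[2:(nh - 1)]
    acc <- acc + p
  }
  psd <- acc / length(starts)
  f_native <- (0:(nh - 1)) * fs / nfft
  # linear interpolation onto the requested grid
  sapply(freqs, function(f) {
    i <- findInterval(f, f_native)
    if (f_native[i] == f) return(psd[i])
    lam <- (f - f_native[i]) / (f_native[i + 1] - f_native[i])
    (1 - lam) * psd[i] + lam * psd[i + 1]
  })
}

# Direct evaluation of the distance-weighted average over a set of spectra.
oracle_weighted_mean <- function(powers, distances) {
  num <- 0
  den <- 0
  for (i in seq_along(distances)) {
    num <- num + powers[[i]] * (1 / distances[i])
    den <- den + 1 / distances[i]
  }
  num / den
}

# Brute-force Spearman rho: rank with average ties, then Pearson via cor().
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# Exact two-sided permutation p for Spearman rho by full enumeration,
# using recursive permutation generation distinct from the package's.
oracle_spearman_p <- function(x, y) {
  rho_obs <- oracle_spearman(x, y)
  n <- length(y)
  perm_list <- list(integer(0))
  for (k in seq_len(n)) {
    perm_list <- unlist(lapply(perm_list, function(p) {
      lapply(setdiff(seq_len(n), p), function(e) c(p, e))
    }), recursive = FALSE)
  }
  rhos <- vapply(perm_list, function(p) oracle_spearman(x, y[p]), numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# Synthetic spectrum: power law with optional log-domain Gaussian bump and
# log-normal jitter.
synth_spectrum <- function(offset = 1, exponent = 1.5, freqs = 1:100,
                           bump_freq = NULL, bump_height = 0,
                           bump_width = 2, jitter_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ly <- offset - exponent * log10(freqs)
  if (!is.null(bump_freq)) {
    ly <- ly + bump_height * exp(-(freqs - bump_freq)^2 / (2 * bump_width^2))
  }
  if (jitter_sd > 0) ly <- ly + rnorm(length(freqs), sd = jitter_sd)
  new_spectrum(freqs, 10^ly, stage = "raw")
}
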