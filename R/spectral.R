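# Welch spectral estimation and the fixed analysis grid.
#
# Convention (fixed for determinism): one-sided power spectral density,
# symmetric hamming window, per-segment mean removal before windowing,
# density scaling 1 / (fs * sum(w^2)) with doubling of non-DC/non-Nyquist
# bins, linear interpolation of the averaged periodogram onto the package's
# 1-100 Hz grid at 1 Hz per bin.

#' The fixed 1-100 Hz analysis grid
#'
#' All spectra in the package live on 100 frequency bins between 1 and
#' 100 Hz at a resolution of 1 Hz per bin.
#'
#' @return Integer vector 1:100 (Hz).
#' @export
spectrum_grid <- function() 1:100

#' Construct a spectrum object
#'
#' @param freqs Frequency grid in Hz.
#' @param power Per-bin power values; non-negative for `stage = "raw"`,
#'   may be negative for `stage = "flattened"` (residual power after
#'   aperiodic removal).
#' @param stage `"raw"` or `"flattened"`.
#' @return Object of class `detec_spectrum`.
#' @export
new_spectrum <- function(freqs, power, stage = c("raw", "flattened")) {
  stage <- match.arg(stage)
  stopifnot(length(freqs) == length(power), is.numeric(power))
  if (stage == "raw" && any(power < 0, na.rm = TRUE)) {
    stop("raw spectra must be non-negative at every bin", call. = FALSE)
  }
  structure(list(freqs = as.numeric(freqs), power = as.numeric(power),
                 stage = stage),
            class = "detec_spectrum")
}

#' @export
print.detec_spectrum <- function(x, ...) {
  cat("<detec_spectrum>", x$stage, "stage,", length(x$freqs), "bins",
      sprintf("(%g-%g Hz)\n", min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Welch power spectral density on the fixed grid
#'
#' Averaged modified periodograms: the series is cut into 1 s segments with
#' 50% overlap, each segment is mean-removed, hamming-windowed and
#' zero-padded to `nfft` points (the 250-sample segment at the default
#' 250 Hz sampling rate falls below the 256-point FFT), the one-sided
#' periodograms are averaged and interpolated onto the 1-100 Hz grid.
#'
#' @param samples Numeric time series (arbitrary amplitude units).
#' @param fs Sampling rate in Hz (default 250, the sensing device's rate).
#' @param window_sec Segment length in seconds (default 1).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param nfft FFT length; segments shorter than `nfft` are zero-padded,
#'   and `nfft` is raised to the segment length if smaller (default 256).
#' @param freqs Output grid (default [spectrum_grid()]).
#' @return A raw [new_spectrum()] in units of power density (input^2/Hz).
#' @examples
#' x <- sin(2 * pi * 20 * seq(0, 20, by = 1 / 250))
#' s <- welch_psd(x)
#' s$freqs[which.max(s$power)]  # 20
#' @export
welch_psd <- function(samples, fs = 250, window_sec = 1, overlap = 0.5,
                      nfft = 256, freqs = spectrum_grid()) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a positive number", call. = FALSE)
  }
  samples <- as.numeric(samples)
  if (anyNA(samples)) stop("samples contain NA", call. = FALSE)
  nwin <- round(window_sec * fs)
  if (nwin < 2L) stop("window too short for the sampling rate", call. = FALSE)
  if (length(samples) < 2L * nwin) {
    stop("insufficient data: need at least two full windows (",
         2L * nwin, " samples), got ", length(samples), call. = FALSE)
  }
  nfft <- max(nfft, nwin)
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(samples) - nwin + 1L, by = step)

  w <- as.numeric(signal::hamming(nwin))
  segs <- vapply(starts, function(s) samples[s:(s + nwin - 1L)],
                 numeric(nwin))
  segs <- sweep(segs, 2L, colMeans(segs))      # per-segment mean removal
  segs <- segs * w
  padded <- rbind(segs, matrix(0, nfft - nwin, ncol(segs)))
  ft <- stats::mvfft(padded)

  nh <- nfft %/% 2L + 1L
  p <- Mod(ft[seq_len(nh), , drop = FALSE])^2 / (fs * sum(w^2))
  if (nh > 2L) p[2:(nh - 1L), ] <- 2 * p[2:(nh - 1L), ]
  psd <- rowMeans(p)
  f_native <- (seq_len(nh) - 1L) * fs / nfft

  if (max(freqs) > max(f_native)) {
    stop("requested grid exceeds the Nyquist range of the estimate",
         call. = FALSE)
  }
  power <- stats::approx(f_native, psd, xout = freqs)$y
  new_spectrum(freqs, power, stage = "raw")
}
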