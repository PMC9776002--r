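# Aperiodic (1/f) parameterization and beta-peak detection.
#
# The aperiodic component is modeled as log10 P(f) = offset - exponent *
# log10 f and fit by two-pass least squares: an initial fit over the fit
# range, then a refit using only bins at or below the initial fit, so that
# oscillatory peaks do not drag the fit upward (the robust scheme popularized
# by spectral parameterization ("FOOOF") tooling). No knee term: at these
# recording lengths a knee is rarely identifiable.

#' Fit the aperiodic 1/f component of a raw spectrum
#'
#' @param spec Raw [new_spectrum()] on the standard grid.
#' @param fit_range Frequency range (Hz) used for the fit; default the full
#'   1-100 Hz grid (narrow to e.g. 3-45 Hz for recordings with heavy drift
#'   or line-noise residue).
#' @return List with `offset` (b), `exponent` (chi, positive for decaying
#'   spectra), `rmse` (root-mean-square error of the fit in log10 power
#'   units, over the bins retained by the robust pass), `rmse_linear` (the
#'   same fit error measured on the linear power scale, the prominence
#'   threshold of [detect_peak()]), `fitted_log` (fitted log10 power on the
#'   full grid) and `fit_range`.
#' @export
fit_aperiodic <- function(spec, fit_range = c(1, 100)) {
  stopifnot(inherits(spec, "detec_spectrum"))
  if (spec$stage != "raw") {
    stop("aperiodic fit expects a raw spectrum", call. = FALSE)
  }
  idx <- which(spec$freqs >= fit_range[1] & spec$freqs <= fit_range[2])
  if (length(idx) < 5L) stop("fit range covers too few bins", call. = FALSE)
  if (any(spec$power[idx] <= 0)) {
    stop("non-positive power inside the aperiodic fit range; the spectrum ",
         "is degenerate (e.g. a constant or empty signal) - screen inputs ",
         "with qc_screen() or narrow fit_range", call. = FALSE)
  }
  lx <- log10(spec$freqs[idx])
  ly <- log10(spec$power[idx])

  co <- stats::lsfit(lx, ly)$coefficients
  resid <- ly - (co[1] + co[2] * lx)
  # Robust pass: drop bins above the initial fit (peaks only push residuals
  # up); keep the refit only if enough bins remain.
  keep <- resid <= 0
  if (sum(keep) >= 5L) {
    co <- stats::lsfit(lx[keep], ly[keep])$coefficients
    resid <- ly - (co[1] + co[2] * lx)
  } else {
    keep <- rep(TRUE, length(idx))
  }
  # Goodness of fit over the whole fit range (not only the robust-kept
  # bins): the model's RMSE against the data it is meant to describe.
  rmse <- sqrt(mean(resid^2))
  # The same fit error on the linear power scale; dominated by the low end
  # of the fit range, where absolute power is largest.
  rmse_linear <- sqrt(mean((spec$power[idx] - 10^(co[1] + co[2] * lx))^2))

  list(offset = unname(co[1]), exponent = unname(-co[2]), rmse = rmse,
       rmse_linear = rmse_linear,
       fitted_log = unname(co[1] + co[2] * log10(spec$freqs)),
       fit_range = fit_range)
}

#' Remove the aperiodic component from a raw spectrum
#'
#' Subtracts the fitted power-law background bin-wise on the linear power
#' scale: `flattened = raw - 10^fit`. Flattened power may be negative where
#' the raw spectrum dips below the fit.
#'
#' @inheritParams fit_aperiodic
#' @return List with `spectrum` (flattened [new_spectrum()]), `offset`,
#'   `exponent`, `rmse` and `fitted_log` as in [fit_aperiodic()].
#' @examples
#' f <- spectrum_grid()
#' s <- new_spectrum(f, 10 * f^-1.5, "raw")
#' ap <- remove_aperiodic(s)
#' ap$exponent  # ~1.5
#' @export
remove_aperiodic <- function(spec, fit_range = c(1, 100)) {
  ap <- fit_aperiodic(spec, fit_range)
  flat <- spec$power - 10^ap$fitted_log
  c(list(spectrum = new_spectrum(spec$freqs, flat, stage = "flattened")), ap)
}

# Topographic prominence of a local maximum at index i of y: height above
# the higher of the two minima separating it from higher terrain (or the
# series edge).
.prominence <- function(y, i) {
  n <- length(y)
  lmin <- y[i]
  j <- i
  while (j > 1L && y[j - 1L] <= y[i]) {
    j <- j - 1L
    lmin <- min(lmin, y[j])
  }
  if (j == 1L) lmin <- min(lmin, y[seq_len(i)])
  rmin <- y[i]
  j <- i
  while (j < n && y[j + 1L] <= y[i]) {
    j <- j + 1L
    rmin <- min(rmin, y[j])
  }
  if (j == n) rmin <- min(rmin, y[i:n])
  y[i] - max(lmin, rmin)
}

#' Detect a qualifying beta peak in a raw spectrum
#'
#' Fits the aperiodic curve model ([fit_aperiodic()]) and inspects the
#' flattened residual (raw power minus the fitted power law, linear power
#' scale). A local maximum inside the band qualifies as a peak when its
#' value exceeds the fitted curve at that frequency and its topographic
#' prominence over neighboring bins is at least the fit's root-mean-square
#' error on the same linear scale. Because the linear fit error is dominated
#' by the low end of the fit range where absolute power is largest, in-band
#' noise wiggles fall well below the threshold while genuine beta peaks of
#' near-background magnitude clear it. With several qualifying peaks, one
#' inside the low beta range is preferred (the highest-prominence one);
#' otherwise the highest-prominence peak wins. The decision is invariant to
#' overall amplitude scaling.
#'
#' @param spec Raw [new_spectrum()] on the standard grid.
#' @param band Search band in Hz, inclusive on both edges (default 13-35,
#'   the beta band).
#' @param low_beta Preferred sub-band in Hz (default 13-20).
#' @param fit_range Passed to [fit_aperiodic()].
#' @return List of class `detec_peak`: `found`, `peak_freq` (Hz, NA when
#'   not found), `peak_height` (residual power above the fit at the peak),
#'   `prominence`, `rmse` (the linear-scale fit RMSE used as threshold),
#'   and `candidates` (data frame of all qualifying maxima).
#' @export
detect_peak <- function(spec, band = c(13, 35), low_beta = c(13, 20),
                        fit_range = c(1, 100)) {
  stopifnot(inherits(spec, "detec_spectrum"))
  ap <- fit_aperiodic(spec, fit_range)
  no_peak <- structure(list(found = FALSE, peak_freq = NA_real_,
                            peak_height = NA_real_, prominence = NA_real_,
                            rmse = ap$rmse_linear,
                            candidates = data.frame(freq = numeric(0),
                                                    height = numeric(0),
                                                    prominence = numeric(0))),
                       class = "detec_peak")
  # Flattened residual on the linear power scale; the aperiodic trend is
  # removed so the 1/f slope does not bias maxima or cols.
  resid <- spec$power - 10^ap$fitted_log
  n <- length(resid)
  in_band <- spec$freqs >= band[1] & spec$freqs <= band[2]
  is_max <- c(FALSE, diff(resid) > 0) & c(diff(resid) < 0, FALSE)
  cand_idx <- which(is_max & in_band & resid > 0)
  if (length(cand_idx) == 0L) return(no_peak)

  prom <- vapply(cand_idx, function(i) .prominence(resid, i), numeric(1))
  qual <- prom >= ap$rmse_linear
  if (!any(qual)) return(no_peak)
  cand <- data.frame(freq = spec$freqs[cand_idx[qual]],
                     height = resid[cand_idx[qual]],
                     prominence = prom[qual])
  pref <- cand$freq >= low_beta[1] & cand$freq <= low_beta[2]
  pool <- if (any(pref)) cand[pref, , drop = FALSE] else cand
  best <- pool[which.max(pool$prominence), ]

  structure(list(found = TRUE, peak_freq = best$freq,
                 peak_height = best$height, prominence = best$prominence,
                 rmse = ap$rmse_linear, candidates = cand),
            class = "detec_peak")
}

#' @export
print.detec_peak <- function(x, ...) {
  if (x$found) {
    cat(sprintf("<detec_peak> found at %g Hz (height %.3g, prominence %.3g, fit RMSE %.3g)\n",
                x$peak_freq, x$peak_height, x$prominence, x$rmse))
  } else {
    cat(sprintf("<detec_peak> no qualifying peak (fit RMSE %.3g)\n", x$rmse))
  }
  invisible(x)
}
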