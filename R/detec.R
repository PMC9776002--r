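# Core selection algorithm: distance-weighted monopolar spectra from bipolar
# survey recordings, hemisphere strategy (beta peak vs low-beta band),
# normalized activity scoring, level ranking and directional contact choice.

#' Default analysis configuration
#'
#' All tunable parameters of the pipeline with their fixed defaults:
#' sampling rate 250 Hz, 1 s hamming windows with 50% overlap zero-padded to
#' a 256-point FFT, 1-100 Hz grid, beta band 13-35 Hz, low beta 13-20 Hz
#' (band edges inclusive), +/- 2 Hz peak scoring window, 5-95 Hz
#' normalization range, 1-100 Hz aperiodic fit range.
#'
#' @param ... Named overrides of individual defaults.
#' @return Named list of parameters.
#' @export
detec_config <- function(...) {
  cfg <- list(
    fs = 250, window_sec = 1, overlap = 0.5, nfft = 256,
    beta = c(13, 35), low_beta = c(13, 20),
    peak_halfwidth = 2, norm_range = c(5, 95), fit_range = c(1, 100),
    distance_mode = "3d",
    screen = "monopolar"   # or "bipolar": where peaks are screened
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(ov)] <- ov
  cfg
}

# Contributing recordings and weights for one screened configuration.
# Returns data.frame(label, distance). For a physical contact: all channels
# with the contact as an endpoint, distance to the partner. For a ring-mode
# virtual contact ("1"/"2"): all channels involving the level itself or any
# of its segments, distance from the level's axial center to the partner;
# for intra-level pairs (both endpoints in the level) the partner sits on
# the cylinder wall, so the distance is the lead radius.
.contributions <- function(contact, labels, geom, mode = "3d") {
  # canonical channel order: montage order first, then alphabetical, so the
  # floating-point summation order (and hence the result, bit for bit) does
  # not depend on the order channels appear in the survey
  labels <- labels[order(match(labels, montage_pairs(),
                               nomatch = length(montage_pairs()) + 1L),
                         labels)]
  out <- list()
  is_level <- contact %in% c("1", "2")
  members <- if (is_level) c(contact, segments_of_level(as.integer(contact)))
             else contact
  for (lab in labels) {
    pair <- split_pair(lab)
    inv <- pair %in% members
    if (!any(inv)) next
    if (all(inv)) {  # intra-level pair of a ring-mode virtual contact
      d <- geom$radius
    } else {
      partner <- pair[!inv]
      d <- contact_distance(geom, contact, partner, mode = mode)
    }
    out[[length(out) + 1L]] <- data.frame(label = lab, distance = d)
  }
  if (length(out) == 0L) {
    stop("no recording in the survey involves contact '", contact, "'",
         call. = FALSE)
  }
  do.call(rbind, out)
}

#' Distance-weighted monopolar spectrum of one contact
#'
#' Averages the spectra of all bipolar recordings involving the contact,
#' each weighted by the inverse distance between the contact's center and
#' its bipolar recording partner:
#' `PSD_weighted = sum_i PSD_i / d_i / sum_i (1 / d_i)`.
#' Ring-mode virtual contacts "1" and "2" average every channel involving
#' any segment of the level, with distances taken from the level's axial
#' center.
#'
#' @param contact Configuration id (see [monopolar_configs()]).
#' @param survey A [read_survey()]/[simulate_survey()] hemisphere survey.
#' @param spectra Optional named list of precomputed raw spectra per channel
#'   label (computed with [welch_psd()] if missing).
#' @param config A [detec_config()].
#' @return Raw [new_spectrum()] with attributes `n_contributing` and
#'   `weights` (the contributing channels and distances).
#' @export
weighted_monopolar_spectrum <- function(contact, survey, spectra = NULL,
                                        config = detec_config()) {
  stopifnot(inherits(survey, "hemisphere_survey"))
  if (is.null(spectra)) spectra <- survey_spectra(survey, config)
  contrib <- .contributions(contact, names(spectra), survey$geometry,
                            mode = config$distance_mode)
  w <- 1 / contrib$distance
  mat <- vapply(spectra[contrib$label], function(s) s$power,
                numeric(length(spectrum_grid())))
  power <- as.numeric(mat %*% w) / sum(w)
  out <- new_spectrum(spectrum_grid(), power, stage = "raw")
  attr(out, "n_contributing") <- nrow(contrib)
  attr(out, "weights") <- contrib
  out
}

#' Welch spectra of every channel in a survey
#'
#' @inheritParams weighted_monopolar_spectrum
#' @return Named list of raw spectra, one per channel label.
#' @export
survey_spectra <- function(survey, config = detec_config()) {
  lapply(survey$recordings, function(x) {
    welch_psd(x, fs = survey$fs, window_sec = config$window_sec,
              overlap = config$overlap, nfft = config$nfft)
  })
}

#' Weighted monopolar spectra of all screened configurations
#'
#' @inheritParams weighted_monopolar_spectrum
#' @param contacts Configuration ids (default the 10 of
#'   [monopolar_configs()] restricted to those with any data).
#' @return Named list of raw spectra (class `monopolar_set`).
#' @export
monopolar_spectra <- function(survey, contacts = monopolar_configs(),
                              config = detec_config()) {
  spectra <- survey_spectra(survey, config)
  out <- lapply(contacts, function(ct) {
    weighted_monopolar_spectrum(ct, survey, spectra, config)
  })
  names(out) <- contacts
  class(out) <- "monopolar_set"
  out
}

#' Choose the hemisphere analysis strategy
#'
#' Runs [detect_peak()] on each screened spectrum. If at least one
#' configuration shows a qualifying beta peak, the strategy is `"peak"` at a
#' consensus frequency (low-beta candidates preferred, then highest
#' prominence); otherwise normalized low-beta band activity is used.
#'
#' @param monos A [monopolar_spectra()] set (or any named list of raw
#'   spectra, e.g. the 15 bipolar spectra when screening bipolarly).
#' @param config A [detec_config()].
#' @return List of class `hemisphere_strategy`: `mode` ("peak" or
#'   "low_beta"), `peak_freq` (Hz, NA in low_beta mode), `peaks` (per
#'   configuration peak results) and `qc` (consensus disagreement flag when
#'   qualifying frequencies spread over more than 3 Hz).
#' @export
choose_strategy <- function(monos, config = detec_config()) {
  peaks <- lapply(monos, function(s) {
    tryCatch(detect_peak(s, band = config$beta, low_beta = config$low_beta,
                         fit_range = config$fit_range),
             error = function(e) NULL)
  })
  found <- !vapply(peaks, is.null, logical(1)) &
    vapply(peaks, function(p) isTRUE(p$found), logical(1))
  qc <- list(consensus_disagreement = FALSE, degenerate = any(
    vapply(peaks, is.null, logical(1))))
  if (!any(found)) {
    return(structure(list(mode = "low_beta", peak_freq = NA_real_,
                          peaks = peaks, qc = qc),
                     class = "hemisphere_strategy"))
  }
  freq <- vapply(peaks[found], function(p) p$peak_freq, numeric(1))
  prom <- vapply(peaks[found], function(p) p$prominence, numeric(1))
  if (diff(range(freq)) > 3) qc$consensus_disagreement <- TRUE
  pref <- freq >= config$low_beta[1] & freq <= config$low_beta[2]
  pool <- if (any(pref)) which(pref) else seq_along(freq)
  pick <- pool[which.max(prom[pool])]
  structure(list(mode = "peak", peak_freq = unname(freq[pick]),
                 peaks = peaks, qc = qc),
            class = "hemisphere_strategy")
}

#' Normalized beta activity of a flattened spectrum
#'
#' In peak mode: mean flattened power within `peak_freq` +/- the peak
#' half-width. In low-beta mode: mean flattened power over the low beta
#' band. Either score is divided by the total positive flattened power over
#' the normalization range (5-95 Hz by default), making it scale-free.
#'
#' @param spec Flattened [new_spectrum()] (see [remove_aperiodic()]).
#' @param strategy A [choose_strategy()] result (or a list with `mode` and
#'   `peak_freq`).
#' @param config A [detec_config()].
#' @return Scalar score with attribute `qc_degenerate` set to TRUE when the
#'   normalization constant is non-positive (score is then 0).
#' @export
score_activity <- function(spec, strategy, config = detec_config()) {
  stopifnot(inherits(spec, "detec_spectrum"))
  if (spec$stage != "flattened") {
    stop("score_activity expects a flattened spectrum", call. = FALSE)
  }
  band <- if (identical(strategy$mode, "peak")) {
    c(strategy$peak_freq - config$peak_halfwidth,
      strategy$peak_freq + config$peak_halfwidth)
  } else {
    config$low_beta
  }
  f <- spec$freqs
  num <- mean(spec$power[f >= band[1] & f <= band[2]])
  nr <- config$norm_range
  denom <- sum(pmax(spec$power[f >= nr[1] & f <= nr[2]], 0))
  if (!is.finite(denom) || denom <= 0) {
    return(structure(0, qc_degenerate = TRUE))
  }
  structure(num / denom, qc_degenerate = FALSE)
}

# Rank a named activity vector ascending (rank 1 = lowest, rank n = highest
# activity). Ties broken deterministically by `pref` (higher pref wins the
# higher rank); ties are reported.
.rank_with_ties <- function(activity, pref) {
  ord <- order(activity, pref)   # last entry = best
  ranks <- integer(length(activity))
  ranks[ord] <- seq_along(activity)
  names(ranks) <- names(activity)
  list(ranks = ranks, best = names(activity)[ord[length(ord)]],
       tied = anyDuplicated(activity) > 0L)
}

#' Rank the four stimulation levels by beta activity
#'
#' Scores the four level configurations (rings 0 and 3, levels 1 and 2 in
#' ring mode) under the hemisphere strategy and ranks them ascending: rank
#' #1 = lowest, rank #4 = highest activity. The best level is the rank-4
#' holder. Ties are broken toward the more ventral level and flagged.
#'
#' @param flats Named list of flattened spectra per configuration (must
#'   include "0", "1", "2", "3"); entries may carry `qc_degenerate` scores.
#' @param strategy A [choose_strategy()] result.
#' @param config A [detec_config()].
#' @return List: `level_activity` (named numeric), `level_ranks`
#'   (permutation of 1:4), `best_level` (integer 0-3), `qc` (tie /
#'   degenerate flags).
#' @export
rank_levels <- function(flats, strategy, config = detec_config()) {
  ids <- c("0", "1", "2", "3")
  missing <- setdiff(ids, names(flats))
  if (length(missing)) {
    stop("missing spectra for level configuration(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  act <- vapply(flats[ids], function(s) {
    as.numeric(score_activity(s, strategy, config))
  }, numeric(1))
  degen <- vapply(flats[ids], function(s) {
    isTRUE(attr(score_activity(s, strategy, config), "qc_degenerate"))
  }, logical(1))
  r <- .rank_with_ties(act, pref = c(4, 3, 2, 1))  # ventral wins ties
  list(level_activity = act, level_ranks = r$ranks,
       best_level = as.integer(r$best),
       qc = list(tie = r$tied, degenerate = any(degen)))
}

#' Select the best directional contact
#'
#' Uses the best level directly when it is a directional level (1 or 2);
#' when a ring wins, the neighboring directional level is analyzed instead
#' (level 0 -> 1, level 3 -> 2). The level's three segments are scored and
#' ranked ascending (rank #3 = highest); the best contact is the rank-3
#' holder. Ties break alphabetically and are flagged.
#'
#' @param flats Named list of flattened spectra including the six segments.
#' @param strategy A [choose_strategy()] result.
#' @param best_level Integer 0-3 from [rank_levels()].
#' @param config A [detec_config()].
#' @return List: `directional_level_used`, `contact_activity`,
#'   `contact_ranks` (permutation of 1:3), `best_contact`, `qc`.
#' @export
select_directional <- function(flats, strategy, best_level,
                               config = detec_config()) {
  level_used <- switch(as.character(best_level),
                       "0" = 1L, "3" = 2L, as.integer(best_level))
  segs <- segments_of_level(level_used)
  missing <- setdiff(segs, names(flats))
  if (length(missing)) {
    stop("missing spectra for segment(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  act <- vapply(flats[segs], function(s) {
    as.numeric(score_activity(s, strategy, config))
  }, numeric(1))
  r <- .rank_with_ties(act, pref = c(3, 2, 1))  # alphabetically first wins
  list(directional_level_used = level_used, contact_activity = act,
       contact_ranks = r$ranks, best_contact = r$best,
       qc = list(tie = r$tied))
}

#' Run the full contact-selection pipeline on one hemisphere survey
#'
#' Composes the stages: Welch spectra of the bipolar channels,
#' distance-weighted monopolar spectra of the 10 screened configurations,
#' aperiodic removal, strategy choice (beta peak vs low-beta band), level
#' ranking, and directional contact selection with the neighboring-level
#' fallback. Fully deterministic given the input survey.
#'
#' @param survey A [read_survey()] or [simulate_survey()] hemisphere survey.
#' @param config A [detec_config()].
#' @return Object of class `detec_selection`: `hemisphere`, `strategy`,
#'   `level_activity`, `level_ranks`, `best_level`,
#'   `directional_level_used`, `contact_activity`, `contact_ranks`,
#'   `best_contact`, `monopolar` (the weighted raw spectra), `qc`.
#' @examples
#' geom <- lead_geometry()
#' sim <- simulate_survey(source_model(source_near_segment(geom, "2B")),
#'                        noise_model(), geom, seed = 1)
#' res <- run_detec(sim$survey)
#' res$best_level; res$best_contact
#' @export
run_detec <- function(survey, config = detec_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  spectra <- stage("welch_psd", survey_spectra(survey, config))
  monos <- stage("weighted_monopolar_spectrum", {
    out <- lapply(monopolar_configs(), function(ct) {
      weighted_monopolar_spectrum(ct, survey, spectra, config)
    })
    names(out) <- monopolar_configs()
    out
  })
  # Aperiodic removal per configuration; a degenerate spectrum (all-zero
  # signal) yields an all-zero flattened spectrum and a QC flag rather than
  # an error, so ranking stays defined.
  degenerate <- character(0)
  flats <- lapply(names(monos), function(ct) {
    tryCatch(remove_aperiodic(monos[[ct]], config$fit_range)$spectrum,
             error = function(e) {
               degenerate <<- c(degenerate, ct)
               new_spectrum(spectrum_grid(),
                            rep(0, length(spectrum_grid())), "flattened")
             })
  })
  names(flats) <- names(monos)

  screened <- if (identical(config$screen, "bipolar")) spectra else monos
  strategy <- stage("choose_strategy", choose_strategy(screened, config))
  lv <- stage("rank_levels", rank_levels(flats, strategy, config))
  dc <- stage("select_directional",
              select_directional(flats, strategy, lv$best_level, config))

  structure(list(
    hemisphere = survey$hemisphere,
    strategy = strategy,
    level_activity = lv$level_activity,
    level_ranks = lv$level_ranks,
    best_level = lv$best_level,
    directional_level_used = dc$directional_level_used,
    contact_activity = dc$contact_activity,
    contact_ranks = dc$contact_ranks,
    best_contact = dc$best_contact,
    monopolar = monos,
    qc = list(level_tie = lv$qc$tie, contact_tie = dc$qc$tie,
              degenerate_configs = degenerate,
              strategy = strategy$qc,
              incomplete_montage = !isTRUE(survey$complete)),
    config = config
  ), class = "detec_selection")
}

#' @export
print.detec_selection <- function(x, ...) {
  cat("<detec_selection>", x$hemisphere, "\n")
  cat(" strategy:", x$strategy$mode,
      if (x$strategy$mode == "peak") sprintf("(%g Hz)", x$strategy$peak_freq)
      else "", "\n")
  cat(" level activity:",
      paste(sprintf("%s=%.4g", names(x$level_activity), x$level_activity),
            collapse = ", "), "\n")
  cat(" best level:", x$best_level,
      "| directional level used:", x$directional_level_used, "\n")
  cat(" best directional contact:", x$best_contact, "\n")
  invisible(x)
}
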