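# Reading and writing survey recordings, selection reports and auxiliary
# tables in documented plain-text formats.
#
# Survey JSON schema (format_version "1.0"):
#   {
#     "format_version": "1.0",
#     "hemisphere": "<subject_side label>",
#     "fs": 250,
#     "geometry": "sensight-short",        # registered dialect (optional)
#     "channels": { "0-1": [samples...], "1A-1B": [...], ... }
#   }
# Channel keys are montage pair labels (see montage_pairs()). Native device
# session files (proprietary JSON) are not parsed; users of the external
# Perceive toolbox can export per-channel series and map them onto this
# schema (channel label = anode-cathode contact pair, fs = 250).
#
# Clinical scores CSV: columns hemisphere, contact_id, efficacy.
# Coordinates CSV: columns hemisphere, contact_id, x, y, z [, side].

#' Construct a hemisphere survey
#'
#' @param recordings Named list of numeric sample vectors, keyed by channel
#'   label (e.g. `"0-1"`, `"1A-2A"`).
#' @param fs Sampling rate in Hz.
#' @param geometry A [lead_geometry()].
#' @param hemisphere Label (subject + side).
#' @return Object of class `hemisphere_survey` with a `complete` flag and
#'   the list of `missing_pairs` relative to the standard 15-pair montage.
#' @export
new_hemisphere_survey <- function(recordings, fs, geometry,
                                  hemisphere = "unknown") {
  stopifnot(inherits(geometry, "lead_geometry"))
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a positive number", call. = FALSE)
  }
  labs <- names(recordings)
  if (is.null(labs) || any(labs == "")) {
    stop("recordings must be a named list keyed by channel label",
         call. = FALSE)
  }
  for (lab in labs) split_pair(lab)  # validates contact labels
  if (anyDuplicated(labs)) {
    stop("duplicate channel labels: ",
         paste(labs[duplicated(labs)], collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(montage_pairs(), labs)
  structure(list(hemisphere = hemisphere, fs = fs,
                 recordings = lapply(recordings, as.numeric),
                 geometry = geometry,
                 complete = length(missing) == 0L,
                 missing_pairs = missing),
            class = "hemisphere_survey")
}

#' @export
print.hemisphere_survey <- function(x, ...) {
  cat("<hemisphere_survey>", x$hemisphere, "-", length(x$recordings),
      "channels at", x$fs, "Hz",
      if (x$complete) "(complete montage)" else
        paste0("(missing: ", paste(x$missing_pairs, collapse = ", "), ")"),
      "\n")
  invisible(x)
}

#' Read a survey JSON file
#'
#' @param path Path to a survey file in the documented JSON schema.
#' @param geometry A [lead_geometry()]; when `NULL`, built from the file's
#'   `geometry` field (default dialect if absent).
#' @return A [new_hemisphere_survey()]. A partial montage is accepted with
#'   a warning listing the missing pairs.
#' @export
read_survey <- function(path, geometry = NULL) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("cannot parse survey file '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (is.null(raw$channels) || !length(raw$channels)) {
    stop("survey file has no 'channels' object", call. = FALSE)
  }
  fs <- raw$fs
  if (is.null(fs) || !is.numeric(fs) || fs <= 0) {
    stop("survey file has missing or non-positive 'fs'", call. = FALSE)
  }
  if (is.null(geometry)) {
    geometry <- lead_geometry(if (is.null(raw$geometry)) "sensight-short"
                              else raw$geometry)
  }
  survey <- new_hemisphere_survey(
    raw$channels, fs = fs, geometry = geometry,
    hemisphere = if (is.null(raw$hemisphere)) "unknown" else raw$hemisphere)
  if (!survey$complete) {
    warning("survey montage incomplete; missing pairs: ",
            paste(survey$missing_pairs, collapse = ", "), call. = FALSE)
  }
  survey
}

#' Write a survey to JSON
#'
#' @param survey A [new_hemisphere_survey()].
#' @param path Destination file.
#' @return `path`, invisibly. `read_survey()` of the written file
#'   round-trips the survey.
#' @export
write_survey <- function(survey, path) {
  stopifnot(inherits(survey, "hemisphere_survey"))
  obj <- list(format_version = "1.0",
              hemisphere = survey$hemisphere,
              fs = survey$fs,
              geometry = survey$geometry$model_name,
              channels = survey$recordings)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Write a selection report to JSON
#'
#' Serializes a [run_detec()] result: strategy, per-level and per-contact
#' activity and ranks, chosen level and contact, QC flags, the resolved
#' configuration and the package version. Non-finite activity values are
#' written as `null` and flagged.
#'
#' @param result A `detec_selection`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "detec_selection"))
  nonfinite <- any(!is.finite(result$level_activity)) ||
    any(!is.finite(result$contact_activity))
  qc <- result$qc
  qc$nonfinite_activity <- nonfinite
  obj <- list(
    format_version = "1.0",
    package_version = as.character(utils::packageVersion("detecr")),
    hemisphere = result$hemisphere,
    strategy = list(mode = result$strategy$mode,
                    peak_freq = result$strategy$peak_freq),
    level_activity = as.list(result$level_activity),
    level_ranks = as.list(result$level_ranks),
    best_level = result$best_level,
    directional_level_used = result$directional_level_used,
    contact_activity = as.list(result$contact_activity),
    contact_ranks = as.list(result$contact_ranks),
    best_contact = result$best_contact,
    qc = qc,
    config = result$config)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("cannot write report: directory does not exist: ", dir,
         call. = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a selection report
#'
#' @param path A report written by [write_report()].
#' @return Named list mirroring the report structure, numeric vectors
#'   restored (JSON `null` activity becomes `NA`).
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(x) {
    out <- vapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
                  numeric(1))
    out
  }
  obj$level_activity <- num(obj$level_activity)
  obj$contact_activity <- num(obj$contact_activity)
  obj$level_ranks <- vapply(obj$level_ranks, as.integer, integer(1))
  obj$contact_ranks <- vapply(obj$contact_ranks, as.integer, integer(1))
  obj
}

#' Advisory quality-control screen of one recording
#'
#' Flags (a) constant or clipped signals, (b) ECG-like contamination
#' (periodic high-amplitude transients of roughly 150 ms width repeating at
#' 0.7-2 Hz, the QRS signature), and (c) excessive low-frequency drift.
#' Flags are advisory and never block the pipeline. The ECG flag is
#' invariant to overall amplitude scaling.
#'
#' @param samples Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @return List of logicals `constant`, `clipping`, `ecg_like`, `drift`,
#'   plus `details` (event count and median inter-event interval).
#' @export
qc_screen <- function(samples, fs = 250) {
  x <- as.numeric(samples)
  n <- length(x)
  out <- list(constant = FALSE, clipping = FALSE, ecg_like = FALSE,
              drift = FALSE, details = list())
  if (n < 2L || stats::sd(x) < 1e-12 * (abs(mean(x)) + 1)) {
    out$constant <- TRUE
    return(out)
  }
  rng <- range(x)
  at_rail <- mean(x == rng[1] | x == rng[2])
  out$clipping <- at_rail > 0.05

  # ECG-like: amplitude-normalized deviations, clustered into events; flag
  # when many events recur regularly at a cardiac rate.
  med <- stats::median(x)
  madv <- stats::mad(x)
  if (madv > 0) {
    z <- abs(x - med) / madv
    hits <- which(z > 3.5)
    if (length(hits) >= 3L) {
      gaps <- diff(hits)
      starts <- hits[c(TRUE, gaps > 0.1 * fs)]  # merge within 100 ms
      if (length(starts) >= 8L) {
        iv <- diff(starts) / fs
        base <- stats::median(iv)
        # tolerate missed beats: intervals should be near-integer
        # multiples of the base period
        mult <- iv / base
        regular <- mean(abs(mult - round(mult)) < 0.15) > 0.8
        out$ecg_like <- base >= 0.5 && base <= 1 / 0.7 && regular
        out$details <- list(n_events = length(starts),
                            base_interval_s = base)
      }
    }
  }

  # Drift: slow polynomial trend explaining most of the variance.
  tt <- seq_len(n) / n
  trend <- stats::lm.fit(cbind(1, tt, tt^2, tt^3), x)$fitted.values
  out$drift <- stats::var(trend) / stats::var(x) > 0.5
  out
}

#' Read clinical monopolar-review scores
#'
#' Expects columns `hemisphere`, `contact_id`, `efficacy` (the baseline
#' StimOFF-MedOFF score sum minus the StimON sum of the rigidity and
#' akinesia items; half-point resolution).
#'
#' @param path CSV file.
#' @return Data frame with the three columns, `contact_id` as character.
#' @export
read_clinical_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("hemisphere", "contact_id", "efficacy")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("clinical scores CSV lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$contact_id <- as.character(df$contact_id)
  df$efficacy <- as.numeric(df$efficacy)
  df
}

#' Read per-contact coordinates
#'
#' Expects columns `hemisphere`, `contact_id`, `x`, `y`, `z` in MNI mm and
#' optionally `side` (`"left"`/`"right"`; inferred from the sign of `x`
#' when absent).
#'
#' @param path CSV file.
#' @return Data frame with a guaranteed `side` column.
#' @export
read_contact_coords <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("hemisphere", "contact_id", "x", "y", "z")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("coordinates CSV lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$contact_id <- as.character(df$contact_id)
  if (is.null(df$side)) df$side <- ifelse(df$x > 0, "right", "left")
  df
}
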