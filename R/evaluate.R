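# Evaluation against clinical monopolar-review scores: rank correlation,
# selection match rates and sweet-spot distance analysis.

# All permutations of 1..n as an n! x n matrix (n <= 9).
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes Spearman's rho with average-rank tie handling. The two-sided
#' p-value is exact (full enumeration of the n! orderings of one variable)
#' for n <= 9, and otherwise uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List: `rho`, `p`, `n`, `method` ("exact" or "t-approximation").
#' @examples
#' spearman_rank(1:4, c(2, 1, 4, 3))  # rho = 0.6
#' @export
spearman_rank <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("NA values are not allowed", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("undefined correlation: one of the series has zero variance",
         call. = FALSE)
  }
  rho_of <- function(a, b) {
    a <- a - mean(a); b <- b - mean(b)
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  rho <- rho_of(rx, ry)
  if (n <= 9L) {
    perms <- .permutations(n)
    rhos <- apply(perms, 1L, function(p) rho_of(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tval <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

# Clinical level / segment ranking for one hemisphere's score table.
.clinical_best <- function(scores, ids) {
  sub <- scores[scores$contact_id %in% ids, ]
  if (nrow(sub) < length(ids)) return(NULL)
  eff <- stats::setNames(sub$efficacy, sub$contact_id)[ids]
  best <- names(eff)[eff == max(eff)]
  list(efficacy = eff, best = best, tied = length(best) > 1L)
}

#' Agreement between algorithmic selections and clinical review
#'
#' For each hemisphere present in both inputs, compares the selected
#' stimulation level and directional contact with the clinically most
#' effective ones. Reports the fraction of hemispheres where the selected
#' level is the clinical argmax, where the clinically best level carries
#' the highest or second-highest beta activity (top-2 agreement), and where
#' the selected directional contact is the clinical argmax among the three
#' segments of the analyzed level. Clinical ties count as a match when the
#' selection belongs to the tied argmax set (flagged in the output).
#'
#' @param selections Named list of `detec_selection` objects (names =
#'   hemisphere labels; unnamed lists use each element's `hemisphere`).
#' @param clinical Data frame from [read_clinical_scores()].
#' @return List: `level_match`, `level_top2`, `contact_match` (rates in
#'   \[0, 1\]), `n` (hemispheres compared), `excluded` (labels lacking
#'   clinical data), `per_hemisphere` (tidy data frame).
#' @export
match_rates <- function(selections, clinical) {
  if (is.null(names(selections)) || any(names(selections) == "")) {
    names(selections) <- vapply(selections, function(s) s$hemisphere,
                                character(1))
  }
  rows <- list()
  excluded <- character(0)
  for (hemi in names(selections)) {
    sel <- selections[[hemi]]
    sc <- clinical[clinical$hemisphere == hemi, ]
    lv <- .clinical_best(sc, c("0", "1", "2", "3"))
    segs <- segments_of_level(sel$directional_level_used)
    ct <- .clinical_best(sc, segs)
    if (is.null(lv) || is.null(ct)) {
      excluded <- c(excluded, hemi)
      next
    }
    top2 <- names(sel$level_ranks)[sel$level_ranks >= 3L]
    rows[[hemi]] <- data.frame(
      hemisphere = hemi,
      level_match = as.character(sel$best_level) %in% lv$best,
      level_top2 = any(lv$best %in% top2),
      contact_match = sel$best_contact %in% ct$best,
      clinical_tie = lv$tied || ct$tied,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    stop("no hemisphere has both a selection and complete clinical scores",
         call. = FALSE)
  }
  if (length(excluded)) {
    warning("excluded hemispheres without complete clinical data: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  }
  tab <- do.call(rbind, rows)
  list(level_match = mean(tab$level_match),
       level_top2 = mean(tab$level_top2),
       contact_match = mean(tab$contact_match),
       n = nrow(tab), excluded = excluded, per_hemisphere = tab)
}

#' Distance-to-sweet-spot analysis of contact activity
#'
#' Z-scores activity within each hemisphere, mirrors right-hemisphere
#' coordinates onto the left by flipping the sign of x (a documented
#' simplification of nonlinear mirroring), computes Euclidean distances to
#' the given sweet-spot center, and correlates z-scored activity with
#' distance (Pearson).
#'
#' @param activity Data frame with columns `hemisphere`, `contact_id`,
#'   `activity`.
#' @param coords Data frame from [read_contact_coords()].
#' @param spot Numeric length-3 MNI mm center (left hemisphere), e.g. the
#'   published anatomical STN sweet spot `c(-12.5, -12.72, -5.38)` or the
#'   electrophysiological one `c(-12.2, -12.5, -6.4)`.
#' @return List: `table` (per-contact z-scored activity and distance),
#'   `r`, `p`, `n`.
#' @export
sweetspot_distance_analysis <- function(activity, coords,
                                        spot = c(-12.5, -12.72, -5.38)) {
  need <- c("hemisphere", "contact_id", "activity")
  if (!all(need %in% names(activity))) {
    stop("activity must have columns hemisphere, contact_id, activity",
         call. = FALSE)
  }
  df <- merge(activity, coords, by = c("hemisphere", "contact_id"))
  if (nrow(df) < 3L) {
    stop("insufficient data: fewer than 3 contacts with coordinates",
         call. = FALSE)
  }
  # Per-hemisphere z-scoring enables pooling across subjects.
  for (hemi in unique(df$hemisphere)) {
    idx <- df$hemisphere == hemi
    s <- stats::sd(df$activity[idx])
    if (!is.finite(s) || s == 0) {
      stop("undefined correlation: activity is constant within hemisphere ",
           hemi, call. = FALSE)
    }
    df$activity_z[idx] <- (df$activity[idx] - mean(df$activity[idx])) / s
  }
  flip <- df$side == "right"
  df$x_pooled <- ifelse(flip, -df$x, df$x)
  df$distance <- sqrt((df$x_pooled - spot[1])^2 + (df$y - spot[2])^2 +
                        (df$z - spot[3])^2)
  ct <- stats::cor.test(df$activity_z, df$distance)
  list(table = df[, c("hemisphere", "contact_id", "activity_z",
                      "x_pooled", "y", "z", "distance")],
       r = unname(ct$estimate), p = ct$p.value, n = nrow(df))
}

#' Tidy long-format activity table from selections
#'
#' One row per hemisphere and screened configuration with its activity and
#' rank (levels and directional contacts), for export to external
#' statistics environments.
#'
#' @param selections Named list of `detec_selection` objects.
#' @return Data frame: hemisphere, contact_id, role ("level"/"segment"),
#'   activity, rank, strategy.
#' @export
selection_table <- function(selections) {
  if (is.null(names(selections)) || any(names(selections) == "")) {
    names(selections) <- vapply(selections, function(s) s$hemisphere,
                                character(1))
  }
  rows <- lapply(names(selections), function(hemi) {
    s <- selections[[hemi]]
    rbind(
      data.frame(hemisphere = hemi, contact_id = names(s$level_activity),
                 role = "level", activity = unname(s$level_activity),
                 rank = unname(s$level_ranks[names(s$level_activity)]),
                 strategy = s$strategy$mode, stringsAsFactors = FALSE),
      data.frame(hemisphere = hemi, contact_id = names(s$contact_activity),
                 role = "segment", activity = unname(s$contact_activity),
                 rank = unname(s$contact_ranks[names(s$contact_activity)]),
                 strategy = s$strategy$mode, stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
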