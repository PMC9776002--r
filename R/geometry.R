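# Geometric model of an 8-contact directional DBS lead.
#
# Lead-local frame: z along the shaft (ventral contact 0 at the origin,
# dorsal direction positive), x/y in the axial plane. Ring contacts sit on
# the shaft axis; segment "centers" are the centers of the contact's outer
# surface, i.e. points on the cylinder wall 120 degrees apart. Levels 1 and 2
# driven/recorded as whole rings ("ring mode") are represented by virtual
# contacts "1" and "2" located on the axis at the level's z.

# Registered lead dialects. Center-to-center axial spacing between adjacent
# levels is contact_height + inter_level_gap.
.lead_dialects <- list(
  "sensight-short" = list(contact_height = 1.5, inter_level_gap = 0.5,
                          lead_diameter = 1.27),
  "sensight-long"  = list(contact_height = 1.5, inter_level_gap = 1.5,
                          lead_diameter = 1.27)
)

#' Physical contact identifiers of a directional lead
#'
#' @return Character vector of the 8 contact ids in ventral-to-dorsal order.
#' @export
lead_contacts <- function() {
  c("0", "1A", "1B", "1C", "2A", "2B", "2C", "3")
}

#' The ten monopolar screening configurations
#'
#' The two ring contacts, the two directional levels in ring mode (virtual
#' contacts "1" and "2") and the six directional segments: the configurations
#' tested during a monopolar review and screened by the selection algorithm.
#'
#' @return Character vector of 10 configuration ids.
#' @export
monopolar_configs <- function() {
  c("0", "1", "2", "3", "1A", "1B", "1C", "2A", "2B", "2C")
}

#' Segments belonging to a directional level
#'
#' @param level Integer, 1 or 2.
#' @return Character vector of the three segment ids.
#' @export
segments_of_level <- function(level) {
  if (!level %in% c(1L, 2L)) {
    stop("only levels 1 and 2 carry directional segments", call. = FALSE)
  }
  paste0(level, c("A", "B", "C"))
}

#' Level index of a contact or configuration id
#'
#' @param id Contact id such as "0", "1A" or the ring-mode virtual "2".
#' @return Integer level 0-3.
#' @export
contact_level <- function(id) {
  lv <- suppressWarnings(as.integer(substr(id, 1L, 1L)))
  if (any(is.na(lv)) || any(lv < 0L | lv > 3L)) {
    stop("unknown contact id: ", paste(id[is.na(lv) | lv < 0 | lv > 3],
                                       collapse = ", "), call. = FALSE)
  }
  lv
}

#' Build the geometry of a directional DBS lead
#'
#' Constructs contact identities and 3-D center coordinates (mm, lead-local
#' frame) for an 8-contact directional lead: ventral ring (contact 0), two
#' segmented levels (1A/1B/1C, 2A/2B/2C) and dorsal ring (contact 3).
#' Dimensions come from a registered dialect and can be overridden
#' individually; the dialect defaults are the published datasheet values of
#' the corresponding hardware.
#'
#' @param model_name Registered dialect, one of `"sensight-short"`
#'   (0.5 mm inter-level gap, 2.0 mm center spacing) or `"sensight-long"`
#'   (1.5 mm gap, 3.0 mm spacing). Ignored dimensions may be overridden.
#' @param contact_height Contact height in mm (default from dialect).
#' @param inter_level_gap Gap between adjacent levels in mm.
#' @param lead_diameter Lead body diameter in mm.
#' @param segment_azimuths_deg Named numeric vector giving the azimuth
#'   (degrees, x-axis = 0) of segments A, B, C on each level.
#' @return An object of class `lead_geometry`: list with the dimensions, the
#'   level spacing, and a `contacts` data frame (id, level, kind, x, y, z).
#' @examples
#' geom <- lead_geometry("sensight-short")
#' contact_distance(geom, "1A", "1B")
#' @export
lead_geometry <- function(model_name = "sensight-short",
                          contact_height = NULL,
                          inter_level_gap = NULL,
                          lead_diameter = NULL,
                          segment_azimuths_deg = c(A = 90, B = 210, C = 330)) {
  dialect <- .lead_dialects[[model_name]]
  if (is.null(dialect) &&
      (is.null(contact_height) || is.null(inter_level_gap) ||
       is.null(lead_diameter))) {
    stop("unknown lead model '", model_name, "' and no complete override; ",
         "registered dialects: ",
         paste(names(.lead_dialects), collapse = ", "), call. = FALSE)
  }
  ch <- if (is.null(contact_height)) dialect$contact_height else contact_height
  gap <- if (is.null(inter_level_gap)) dialect$inter_level_gap else inter_level_gap
  dia <- if (is.null(lead_diameter)) dialect$lead_diameter else lead_diameter
  if (!is.finite(ch) || ch <= 0 || !is.finite(gap) || gap < 0 ||
      !is.finite(dia) || dia <= 0) {
    stop("degenerate lead dimensions: contact_height and lead_diameter must ",
         "be > 0 and inter_level_gap >= 0", call. = FALSE)
  }
  if (!setequal(names(segment_azimuths_deg), c("A", "B", "C"))) {
    stop("segment_azimuths_deg must name segments A, B and C", call. = FALSE)
  }
  spacing <- ch + gap
  r <- dia / 2
  az <- segment_azimuths_deg[c("A", "B", "C")] * pi / 180

  rows <- list(data.frame(id = "0", level = 0L, kind = "ring",
                          x = 0, y = 0, z = 0))
  for (lv in 1:2) {
    rows[[length(rows) + 1L]] <- data.frame(
      id = paste0(lv, c("A", "B", "C")), level = lv, kind = "segment",
      x = r * cos(az), y = r * sin(az), z = lv * spacing)
  }
  rows[[length(rows) + 1L]] <- data.frame(id = "3", level = 3L, kind = "ring",
                                          x = 0, y = 0, z = 3 * spacing)
  contacts <- do.call(rbind, rows)
  rownames(contacts) <- contacts$id

  structure(list(model_name = model_name, contact_height = ch,
                 inter_level_gap = gap, lead_diameter = dia,
                 level_spacing = spacing, radius = r, contacts = contacts),
            class = "lead_geometry")
}

#' @export
print.lead_geometry <- function(x, ...) {
  cat("<lead_geometry>", x$model_name, "\n",
      " contact height", x$contact_height, "mm, gap", x$inter_level_gap,
      "mm, diameter", x$lead_diameter, "mm\n",
      " level spacing", x$level_spacing, "mm;",
      nrow(x$contacts), "contacts\n")
  invisible(x)
}

#' Center coordinates of a contact or ring-mode virtual contact
#'
#' @param geom A [lead_geometry()].
#' @param id Physical contact id ("0", "1A", ..., "3") or ring-mode virtual
#'   id ("1", "2"), whose center lies on the shaft axis at the level's z.
#' @return Numeric length-3 vector (x, y, z) in mm.
#' @export
contact_center <- function(geom, id) {
  stopifnot(inherits(geom, "lead_geometry"))
  if (id %in% rownames(geom$contacts)) {
    return(as.numeric(geom$contacts[id, c("x", "y", "z")]))
  }
  if (id %in% c("1", "2")) {
    return(c(0, 0, as.integer(id) * geom$level_spacing))
  }
  stop("unknown contact id: ", id, call. = FALSE)
}

#' Distance between two contact centers
#'
#' Euclidean distance in mm between contact centers; these are the weights
#' 1/d used when averaging bipolar recordings onto a monopolar contact.
#' Ring (and ring-mode virtual) centers lie on the shaft axis, segment
#' centers on the cylinder wall.
#'
#' @inheritParams contact_center
#' @param a,b Distinct contact ids (virtual "1"/"2" allowed).
#' @param mode `"3d"` (default) for the full Euclidean distance, or
#'   `"axial"` to use only the along-shaft component (sensitivity analyses;
#'   falls back to the 3-D distance when the axial component is zero, e.g.
#'   for intra-level segment pairs).
#' @return Distance in mm, strictly positive.
#' @export
contact_distance <- function(geom, a, b, mode = c("3d", "axial")) {
  mode <- match.arg(mode)
  if (identical(a, b)) {
    stop("invalid contact pair: '", a, "' paired with itself", call. = FALSE)
  }
  pa <- contact_center(geom, a)
  pb <- contact_center(geom, b)
  d3 <- sqrt(sum((pa - pb)^2))
  if (mode == "axial") {
    dz <- abs(pa[3] - pb[3])
    return(if (dz > 0) dz else d3)
  }
  d3
}

#' All pairwise contact distances
#'
#' @inheritParams contact_center
#' @param ids Contact ids to include (default: the 8 physical contacts).
#' @param mode Passed to [contact_distance()].
#' @return Symmetric numeric matrix of distances in mm, zero diagonal.
#' @export
distance_matrix <- function(geom, ids = lead_contacts(), mode = "3d") {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- contact_distance(geom, ids[i], ids[j], mode)
    }
  }
  m
}

#' The 15-channel bipolar survey montage
#'
#' The standard survey montage of a sensing-enabled directional lead:
#' 6 ring/level pairs (levels 1 and 2 recorded in ring mode), 6 intra-level
#' segment pairs and 3 inter-level segment pairs.
#'
#' @return Character vector of 15 channel labels, e.g. `"0-1"`, `"1A-2A"`.
#' @export
montage_pairs <- function() {
  c("0-1", "0-2", "0-3", "1-2", "1-3", "2-3",
    "1A-1B", "1A-1C", "1B-1C", "2A-2B", "2A-2C", "2B-2C",
    "1A-2A", "1B-2B", "1C-2C")
}

# Split "1A-2A" into c("1A", "2A"); validates both members.
split_pair <- function(label) {
  parts <- strsplit(label, "-", fixed = TRUE)[[1]]
  valid <- c(lead_contacts(), "1", "2")
  if (length(parts) != 2L || !all(parts %in% valid)) {
    stop("malformed or unknown channel label: '", label, "'", call. = FALSE)
  }
  if (parts[1] == parts[2]) {
    stop("invalid channel label (contact paired with itself): '", label, "'",
         call. = FALSE)
  }
  parts
}
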