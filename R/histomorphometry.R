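#' Average sutural width from section measurements
#'
#' The histomorphometric width statistic: the ratio between the unossified
#' sutural area (um^2) and the length of the central suture trace (um) on a
#' stained section. For a rectangular band of width w this is exactly w;
#' for a curved suture it is the mean gap width along the trace.
#'
#' @param area_um2 sutural area in square micrometres (vectorized).
#' @param length_um trace length in micrometres.
#' @return width in micrometres (full precision; see [histo_widths()] for
#'   the integer-rounded report).
#' @export
average_width <- function(area_um2, length_um) {
  if (any(!is.na(area_um2) & area_um2 <= 0) ||
      any(!is.na(length_um) & length_um <= 0))
    stop("area and trace length must be positive")
  area_um2 / length_um
}

#' Skull-length-normalized sutural width
#'
#' Dimensionless ratio: average width (um) over skull length converted to
#' um (1 cm = 1e4 um). Units are explicit at this boundary to prevent
#' silent ten-fold errors: section skull lengths are recorded in cm.
#'
#' @param area_um2,length_um as in [average_width()].
#' @param skull_length_cm skull length in centimetres.
#' @return dimensionless normalized width.
#' @export
normalized_width <- function(area_um2, length_um, skull_length_cm) {
  if (any(is.na(skull_length_cm)) || any(skull_length_cm <= 0, na.rm = TRUE))
    stop("skull length (cm) must be present and positive")
  average_width(area_um2, length_um) / (skull_length_cm * 1e4)
}

# round half up (printed tables round 208.56 -> 209)
round_half_up <- function(x) floor(x + 0.5)

#' Width table for a set of sections
#'
#' Computes full-precision and integer-rounded (half-up) average widths and,
#' where skull length is available, the normalized width, for a section
#' table as read by [read_suture_sections()].
#'
#' @param sections data frame with `area_um2`, `length_um` and optional
#'   `skull_length_cm`.
#' @return the input with `width_um`, `width_um_rounded` and
#'   `normalized_width` columns appended.
#' @export
histo_widths <- function(sections) {
  w <- average_width(sections$area_um2, sections$length_um)
  sections$width_um <- w
  sections$width_um_rounded <- round_half_up(w)
  sections$normalized_width <-
    ifelse(is.na(sections$skull_length_cm), NA_real_,
           w / (sections$skull_length_cm * 1e4))
  sections
}

#' Area and trace length of a section polygon
#'
#' Shoelace area of the closed sutural-space loop and Euclidean polyline
#' length of the central trace, both in micrometre units.
#'
#' @param poly a `section_polygon` (see [sim_suture_section()]) or a list
#'   with `loop` (n x 2 closed coordinate loop, first point not repeated)
#'   and `trace` (m x 2 polyline).
#' @param check_simple verify that the loop is simple (non-self-intersecting).
#' @return named vector `c(area = , trace_length = )`.
#' @export
polygon_measures <- function(poly, check_simple = TRUE) {
  loop <- poly$loop; trace <- poly$trace
  stopifnot(is.matrix(loop), ncol(loop) == 2, nrow(loop) >= 3)
  if (check_simple && !is_simple_polygon(loop))
    stop("self-intersecting section outline")
  x <- loop[, 1]; y <- loop[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  area <- abs(sum(x * ys - xs * y)) / 2
  tl <- sum(sqrt(diff(trace[, 1])^2 + diff(trace[, 2])^2))
  if (tl <= 0) stop("trace length must be positive")
  c(area = area, trace_length = tl)
}

# no two non-adjacent boundary segments strictly cross (segments sharing an
# endpoint never "strictly" cross, which also covers the wrap-around pair)
is_simple_polygon <- function(loop) {
  is.null(first_polyline_crossing(rbind(loop, loop[1, , drop = FALSE])))
}

#' Width through a maturity-ordered series of sections
#'
#' For each articulation: the widths in maturity order, their successive
#' differences and a monotonicity flag (`increasing`, `non-decreasing`,
#' `decreasing`, `non-increasing`, `constant`, `mixed`).
#'
#' @param sections section table with a numeric `maturity_rank` column
#'   sorted increasing within each articulation (an unordered table is an
#'   error, not silently reordered).
#' @param value which column to trend (default the computed `width_um`).
#' @return data frame with one row per articulation.
#' @export
width_trend <- function(sections, value = "width_um") {
  if (is.null(sections$maturity_rank))
    stop("sections need a 'maturity_rank' column ordered by maturity")
  if (!value %in% names(sections)) sections <- histo_widths(sections)
  out <- lapply(split(sections, sections$articulation), function(d) {
    if (is.unsorted(d$maturity_rank, strictly = FALSE))
      stop("sections for '", d$articulation[1],
           "' are not ordered by maturity")
    w <- d[[value]][!is.na(d[[value]])]
    if (length(w) < 2L)
      stop("need >= 2 measured sections per articulation")
    dl <- diff(w)
    flag <- if (all(dl > 0)) "increasing"
            else if (all(dl >= 0) && any(dl > 0)) "non-decreasing"
            else if (all(dl < 0)) "decreasing"
            else if (all(dl <= 0) && any(dl < 0)) "non-increasing"
            else if (all(dl == 0)) "constant"
            else "mixed"
    data.frame(articulation = d$articulation[1], n = length(w),
               first = w[1], last = w[length(w)],
               trend = flag, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
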