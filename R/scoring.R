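#' Numeric score of one matrix cell
#'
#' A cell's score is the arithmetic mean of its states: a suture open in one
#' region (0) and partially closed in another (1) scores 0.5. Missing cells
#' score `NA`.
#'
#' @param cell integer state vector, or `NA`.
#' @return numeric score or `NA`.
#' @export
cell_score <- function(cell) {
  if (is_missing_cell(cell)) return(NA_real_)
  mean(cell)
}

# specimens x characters numeric score table
score_table <- function(matrix) {
  sc <- vapply(matrix$cells, cell_score, numeric(1))
  base::matrix(sc, nrow = length(matrix$taxa),
               dimnames = list(matrix$taxa, matrix$chars$char_id))
}

#' Averaged degree of sutural closure or interdigitation of one specimen
#'
#' Unweighted mean of the cell scores over all characters of the requested
#' aspect (closure scores lie in 0--3, interdigitation in 0--2), optionally
#' restricted to one anatomical group. Missing cells are excluded from the
#' denominator; every character -- including multiple views of the same
#' suture -- counts once.
#'
#' @param matrix a [character_matrix()].
#' @param specimen specimen id.
#' @param aspect `"closure"` or `"interdigitation"`.
#' @param group optional anatomical group (`"facial"`, `"cranial"`,
#'   `"palatal"`, `"braincase"`).
#' @return numeric average.
#' @export
specimen_average <- function(matrix, specimen,
                             aspect = c("closure", "interdigitation"),
                             group = NULL) {
  aspect <- match.arg(aspect)
  i <- match(specimen, matrix$taxa)
  if (is.na(i)) i <- match(canonical_id(specimen), canonical_id(matrix$taxa))
  if (is.na(i)) stop("specimen '", specimen, "' not in matrix")
  sel <- matrix$chars$aspect == aspect
  if (!is.null(group)) sel <- sel & matrix$chars$group == group
  if (!any(sel)) stop("no characters of aspect '", aspect, "'",
                      if (!is.null(group)) paste0(" in group '", group, "'"))
  sc <- vapply(matrix$cells[i, sel, drop = TRUE], cell_score, numeric(1))
  if (all(is.na(sc))) stop("specimen '", specimen, "' has no scorable ",
                           aspect, " characters")
  mean(sc, na.rm = TRUE)
}

#' Per-specimen score averages with anatomical-group breakdown
#'
#' @param matrix a [character_matrix()].
#' @return data frame with one row per specimen: `closure_avg`,
#'   `interdigitation_avg` (when such characters exist), per-group closure
#'   columns and `n_scored`.
#' @export
specimen_averages <- function(matrix) {
  sc <- score_table(matrix)
  asp <- matrix$chars$aspect
  out <- data.frame(specimen_id = matrix$taxa, stringsAsFactors = FALSE)
  if (any(asp == "closure")) {
    out$closure_avg <- rowMeans(sc[, asp == "closure", drop = FALSE],
                                na.rm = TRUE)
  }
  if (any(asp == "interdigitation")) {
    out$interdigitation_avg <-
      rowMeans(sc[, asp == "interdigitation", drop = FALSE], na.rm = TRUE)
  }
  for (g in intersect(ANATOMICAL_GROUPS, unique(matrix$chars$group))) {
    selg <- asp == "closure" & matrix$chars$group == g
    if (any(selg))
      out[[paste0("closure_", g)]] <- rowMeans(sc[, selg, drop = FALSE],
                                               na.rm = TRUE)
  }
  out$n_scored <- rowSums(!is.na(sc))
  out
}

#' Averaged closure/interdigitation of an ontogenetic category
#'
#' Pools all cell scores of the category's specimens (grand mean of cells;
#' `method = "pooled"`, the default) or averages the specimen means
#' (`method = "specimen_mean"`). With near-complete matrices the two differ
#' negligibly; both are exposed.
#'
#' @param matrix a [character_matrix()].
#' @param records specimen metadata with `specimen_id` and `category`.
#' @param aspect `"closure"` or `"interdigitation"`.
#' @param category one of the ontogenetic categories.
#' @param method `"pooled"` or `"specimen_mean"`.
#' @return numeric average.
#' @export
category_average <- function(matrix, records,
                             aspect = c("closure", "interdigitation"),
                             category, method = c("pooled", "specimen_mean")) {
  aspect <- match.arg(aspect); method <- match.arg(method)
  ids <- records$specimen_id[records$category == category]
  idx <- match(canonical_id(ids), canonical_id(matrix$taxa))
  idx <- idx[!is.na(idx)]
  if (!length(idx)) stop("no specimens of category '", category, "' in matrix")
  sel <- matrix$chars$aspect == aspect
  sc <- score_table(matrix)[idx, sel, drop = FALSE]
  if (method == "pooled") mean(sc, na.rm = TRUE)
  else mean(rowMeans(sc, na.rm = TRUE), na.rm = TRUE)
}

#' Fraction of fully obliterated sutures in one specimen
#'
#' Closure characters are grouped by suture; a suture counts as obliterated
#' only when every scored view-cell is exactly `{3}` (a polymorphic cell
#' containing 3 does not count: complete obliteration means absolutely no
#' trace of the suture line). Sutures with no scored cell are excluded from
#' the denominator.
#'
#' @param matrix a [character_matrix()].
#' @param specimen specimen id.
#' @return fraction in 0--1.
#' @export
obliteration_fraction <- function(matrix, specimen) {
  i <- match(specimen, matrix$taxa)
  if (is.na(i)) i <- match(canonical_id(specimen), canonical_id(matrix$taxa))
  if (is.na(i)) stop("specimen '", specimen, "' not in matrix")
  sel <- which(matrix$chars$aspect == "closure")
  if (!length(sel)) stop("no closure characters in matrix")
  sutures <- split(sel, matrix$chars$suture[sel])
  status <- vapply(sutures, function(js) {
    cells <- matrix$cells[i, js, drop = TRUE]
    scored <- cells[!vapply(cells, is_missing_cell, logical(1))]
    if (!length(scored)) return(NA)
    all(vapply(scored, function(cl) identical(cl, 3L), logical(1)))
  }, logical(1))
  if (all(is.na(status))) stop("specimen '", specimen, "' has no scorable suture")
  mean(status, na.rm = TRUE)
}

#' Ontogenetic staging schemes
#'
#' A staging scheme maps a length variable to ordered ontogenetic
#' categories via lower bounds (inclusive) on consecutive intervals that
#' cover the positive axis.
#'
#' @param categories category names, ordered from least to most mature.
#' @param lower_bounds numeric lower bounds, same length, starting at 0 and
#'   strictly increasing.
#' @param variable which length the bounds refer to:
#'   `"total_length_cm"` or `"skull_length_mm"`.
#' @return object of class `staging_scheme`.
#' @export
staging_scheme <- function(categories, lower_bounds,
                           variable = c("total_length_cm", "skull_length_mm")) {
  variable <- match.arg(variable)
  stopifnot(length(categories) == length(lower_bounds),
            lower_bounds[1] == 0, !is.unsorted(lower_bounds, strictly = TRUE))
  structure(list(categories = as.character(categories),
                 lower_bounds = as.numeric(lower_bounds),
                 variable = variable),
            class = "staging_scheme")
}

#' @rdname staging_scheme
#' @details `alligator_staging()` uses the published total-length bounds:
#'   juveniles to 121 cm, sub-adults from 122 cm, sexually mature from
#'   201 cm, skeletally mature from 271 cm. `emu_staging()` stages on skull
#'   length (mm); because the observed category ranges overlap, its bounds
#'   (97/143/152 mm) are the least-mature skull length observed in each
#'   category.
#' @export
alligator_staging <- function() {
  staging_scheme(CATEGORY_LEVELS, c(0, 122, 201, 271), "total_length_cm")
}

#' @rdname staging_scheme
#' @export
emu_staging <- function() {
  staging_scheme(c("juvenile", "subadult", "skeletally_mature",
                   "sexually_mature"),
                 c(0, 97, 143, 152), "skull_length_mm")
}

#' Assign an ontogenetic category from a staging scheme
#'
#' @param length_value numeric length (units of the scheme's variable), or a
#'   specimen record (one-row data frame / list with the variable).
#' @param scheme a [staging_scheme()].
#' @return category string; `"unknown"` with a warning when the length is
#'   missing.
#' @export
assign_category <- function(length_value, scheme) {
  if (is.list(length_value)) length_value <- length_value[[scheme$variable]]
  if (is.null(length_value) || length(length_value) == 0L ||
      is.na(length_value)) {
    warning("missing ", scheme$variable, "; category unknown")
    return("unknown")
  }
  if (length_value <= 0) stop("length must be positive")
  scheme$categories[findInterval(length_value, scheme$lower_bounds)]
}
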