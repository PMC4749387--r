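#' Character matrices of ontogenetic sutural characters
#'
#' A `character_matrix` holds an ordered set of specimens (taxa) scored for
#' multistate ontogenetic characters. Each cell is a non-empty set of integer
#' states (a polymorphic cell holds two or more states, e.g. a suture that is
#' open in one region and partially closed in another) or is missing.
#' Characters carry metadata: the suture or synchondrosis they describe, its
#' anatomical group, whether they grade closure (states 0--3: open, partially
#' closed, closed, obliterated) or interdigitation (states 0--2: straight,
#' slightly, very interdigitated), and the anatomical view they were scored
#' in.
#'
#' @param taxa character vector of unique specimen identifiers.
#' @param cells a list-matrix (`nrow = length(taxa)`, `ncol = nrow(chars)`);
#'   each element an integer vector of states, or `NA` for a missing score.
#'   A plain character matrix of cell tokens (`"0"`, `"(01)"`, `"?"`) is also
#'   accepted.
#' @param chars data frame of character definitions with columns `char_id`,
#'   `suture`, `group`, `aspect`, `view`, `max_state`. If `NULL`, generic
#'   closure characters (`max_state = 3`) are generated.
#' @param notation optional character matrix recording the original NEXUS
#'   grouping style per cell (`"paren"` or `"brace"`); retained so a stricter
#'   polymorphism treatment can distinguish the two.
#' @return an object of class `character_matrix`.
#' @seealso [read_nexus_matrix()], [write_nexus_matrix()],
#'   [add_hypothetical_outgroup()]
#' @export
character_matrix <- function(taxa, cells, chars = NULL, notation = NULL) {
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa))
    stop("duplicate taxon ids: ", paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (is.character(cells)) {
    cells <- matrix(lapply(cells, parse_cell_token), nrow = nrow(cells))
  }
  if (!is.list(cells)) stop("'cells' must be a list-matrix or token matrix")
  if (is.null(dim(cells)))
    stop("'cells' must have dim attributes (taxa x characters)")
  if (nrow(cells) != length(taxa))
    stop("cells has ", nrow(cells), " rows but there are ", length(taxa), " taxa")
  if (is.null(chars)) chars <- generic_chardefs(ncol(cells))
  chars <- validate_chardefs(chars)
  if (ncol(cells) != nrow(chars))
    stop("cells has ", ncol(cells), " columns but there are ", nrow(chars),
         " character definitions")
  cells <- matrix(lapply(cells, normalize_cell), nrow = length(taxa),
                  dimnames = list(taxa, chars$char_id))
  obj <- structure(list(taxa = taxa, chars = chars, cells = cells,
                        notation = notation),
                   class = "character_matrix")
  validate_character_matrix(obj)
  obj
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("character_matrix: ", length(x$taxa), " taxa x ", nrow(x$chars),
      " characters\n", sep = "")
  asp <- table(x$chars$aspect)
  cat("  aspects:", paste(names(asp), asp, sep = "=", collapse = ", "), "\n")
  nmiss <- sum(vapply(x$cells, is_missing_cell, logical(1)))
  npoly <- sum(vapply(x$cells, function(z) !is_missing_cell(z) && length(z) > 1,
                      logical(1)))
  cat("  missing cells:", nmiss, " polymorphic cells:", npoly, "\n")
  invisible(x)
}

#' @export
dim.character_matrix <- function(x) c(length(x$taxa), nrow(x$chars))

# -- internal helpers ---------------------------------------------------------

is_missing_cell <- function(cell) length(cell) == 1L && is.na(cell[1L])

normalize_cell <- function(cell) {
  if (is.null(cell) || (length(cell) == 0L)) return(NA_integer_)
  cell <- as.integer(cell)
  if (anyNA(cell)) return(NA_integer_)
  sort(unique(cell))
}

parse_cell_token <- function(tok) {
  tok <- trimws(tok)
  if (tok %in% c("?", "-", "")) return(NA_integer_)
  body <- gsub("[(){}]", "", tok)
  st <- suppressWarnings(as.integer(strsplit(body, "")[[1]]))
  if (anyNA(st)) stop("unparseable cell token: '", tok, "'")
  sort(unique(st))
}

generic_chardefs <- function(n, aspect = "closure") {
  data.frame(char_id = sprintf("c%02d", seq_len(n)),
             suture = sprintf("character_%02d", seq_len(n)),
             group = "cranial",
             aspect = aspect,
             view = "none",
             max_state = ifelse(aspect == "closure", 3L, 2L),
             stringsAsFactors = FALSE)
}

ANATOMICAL_GROUPS <- c("facial", "cranial", "palatal", "braincase")

validate_chardefs <- function(chars) {
  chars <- as.data.frame(chars, stringsAsFactors = FALSE)
  need <- c("char_id", "suture", "group", "aspect", "view", "max_state")
  miss <- setdiff(need, names(chars))
  if (length(miss))
    stop("character definitions lack columns: ", paste(miss, collapse = ", "))
  chars$char_id <- as.character(chars$char_id)
  chars$max_state <- as.integer(chars$max_state)
  if (anyDuplicated(chars$char_id)) stop("duplicate char_id values")
  bad <- !chars$aspect %in% c("closure", "interdigitation")
  if (any(bad)) stop("unknown aspect: ", paste(unique(chars$aspect[bad]), collapse = ", "))
  badg <- !chars$group %in% ANATOMICAL_GROUPS
  if (any(badg))
    stop("unknown anatomical group: ", paste(unique(chars$group[badg]), collapse = ", "))
  want <- ifelse(chars$aspect == "closure", 3L, 2L)
  if (any(chars$max_state != want))
    stop("max_state must be 3 for closure and 2 for interdigitation characters")
  chars
}

validate_character_matrix <- function(m) {
  for (j in seq_len(ncol(m$cells))) {
    mx <- m$chars$max_state[j]
    for (i in seq_len(nrow(m$cells))) {
      cell <- m$cells[[i, j]]
      if (is_missing_cell(cell)) next
      if (any(cell < 0L | cell > mx))
        stop("state out of range for taxon '", m$taxa[i], "', character '",
             m$chars$char_id[j], "': states {",
             paste(cell, collapse = ","), "} exceed max_state ", mx)
    }
  }
  invisible(m)
}

#' Append the hypothetical all-immature outgroup
#'
#' The ontogram method polarizes characters with a hypothetical embryo in
#' which every character is at its immature state: a taxon whose every cell
#' is `{0}`. All tree output is rooted on this taxon.
#'
#' @param matrix a [character_matrix()].
#' @param name taxon id for the hypothetical embryo.
#' @return a `character_matrix` with one appended all-zero taxon.
#' @export
add_hypothetical_outgroup <- function(matrix, name = "HYPOTHETICAL_EMBRYO") {
  stopifnot(inherits(matrix, "character_matrix"))
  if (name %in% matrix$taxa)
    stop("taxon '", name, "' already present in the matrix")
  row <- matrix(rep(list(0L), nrow(matrix$chars)), nrow = 1L)
  cells <- rbind(matrix$cells, row)
  character_matrix(c(matrix$taxa, name), cells, matrix$chars)
}

# canonical string key of one cell ("0/1", "?") used for reliability grids
cell_key <- function(cell) {
  if (is_missing_cell(cell)) "?" else paste(cell, collapse = "/")
}

# collapse whitespace/underscores and case for specimen-id matching
canonical_id <- function(x) toupper(gsub("[[:space:]_]+", "", x))
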