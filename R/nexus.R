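#' Read a NEXUS character matrix
#'
#' Parses the CHARACTERS (or DATA) block of a NEXUS document into a
#' [character_matrix()]. Both `(01)` and `{01}` cell groups are read as the
#' state set \{0, 1\} (the original bracket style is retained as a cell
#' annotation); `?` and `-` denote missing. The state symbol order is taken
#' from `FORMAT SYMBOLS` when present. Parsing is insensitive to whitespace
#' style and line wrapping inside `MATRIX`.
#'
#' @param file path to a NEXUS file, or a character vector of lines via
#'   `text`.
#' @param text optional character scalar/vector holding the document itself.
#' @param chars optional character-definition data frame (see
#'   [character_matrix()]); defaults to generic closure characters.
#' @return a `character_matrix`.
#' @export
read_nexus_matrix <- function(file, text = NULL, chars = NULL) {
  lines <- if (!is.null(text)) {
    unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  } else readLines(file, warn = FALSE)
  # strip NEXUS comments [...] (single-line scope is enough for matrices)
  lines <- gsub("\\[[^]]*\\]", "", lines)
  up <- toupper(lines)
  dim_line <- grep("\\bDIMENSIONS\\b", up)
  if (!length(dim_line)) stop("NEXUS parse error: no DIMENSIONS command found")
  dl <- paste(lines[dim_line], collapse = " ")
  ntax <- as.integer(sub(".*NTAX\\s*=\\s*(\\d+).*", "\\1", toupper(dl)))
  nchar_ <- as.integer(sub(".*NCHAR\\s*=\\s*(\\d+).*", "\\1", toupper(dl)))
  if (is.na(ntax) || is.na(nchar_))
    stop("NEXUS parse error at line ", dim_line[1],
         ": DIMENSIONS must give NTAX and NCHAR")
  sym <- NULL
  fmt_line <- grep("\\bFORMAT\\b", up)
  if (length(fmt_line)) {
    fl <- paste(lines[fmt_line], collapse = " ")
    mm <- regmatches(fl, regexpr('SYMBOLS\\s*=\\s*"[^"]*"', fl, ignore.case = TRUE))
    if (length(mm)) sym <- gsub('[^0-9]', "", mm)
  }
  mstart <- grep("^\\s*MATRIX\\b", up)
  if (!length(mstart)) stop("NEXUS parse error: no MATRIX command found")
  mstart <- mstart[1]
  body <- lines[(mstart + 1L):length(lines)]
  semi <- grep(";", body, fixed = TRUE)
  stop_at <- if (length(semi)) semi[1] else length(body)
  body[stop_at] <- sub(";.*$", "", body[stop_at])
  body <- body[seq_len(stop_at)]
  body <- body[nzchar(trimws(body))]

  taxa <- character(0)
  rows <- list()
  notat <- list()
  for (ln in body) {
    parsed <- parse_matrix_row(ln, mstart)
    id <- parsed$taxon
    if (id %in% taxa) {            # interleaved continuation
      k <- match(id, taxa)
      rows[[k]] <- c(rows[[k]], parsed$cells)
      notat[[k]] <- c(notat[[k]], parsed$notation)
    } else {
      taxa <- c(taxa, id)
      rows[[length(taxa)]] <- parsed$cells
      notat[[length(taxa)]] <- parsed$notation
    }
  }
  if (length(taxa) != ntax)
    stop("NEXUS parse error: DIMENSIONS declares NTAX=", ntax,
         " but MATRIX has ", length(taxa), " taxa")
  nc <- lengths(rows)
  if (any(nc != nchar_))
    stop("NEXUS parse error: taxon '", taxa[which(nc != nchar_)[1]],
         "' has ", nc[which(nc != nchar_)[1]], " cells, expected ", nchar_)
  cells <- matrix(do.call(c, rows), nrow = ntax, byrow = TRUE)
  notation <- matrix(unlist(notat), nrow = ntax, byrow = TRUE)
  # translate through SYMBOLS order when it is not the identity digits
  if (!is.null(sym) && nzchar(sym) &&
      sym != paste(seq_len(nchar(sym)) - 1L, collapse = "")) {
    map <- stats::setNames(seq_len(nchar(sym)) - 1L, strsplit(sym, "")[[1]])
    cells <- matrix(lapply(cells, function(cl) {
      if (is_missing_cell(cl)) cl else unname(sort(map[as.character(cl)]))
    }), nrow = ntax)
  }
  character_matrix(taxa, cells, chars = chars, notation = notation)
}

parse_matrix_row <- function(line, line_no) {
  s <- trimws(line)
  if (startsWith(s, "'")) {
    end <- regexpr("'", substring(s, 2), fixed = TRUE)
    if (end < 0) stop("NEXUS parse error near line ", line_no, ": unterminated quote")
    taxon <- substring(s, 2, end)
    rest <- substring(s, end + 2)
  } else {
    m <- regexpr("^\\S+", s)
    taxon <- regmatches(s, m)
    rest <- substring(s, attr(m, "match.length") + 1L)
  }
  taxon <- gsub("_", " ", taxon)
  toks <- regmatches(rest, gregexpr("\\([^)]*\\)|\\{[^}]*\\}|[0-9?\\-]", rest))[[1]]
  cells <- lapply(toks, parse_cell_token)
  notation <- vapply(toks, function(t) {
    if (startsWith(t, "(")) "paren" else if (startsWith(t, "{")) "brace" else "single"
  }, character(1), USE.NAMES = FALSE)
  list(taxon = taxon, cells = cells, notation = notation)
}

#' Write a character matrix as a NEXUS document
#'
#' Emits a `DATA` block with `DIMENSIONS`, `FORMAT` (`SYMBOLS` covering
#' `0..max(max_state)`, `MISSING=?`), and `MATRIX`. Polymorphic cells are
#' written as parenthesized groups, missing cells as `?`.
#'
#' @param matrix a [character_matrix()].
#' @param file optional path; if `NULL` the document is returned as a
#'   character vector of lines.
#' @return the document lines, invisibly when written to `file`.
#' @export
write_nexus_matrix <- function(matrix, file = NULL) {
  stopifnot(inherits(matrix, "character_matrix"))
  maxsym <- max(matrix$chars$max_state)
  labels <- gsub("[[:space:]]+", "_", matrix$taxa)
  width <- max(nchar(labels)) + 2L
  rows <- vapply(seq_along(matrix$taxa), function(i) {
    toks <- vapply(seq_len(nrow(matrix$chars)), function(j) {
      cell <- matrix$cells[[i, j]]
      if (is_missing_cell(cell)) "?"
      else if (length(cell) == 1L) as.character(cell)
      else paste0("(", paste(cell, collapse = ""), ")")
    }, character(1))
    paste0(formatC(labels[i], width = -width), paste(toks, collapse = ""))
  }, character(1))
  doc <- c("#NEXUS",
           "BEGIN DATA;",
           sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
                   length(matrix$taxa), nrow(matrix$chars)),
           sprintf('  FORMAT DATATYPE=STANDARD SYMBOLS="%s" MISSING=? GAP=-;',
                   paste(0:maxsym, collapse = "")),
           "  MATRIX",
           paste0("    ", rows),
           "  ;",
           "END;")
  if (is.null(file)) return(doc)
  writeLines(doc, file)
  invisible(doc)
}

#' Read a specimen metadata table
#'
#' Reads a CSV/TSV of specimen records (columns `specimen_id`,
#' `skull_length_mm`, `total_length_cm`, `age`, `sex`, `status`, `category`;
#' missing columns are tolerated). Length values suffixed with an `(e)`
#' marker are parsed as numbers and flagged estimated. Unknown or empty sex,
#' status and category map to `"unknown"`.
#'
#' @param file path to the table; the delimiter (comma or tab) is sniffed
#'   from the header line.
#' @param text optional literal table text.
#' @return a data frame of specimen records.
#' @export
read_specimen_table <- function(file, text = NULL) {
  lines <- if (!is.null(text)) unlist(strsplit(paste(text, collapse = "\n"), "\n"))
           else readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  df <- utils::read.table(text = paste(lines, collapse = "\n"), sep = sep,
                          header = TRUE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA", "?"), strip.white = TRUE,
                          comment.char = "")
  if (!"specimen_id" %in% names(df))
    stop("specimen table needs a 'specimen_id' column")
  out <- data.frame(specimen_id = as.character(df$specimen_id),
                    stringsAsFactors = FALSE)
  bad_rows <- integer(0)
  for (col in c("skull_length_mm", "total_length_cm")) {
    if (col %in% names(df)) {
      raw <- as.character(df[[col]])
      est <- grepl("\\(e[^)]*\\)", raw)
      num <- suppressWarnings(as.numeric(sub("\\s*\\(e[^)]*\\).*$", "", raw)))
      bad <- !is.na(raw) & nzchar(trimws(raw)) & is.na(num)
      bad_rows <- union(bad_rows, which(bad))
      if (any(!is.na(num) & num <= 0))
        stop("non-positive ", col, " in rows ",
             paste(which(!is.na(num) & num <= 0), collapse = ", "))
      out[[col]] <- num
      out[[paste0(sub("_mm$|_cm$", "", col), "_estimated")]] <- est
    } else {
      out[[col]] <- NA_real_
      out[[paste0(sub("_mm$|_cm$", "", col), "_estimated")]] <- FALSE
    }
  }
  if (length(bad_rows))
    stop("non-numeric length values in rows: ",
         paste(sort(bad_rows), collapse = ", "))
  out$age <- if ("age" %in% names(df)) as.character(df$age) else NA_character_
  norm_enum <- function(x, levels) {
    x <- tolower(trimws(ifelse(is.na(x), "unknown", as.character(x))))
    x[!x %in% levels] <- "unknown"
    x
  }
  out$sex <- if ("sex" %in% names(df)) {
    s <- toupper(trimws(ifelse(is.na(df$sex), "", as.character(df$sex))))
    ifelse(s %in% c("M", "F"), s, "unknown")
  } else "unknown"
  out$status <- if ("status" %in% names(df))
    norm_enum(df$status, c("wild", "domestic")) else "unknown"
  out$category <- if ("category" %in% names(df))
    norm_enum(df$category,
              c("juvenile", "subadult", "sexually_mature", "skeletally_mature"))
    else "unknown"
  out
}

#' Read a character-definition sidecar table
#'
#' TSV/CSV with headers `char_id`, `suture`, `group` (or `anatomical_group`),
#' `aspect`, `view`, `max_state`.
#'
#' @param file path to the table.
#' @return a validated character-definition data frame.
#' @export
read_chardef_table <- function(file) {
  l1 <- readLines(file, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", l1)) "\t" else ","
  df <- utils::read.table(file, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  if ("anatomical_group" %in% names(df) && !"group" %in% names(df))
    names(df)[names(df) == "anatomical_group"] <- "group"
  if ("suture_name" %in% names(df) && !"suture" %in% names(df))
    names(df)[names(df) == "suture_name"] <- "suture"
  validate_chardefs(df)
}

#' Read sectioned-articulation measurements
#'
#' TSV/CSV with columns `specimen_id`, `articulation`, `tissue`
#' (`suture`/`synchondrosis`), `area_um2`, `length_um` and optional
#' `skull_length_cm`.
#'
#' @param file path to the table.
#' @return a data frame of suture sections.
#' @export
read_suture_sections <- function(file) {
  l1 <- readLines(file, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", l1)) "\t" else ","
  df <- utils::read.table(file, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          na.strings = c("", "NA", "N/A"))
  need <- c("specimen_id", "articulation", "area_um2", "length_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("section table lacks columns: ", paste(miss, collapse = ", "))
  if (!"tissue" %in% names(df)) df$tissue <- "suture"
  if (!"skull_length_cm" %in% names(df)) df$skull_length_cm <- NA_real_
  df
}
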