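test_that("cell tokens parse to state sets and missing markers", {
  expect_identical(ontogram:::parse_cell_token("(012)"), c(0L, 1L, 2L))
  expect_identical(ontogram:::parse_cell_token("{01}"), c(0L, 1L))
  expect_identical(ontogram:::parse_cell_token("2"), 2L)
  expect_true(ontogram:::is_missing_cell(ontogram:::parse_cell_token("?")))
  expect_true(ontogram:::is_missing_cell(ontogram:::parse_cell_token("-")))
  expect_error(ontogram:::parse_cell_token("(0a)"), "unparseable")
})

test_that("NEXUS write/parse round-trips generated matrices cell-for-cell", {
  for (dims in list(c(5, 6), c(10, 12))) {
    m <- random_matrix(dims[1], dims[2], seed = dims[1] * 100 + dims[2])
    doc <- write_nexus_matrix(m)
    m2 <- read_nexus_matrix(text = doc, chars = m$chars)
    expect_identical(m2$taxa, m$taxa)
    expect_identical(m2$chars$char_id, m$chars$char_id)
    expect_identical(unname(m2$cells), unname(m$cells))
  }
})

test_that("single-cell matrices render the expected MATRIX rows", {
  m <- character_matrix("taxon1", matrix(list(0L), 1, 1))
  doc <- write_nexus_matrix(m)
  row <- grep("taxon1", doc, value = TRUE)
  expect_match(row, "taxon1\\s+0$")
  m2 <- character_matrix("t", matrix(list(c(0L, 1L)), 1, 1))
  expect_match(grep("^    t", write_nexus_matrix(m2), value = TRUE), "\\(01\\)$")
})

test_that("parsing is insensitive to whitespace style and line wrapping", {
  doc <- c("#NEXUS", "BEGIN CHARACTERS;",
           "DIMENSIONS  NTAX = 3   NCHAR = 4 ;",
           'FORMAT SYMBOLS="0123" MISSING=?;',
           "MATRIX",
           "  A   01", "  A   (23)?",   # wrapped/interleaved continuation
           "\tB\t0 1 2 3",
           "  C   3210", ";", "END;")
  m <- read_nexus_matrix(text = doc)
  expect_identical(dim(m), c(3L, 4L))
  expect_identical(m$cells[[1, 3]], c(2L, 3L))
  expect_true(ontogram:::is_missing_cell(m$cells[[1, 4]]))
  expect_identical(m$cells[[2, 2]], 1L)
})

test_that("validation rejects out-of-range states and malformed blocks", {
  chars <- ontogram:::generic_chardefs(1, aspect = "interdigitation")
  expect_error(character_matrix("A", matrix(list(3L), 1, 1), chars),
               "max_state")
  expect_error(read_nexus_matrix(text = c("#NEXUS", "MATRIX", "A 01;")),
               "DIMENSIONS")
  expect_error(read_nexus_matrix(
    text = c("#NEXUS", "DIMENSIONS NTAX=2 NCHAR=2;", "MATRIX",
             "A 01", "B 0", ";")), "expected 2")
})

test_that("the hypothetical outgroup appends an all-zero taxon exactly once", {
  m <- random_matrix(6, 8, seed = 42)
  m2 <- add_hypothetical_outgroup(m, "EMBRYO")
  expect_identical(length(m2$taxa), 7L)
  expect_true(all(vapply(m2$cells[7, ], identical, logical(1), 0L)))
  expect_identical(specimen_average(m2, "EMBRYO"), 0)
  expect_identical(obliteration_fraction(m2, "EMBRYO"), 0)
  expect_error(add_hypothetical_outgroup(m2, "EMBRYO"), "already present")
})

test_that("specimen tables parse printed-table conventions", {
  txt <- c("specimen_id,skull_length_mm,age,sex",
           "MOR OST 1803,152.23,20 years,M",
           "ROM R0001,155.00 (e),,",
           "ROM R0002,61.00 (e),A few weeks (?),")
  rec <- read_specimen_table(text = txt)
  expect_equal(rec$skull_length_mm, c(152.23, 155, 61))
  expect_identical(rec$skull_length_estimated, c(FALSE, TRUE, TRUE))
  expect_identical(rec$sex, c("M", "unknown", "unknown"))
  bad <- c("specimen_id,skull_length_mm", "A,abc", "B,12", "C,x2")
  expect_error(read_specimen_table(text = bad), "rows: 1, 3")
})

test_that("the shipped printed-metadata fixtures load cleanly", {
  emu <- read_specimen_table(system.file("extdata", "emu_specimens.tsv",
                                         package = "ontogram"))
  expect_identical(nrow(emu), 24L)
  expect_identical(sum(emu$category == "juvenile"), 7L)
  alg <- read_specimen_table(system.file("extdata", "alligator_specimens.tsv",
                                         package = "ontogram"))
  expect_identical(nrow(alg), 50L)
  expect_true(all(alg$total_length_cm > 0, na.rm = TRUE))
})
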