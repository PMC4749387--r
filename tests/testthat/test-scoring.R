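test_that("cell scores are state-set means", {
  expect_equal(cell_score(c(0L, 1L)), 0.5)
  expect_equal(cell_score(2L), 2)
  expect_equal(cell_score(c(0L, 1L, 2L)), 1)
  expect_true(is.na(cell_score(NA_integer_)))
})

test_that("specimen averages respect aspect, group and missing cells", {
  chars <- rbind(
    data.frame(char_id = "c1", suture = "sA", group = "cranial",
               aspect = "closure", view = "none", max_state = 3L),
    data.frame(char_id = "c2", suture = "sB", group = "facial",
               aspect = "closure", view = "none", max_state = 3L),
    data.frame(char_id = "i1", suture = "sA", group = "cranial",
               aspect = "interdigitation", view = "none", max_state = 2L))
  cells <- matrix(list(3L, c(1L, 2L), 2L,
                       0L, NA_integer_, 1L), 2, 3, byrow = TRUE)
  m <- character_matrix(c("X", "Y"), cells, chars)
  expect_equal(specimen_average(m, "X", "closure"), (3 + 1.5) / 2)
  expect_equal(specimen_average(m, "X", "interdigitation"), 2)
  expect_equal(specimen_average(m, "X", "closure", group = "cranial"), 3)
  expect_equal(specimen_average(m, "Y", "closure"), 0)   # missing excluded
  expect_error(specimen_average(m, "Z"), "not in matrix")
  expect_error(specimen_average(m, "X", "closure", group = "palatal"),
               "no characters")
})

test_that("raising any cell's states never lowers the specimen average", {
  for (seed in 1:10) {
    m <- random_matrix(4, 8, seed = 600 + seed)
    base_avg <- specimen_average(m, "t1")
    # raise one random scorable cell of t1 elementwise
    set.seed(seed)
    scorable <- which(!vapply(m$cells[1, ], ontogram:::is_missing_cell,
                              logical(1)))
    j <- sample(scorable, 1)
    m$cells[[1, j]] <- pmin(m$cells[[1, j]] + 1L, 3L)
    expect_gte(specimen_average(m, "t1"), base_avg)
  }
})

test_that("closure and interdigitation averages stay within their scales", {
  for (seed in 1:5) {
    sim <- sim_ontogeny_study(n_specimens = 10, poly_prob = 0.3, seed = seed)
    av <- specimen_averages(sim$matrix)
    expect_true(all(av$closure_avg >= 0 & av$closure_avg <= 3))
    expect_true(all(av$interdigitation_avg >= 0 & av$interdigitation_avg <= 2))
  }
})

test_that("category averages pool cells, with the specimen-mean alternative", {
  sim <- sim_ontogeny_study(n_specimens = 12, seed = 9)
  rec <- sim$records
  pooled <- category_average(sim$matrix, rec, "closure", "juvenile")
  sc <- ontogram:::score_table(sim$matrix)
  juv <- rec$specimen_id[rec$category == "juvenile"]
  expect_equal(pooled, mean(sc[juv, sim$matrix$chars$aspect == "closure"],
                            na.rm = TRUE))
  # a single-specimen category collapses to that specimen's average
  one <- rec[1, ]; one$category <- "juvenile"
  expect_equal(category_average(sim$matrix, one, "closure", "juvenile"),
               specimen_average(sim$matrix, one$specimen_id))
  expect_equal(category_average(sim$matrix, one, "closure", "juvenile",
                                method = "specimen_mean"),
               specimen_average(sim$matrix, one$specimen_id))
  expect_error(category_average(sim$matrix, rec, "closure", "hatchling"),
               "no specimens")
})

test_that("obliteration fractions require the pure terminal state", {
  chars <- data.frame(char_id = c("c1", "c2", "c3"),
                      suture = c("sA", "sA", "sB"),
                      group = "cranial", aspect = "closure",
                      view = c("dorsal", "palatal", "none"), max_state = 3L)
  cells <- matrix(list(3L, 3L, c(2L, 3L)), 1, 3)
  m <- character_matrix("X", cells, chars)
  # suture sA obliterated in both views; sB polymorphic {2,3} does not count
  expect_equal(obliteration_fraction(m, "X"), 0.5)
  m$cells[[1, 2]] <- 2L
  expect_equal(obliteration_fraction(m, "X"), 0)
  # embryonic obliterations in a widening-mode hatchling: 2 of 37 sutures
  sim <- sim_ontogeny_study(n_specimens = 6,
                            sutures_per_group = c(facial = 12, cranial = 10,
                                                  palatal = 7, braincase = 8),
                            mode = "widening",
                            n_embryonic_obliterations = 2,
                            age_range = c(0, 30), seed = 4)
  young <- sim$records$specimen_id[1]
  # only the designated embryonic midline pair ever reaches {3}
  expect_equal(obliteration_fraction(sim$matrix, young), 2 / 37)
  old <- sim$records$specimen_id[6]
  expect_equal(obliteration_fraction(sim$matrix, old), 2 / 37)
})

test_that("trend fits recover exact collinearity and model variants", {
  rec <- data.frame(specimen_id = paste0("s", 1:6),
                    skull_length_mm = c(50, 70, 90, 110, 130, 150))
  av <- data.frame(specimen_id = paste0("s", 1:6),
                   closure_avg = 0.5 + 0.01 * c(50, 70, 90, 110, 130, 150))
  tr <- suture_trend(rec, av)
  expect_equal(tr$pearson_r, 1)
  expect_equal(tr$slope, 0.01)
  expect_equal(unname(coef(tr)["intercept"]), 0.5)
  expect_equal(unname(predict(tr, 200)), 2.5)
  expect_equal(max(abs(residuals(tr))), 0, tolerance = 1e-12)
  # log model linearizes an exact logarithmic response
  av2 <- av; av2$closure_avg <- log(rec$skull_length_mm)
  tr2 <- suture_trend(rec, av2, model = "log")
  expect_equal(tr2$pearson_r, 1)
  expect_error(suture_trend(rec[1:2, ], av[1:2, ]), "at least 3")
  av3 <- av; av3$closure_avg <- 1
  expect_error(suture_trend(rec, av3), "zero variance")
})

test_that("staging schemes assign categories with inclusive lower bounds", {
  sch <- alligator_staging()
  expect_identical(assign_category(150, sch), "subadult")
  expect_identical(assign_category(280, sch), "skeletally_mature")
  expect_identical(assign_category(122, sch), "subadult")   # boundary
  expect_identical(assign_category(121.9, sch), "juvenile")
  expect_identical(assign_category(list(total_length_cm = 250), sch),
                   "sexually_mature")
  expect_warning(out <- assign_category(list(total_length_cm = NA), sch),
                 "missing")
  expect_identical(out, "unknown")
  expect_error(staging_scheme(c("a", "b"), c(5, 10)), "lower_bounds")
  emu <- emu_staging()
  expect_identical(assign_category(60, emu), "juvenile")
  expect_identical(assign_category(160, emu), "sexually_mature")
})
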