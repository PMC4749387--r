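sections_path <- function() {
  system.file("extdata", "alligator_sections.tsv", package = "ontogram")
}

test_that("width is the area/length ratio with half-up rounding", {
  expect_equal(average_width(6412890, 30749), 208.5561, tolerance = 1e-6)
  expect_equal(ontogram:::round_half_up(average_width(6412890, 30749)), 209)
  expect_equal(ontogram:::round_half_up(average_width(25806, 290)), 89)
  # rectangle: area L*w over trace L gives exactly w
  expect_equal(average_width(500 * 80, 500), 80)
  expect_error(average_width(-1, 10), "positive")
  expect_error(average_width(10, 0), "positive")
})

test_that("printed section table reproduces its width column within 1 um", {
  sec <- read_suture_sections(sections_path())
  h <- histo_widths(sec)
  ok <- !is.na(h$printed_width_um)
  expect_true(all(abs(h$width_um_rounded[ok] - h$printed_width_um[ok]) <= 1))
})

test_that("normalized widths are dimensionless and unit-correct", {
  expect_equal(normalized_width(83871, 681, 2.5), 4.92e-3, tolerance = 2e-3)
  expect_equal(normalized_width(225806, 1737, 15.5), 0.84e-3, tolerance = 5e-3)
  # width equal to skull length normalizes to 1
  expect_equal(normalized_width(1e4 * 100, 100, 1), 1)
  expect_error(normalized_width(10, 10, NA), "skull length")
})

test_that("polygon measures: shoelace area, trace length, scale covariance", {
  sq <- list(loop = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
             trace = rbind(c(0, 0.5), c(1, 0.5)))
  pm <- polygon_measures(sq)
  expect_equal(unname(pm["area"]), 1)
  expect_equal(unname(pm["trace_length"]), 1)
  p <- sim_suture_section(width = 100, amplitude = 120, wavelength = 500,
                          trace_length = 1500)
  pm1 <- polygon_measures(p)
  p2 <- list(loop = p$loop * 3, trace = p$trace * 3)
  pm2 <- polygon_measures(p2)
  expect_equal(unname(pm2["area"]), unname(9 * pm1["area"]), tolerance = 1e-9)
  expect_equal(unname(pm2["trace_length"]), unname(3 * pm1["trace_length"]),
               tolerance = 1e-9)
  bow <- list(loop = rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1)),
              trace = rbind(c(0, 0), c(1, 1)))
  expect_error(polygon_measures(bow), "self-intersecting")
})

test_that("the width estimator recovers generative widths on sinusoid bands", {
  p <- sim_suture_section(width = 150, amplitude = 200, wavelength = 400,
                          trace_length = 2000)
  pm <- polygon_measures(p)
  expect_equal(unname(pm["area"] / pm["trace_length"]), 150, tolerance = 0.05)
  # amplitude 0 collapses to a rectangle: exact recovery
  p0 <- sim_suture_section(width = 80, amplitude = 0, trace_length = 500)
  pm0 <- polygon_measures(p0)
  expect_equal(unname(pm0["area"] / pm0["trace_length"]), 80,
               tolerance = 1e-9)
  # doubling all geometric parameters doubles the recovered width
  pd <- sim_suture_section(width = 300, amplitude = 400, wavelength = 800,
                           trace_length = 4000)
  pmd <- polygon_measures(pd)
  expect_equal(unname(pmd["area"] / pmd["trace_length"]),
               2 * unname(pm["area"] / pm["trace_length"]), tolerance = 1e-6)
  expect_error(sim_suture_section(width = 420, amplitude = 300,
                                  wavelength = 400, trace_length = 2000),
               "self-intersects")
})

test_that("maturity-ordered width series classify their monotonicity", {
  sec <- read_suture_sections(sections_path())
  sec$maturity_rank <- as.integer(sec$maturity_rank)
  tr <- width_trend(sec, value = "printed_width_um")
  fp <- tr[tr$articulation == "frontoparietal", ]
  expect_identical(fp$trend, "non-decreasing")   # printed 123, 123, 209
  expect_true(all(tr$trend %in% c("increasing", "non-decreasing")))
  # at full precision the same series rises strictly (123.2, 123.5, 208.6)
  expect_identical(width_trend(sec)$trend,
                   rep("increasing", 3))
  ntr <- width_trend(sec, value = "normalized_width")
  expect_identical(ntr$trend[ntr$articulation == "frontoparietal"],
                   "decreasing")                  # 4.92, 0.80, 0.73 (x1e-3)
  pair <- data.frame(articulation = "x", area_um2 = c(1000, 900),
                     length_um = c(10, 10), skull_length_cm = NA,
                     maturity_rank = 1:2)
  expect_identical(width_trend(pair)$trend, "decreasing")
  bad <- pair; bad$maturity_rank <- c(2, 1)
  expect_error(width_trend(bad), "not ordered")
})
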