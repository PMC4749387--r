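test_that("fitch length handles the textbook four-taxon cases", {
  m <- character_matrix(c("A", "B", "C", "D"),
                        matrix(c("0", "0", "1", "1"), 4, 1))
  expect_identical(fitch_length(tree_ab_cd(), m), 1L)       # single origin
  m2 <- character_matrix(c("A", "B", "C", "D"),
                         matrix(rep("2", 4), 4, 1))
  expect_identical(fitch_length(tree_ab_cd(), m2), 0L)      # constant
  split_tree <- rbind(c(5, 1), c(5, 3), c(5, 6), c(6, 2), c(6, 4))
  expect_identical(fitch_length(split_tree, m), 2L)         # homoplasy forced
})

test_that("the C++ kernel agrees with an independent recursive oracle", {
  for (seed in 1:12) {
    m <- random_matrix(6, 8, seed = seed)
    for (E in all_unrooted_trees(6)[c(1, 37, 105)]) {
      expect_identical(fitch_length(E, m), ref_fitch_length(E, m),
                       info = paste("seed", seed))
    }
  }
})

test_that("fitch agrees with phangorn on singleton and polymorphic cells", {
  skip_if_not_installed("phangorn")
  for (seed in 1:6) {
    m <- random_matrix(7, 10, seed = 100 + seed)
    E <- all_unrooted_trees(7)[[seed * 7]]
    phy <- ape::unroot(ontogram:::as_phylo_tree(E, 7, m$taxa, root_tip = 1L))
    # phangorn: contrast matrix with one row per observed set
    keys <- vapply(m$cells, ontogram:::cell_key, character(1))
    sets <- sort(unique(keys))
    contrast <- t(vapply(sets, function(k) {
      if (k == "?") rep(1, 4)
      else as.numeric(0:3 %in% as.integer(strsplit(k, "/")[[1]]))
    }, numeric(4)))
    colnames(contrast) <- as.character(0:3)
    dat <- matrix(keys, nrow = length(m$taxa), dimnames = list(m$taxa, NULL))
    pd <- phangorn::phyDat(dat, type = "USER", contrast = contrast)
    expect_identical(as.integer(phangorn::fitch(phy, pd)),
                     fitch_length(E, m), info = paste("seed", seed))
  }
})

test_that("polymorphism semantics add the per-cell surcharge", {
  m <- character_matrix(c("A", "B", "C", "D"),
                        matrix(list(c(0L, 1L), 0L, c(1L, 2L, 3L), 1L), 4, 1))
  lu <- fitch_length(tree_ab_cd(), m, mode = "uncertainty")
  lp <- fitch_length(tree_ab_cd(), m, mode = "polymorphism")
  expect_identical(lp, lu + 3L)  # (2-1) + (3-1) extra states
  for (seed in 1:8) {
    m <- random_matrix(6, 6, seed = 200 + seed)
    E <- all_unrooted_trees(6)[[seed]]
    expect_lte(fitch_length(E, m, "uncertainty"),
               fitch_length(E, m, "polymorphism"))
  }
})

test_that("scoring refuses polytomies and mismatched tips", {
  m <- random_matrix(4, 3, seed = 1)
  star <- rbind(c(5, 1), c(5, 2), c(5, 3), c(5, 4))
  expect_error(fitch_length(star, m), "binary")
  expect_error(fitch_length(tree_ab_cd(), random_matrix(5, 3, seed = 2)),
               "tips")
})

test_that("character step bounds match direct counting", {
  expect_identical(character_step_bounds(list(1L, 1L, 1L)), c(m = 0L, g = 0L))
  expect_identical(character_step_bounds(list(0L, 0L, 0L, 1L, 1L)),
                   c(m = 1L, g = 2L))
  expect_identical(character_step_bounds(list(0L, 0L, 1L, 1L, 2L, 2L))[["m"]],
                   2L)
  # missing cells drop out of g's taxon count
  expect_identical(character_step_bounds(list(0L, NA_integer_, 1L, 1L)),
                   c(m = 1L, g = 1L))
  expect_warning(b <- character_step_bounds(list(NA_integer_, NA_integer_)),
                 "all-missing")
  expect_identical(b, c(m = 0L, g = 0L))
  # a state seen only inside a polymorphic cell forces no extra step
  expect_identical(character_step_bounds(list(0L, 0L, c(0L, 1L)))[["m"]], 0L)
})

test_that("ensemble indices satisfy their defining identities", {
  m <- random_matrix(6, 10, seed = 7, poly_prob = 0, miss_prob = 0)
  best <- exhaustive_min_length(m)
  sc <- score_indices(best, m)
  expect_equal(sc$ci * sc$length, sc$min_steps)
  expect_equal(sc$hi, 1 - sc$ci)
  expect_true(sc$min_steps <= sc$length && sc$length <= sc$max_steps)
  if (sc$length == sc$min_steps) expect_equal(sc$ri, 1)
  # perfect fit on a clean hierarchical matrix
  m2 <- character_matrix(paste0("t", 1:4),
                         matrix(c("0", "0", "1", "1",
                                  "0", "1", "1", "1"), 4, 2))
  sc2 <- score_indices(2, m2)
  expect_equal(sc2$ci, 1)
  expect_equal(sc2$hi, 0)
  expect_equal(sc2$ri, 1)
  expect_error(score_indices(1, m2), "below the matrix minimum")
})

test_that("hand-crafted homoplasy example matches the enumerated optimum", {
  # two characters supporting conflicting pairings: one must be homoplastic
  m <- character_matrix(paste0("t", 1:4),
                        matrix(c("0", "0", "1", "1",
                                 "0", "1", "0", "1"), 4, 2))
  best <- exhaustive_min_length(m)
  expect_identical(best, 3)
  sc <- score_indices(best, m)
  expect_equal(sc$ci, 2 / 3)
  expect_equal(sc$hi, 1 / 3)
})

test_that("indices excluding uninformative characters drop constant steps", {
  # char 1 informative (0011), chars 2-3 uninformative (autapomorphy/constant)
  m <- character_matrix(paste0("t", 1:4),
                        matrix(c("0", "0", "1", "1",
                                 "0", "0", "0", "1",
                                 "2", "2", "2", "2"), 4, 3))
  sc <- score_indices(2, m)   # best tree: 1 + 1 + 0
  expect_identical(sc$n_uninformative, 2L)
  expect_equal(sc$ci, 2 / 2)
  expect_equal(sc$ci_excl_uninformative, 1 / 1)
  sc2 <- score_indices(3, m)  # homoplastic tree: informative char costs 2
  expect_equal(sc2$ci, 2 / 3)
  expect_equal(sc2$ci_excl_uninformative, 1 / 2)
})
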