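#' @useDynLib ontogram, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# bitmask encoding of cells: bit s set <=> state s in the set; missing cells
# get the full mask of their character
state_masks <- function(matrix) {
  nt <- length(matrix$taxa); nc <- nrow(matrix$chars)
  out <- base::matrix(0L, nt, nc)
  full <- bitwShiftL(1L, matrix$chars$max_state + 1L) - 1L
  for (j in seq_len(nc)) {
    for (i in seq_len(nt)) {
      cell <- matrix$cells[[i, j]]
      out[i, j] <- if (is_missing_cell(cell)) full[j]
                   else sum(bitwShiftL(1L, cell))
    }
  }
  out
}

# tree-independent extra steps charged by 'polymorphism' semantics:
# each polymorphic leaf cell contributes (|states| - 1)
polymorphism_surcharge <- function(matrix) {
  sum(vapply(matrix$cells, function(cl)
    if (is_missing_cell(cl)) 0L else length(cl) - 1L, integer(1)))
}

#' Parsimony length of a tree under unordered multistate characters
#'
#' Total Fitch steps of `tree` on `matrix`, all characters equally weighted
#' and unordered. With `mode = "uncertainty"` a polymorphic cell enters the
#' downpass as its state set (the conservative lower bound); with
#' `mode = "polymorphism"` each polymorphic leaf cell is additionally
#' charged `|states| - 1` steps, so the observed within-specimen variation
#' itself counts as change. Missing cells contribute the full state set.
#'
#' @param tree an ape `phylo`, or an internal edge matrix.
#' @param matrix a [character_matrix()].
#' @param mode `"uncertainty"` (default) or `"polymorphism"`.
#' @param per_character return the per-character step vector instead of the
#'   total (uncertainty component only).
#' @return integer steps.
#' @export
fitch_length <- function(tree, matrix,
                         mode = c("uncertainty", "polymorphism"),
                         per_character = FALSE) {
  mode <- match.arg(mode)
  E <- if (inherits(tree, "phylo")) phylo_to_tree(tree, matrix$taxa) else tree
  nTip <- length(matrix$taxa)
  check_tree_tips(E, nTip)
  if (!is_binary_unrooted(E, nTip))
    stop("fitch_length requires a fully binary tree (polytomies refused)")
  steps <- fitch_steps_cpp(E, nTip, state_masks(matrix))
  if (per_character) return(steps)
  total <- sum(steps)
  if (mode == "polymorphism") total <- total + polymorphism_surcharge(matrix)
  total
}

#' Per-character minimum and maximum step bounds
#'
#' For one character column: `m`, the minimum steps on any tree (number of
#' distinct observed states minus one, counting every state of a polymorphic
#' cell as observed), and `g`, the maximum steps (star-tree length: scored
#' taxa minus the largest single-state count after resolving each
#' polymorphic cell to the globally most frequent of its states). These are
#' the ingredients of the ensemble consistency and retention indices.
#'
#' @param column list of cells (integer state vectors, `NA` for missing).
#' @return named integer vector `c(m = , g = )`.
#' @export
character_step_bounds <- function(column) {
  scored <- column[!vapply(column, is_missing_cell, logical(1))]
  if (!length(scored)) {
    warning("all-missing character column; bounds are (0, 0)")
    return(c(m = 0L, g = 0L))
  }
  observed <- sort(unique(unlist(scored)))
  # m: fewest states that intersect every scored cell, minus one -- the
  # Fitch minimum when polymorphic cells enter as state sets (a state seen
  # only inside polymorphic cells need not force a step)
  m <- length(observed) - 1L
  if (any(lengths(scored) > 1L)) {
    for (k in seq_along(observed)) {
      hit <- FALSE
      for (sub in utils::combn(observed, k, simplify = FALSE)) {
        if (all(vapply(scored, function(cl) any(cl %in% sub), logical(1)))) {
          hit <- TRUE; break
        }
      }
      if (hit) { m <- k - 1L; break }
    }
  }
  counts <- table(factor(unlist(scored), levels = observed))
  resolved <- vapply(scored, function(cl) {
    cl[which.max(counts[as.character(cl)])]
  }, integer(1))
  g <- length(scored) - max(tabulate(resolved + 1L))
  c(m = m, g = as.integer(g))
}

step_bounds_matrix <- function(matrix) {
  nc <- nrow(matrix$chars)
  t(vapply(seq_len(nc), function(j)
    suppressWarnings(character_step_bounds(matrix$cells[, j])),
    c(m = 0L, g = 0L)))
}

#' Ensemble tree-score indices
#'
#' Consistency, homoplasy and retention indices of a tree length on a
#' matrix: `CI = m/L`, `HI = 1 - CI`, `RI = (g - L)/(g - m)`, with `m` and
#' `g` the summed per-character step bounds. The `excluding uninformative`
#' variants drop characters whose minimum equals their maximum steps (their
#' constant contribution is removed from both numerator and denominator).
#'
#' @param length observed tree length (steps) under uncertainty semantics.
#' @param matrix the scored [character_matrix()].
#' @return object of class `tree_score`: length, min/max steps, ci, hi, ri,
#'   ci/hi excluding uninformative characters.
#' @export
score_indices <- function(length, matrix) {
  b <- step_bounds_matrix(matrix)
  m <- sum(b[, "m"]); g <- sum(b[, "g"])
  if (length < m)
    stop("length ", length, " is below the matrix minimum ", m,
         "; inconsistent inputs")
  ci <- if (length > 0) m / length else 1
  ri <- if (g > m) (g - length) / (g - m) else if (length == m) 1 else NaN
  uninf <- b[, "m"] == b[, "g"]
  m_eu <- sum(b[!uninf, "m"]); len_eu <- length - sum(b[uninf, "m"])
  ci_eu <- if (len_eu > 0) m_eu / len_eu else 1
  structure(list(length = as.integer(length), min_steps = as.integer(m),
                 max_steps = as.integer(g), ci = ci, hi = 1 - ci, ri = ri,
                 ci_excl_uninformative = ci_eu,
                 hi_excl_uninformative = 1 - ci_eu,
                 n_uninformative = sum(uninf)),
            class = "tree_score")
}

#' @export
print.tree_score <- function(x, ...) {
  cat(sprintf("tree score: length %d (min %d, max %d)\n",
              x$length, x$min_steps, x$max_steps))
  cat(sprintf("  CI %.2f (e.u. %.2f)  HI %.2f (e.u. %.2f)  RI %.2f\n",
              x$ci, x$ci_excl_uninformative, x$hi,
              x$hi_excl_uninformative, x$ri))
  invisible(x)
}
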