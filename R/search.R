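#' Search configuration
#'
#' Bundle of settings for [heuristic_search()] and [bootstrap_support()]:
#' number of random-addition replicates, the cap on stored equally
#' parsimonious trees (maxtrees), the random seed, the polymorphism
#' semantics and whether equal-length trees found while swapping are kept.
#'
#' @param n_addition_replicates random-addition-sequence replicates.
#' @param maxtrees cap on the stored tree pool; the search keeps looking for
#'   shorter trees after the cap is hit and flags truncation.
#' @param seed integer seed; replicate `r` draws from a stream derived from
#'   `seed` and `r`, so results are reproducible under any execution order.
#' @param polymorphism_mode `"uncertainty"` (state sets enter the Fitch
#'   downpass) or `"polymorphism"` (adds the per-cell surcharge).
#' @param keep_ties collect equal-length distinct trees at each swap
#'   optimum.
#' @return a list of class `search_config`.
#' @export
search_config <- function(n_addition_replicates = 1000, maxtrees = 5000,
                          seed = 1L,
                          polymorphism_mode = c("uncertainty", "polymorphism"),
                          keep_ties = TRUE) {
  stopifnot(n_addition_replicates >= 1, maxtrees >= 1)
  structure(list(n_addition_replicates = as.integer(n_addition_replicates),
                 maxtrees = as.integer(maxtrees),
                 seed = as.integer(seed),
                 polymorphism_mode = match.arg(polymorphism_mode),
                 keep_ties = isTRUE(keep_ties)),
            class = "search_config")
}

# derived per-replicate seed stream (kept below 2^31)
replicate_seed <- function(seed, r) {
  as.integer((as.double(seed) * 48271 + as.double(r) * 7919) %% 2147483647)
}

# one random-addition tree: taxa inserted in random order, each at its
# best position (ties broken uniformly at random from the stream); the
# hypothetical outgroup, when identified, is attached last so that the
# ingroup structure forms first and the root placement is a single
# parsimony decision
random_addition_tree <- function(nTip, masks, ord) {
  E <- three_tip_tree(ord[1:3], nTip)
  for (t in ord[seq(4L, length.out = nTip - 3L)]) {
    new_int <- max(E) + 1L
    lens <- vapply(seq_len(nrow(E)), function(i)
      sum(fitch_steps_cpp(insert_leaf(E, i, t, new_int), nTip, masks)),
      numeric(1))
    best <- which(lens == min(lens))
    pick <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best
    E <- insert_leaf(E, pick, t, new_int)
  }
  renumber_tree(E, nTip)
}

# one scan of the TBR neighborhood, generated lazily edge by edge:
# first-improvement descent (returns as soon as a strictly shorter tree is
# found); at a local optimum the full scan collects equal-length neighbors
tbr_scan <- function(E, nTip, masks, len) {
  ties <- list()
  top <- max(E)
  for (i in seq_len(nrow(E))) {
    E2 <- E[-i, , drop = FALSE]
    sideA <- split_side(E2, E[i, 1])
    sideB <- split_side(E2, E[i, 2])
    for (oa in attach_options(sideA)) {
      A <- attach_at(sideA, oa, top + 1L)
      for (ob in attach_options(sideB)) {
        B <- attach_at(sideB, ob, top + 2L)
        En <- rbind(A$edges, B$edges, c(A$node, B$node))
        l <- sum(fitch_steps_cpp(En, nTip, masks))
        if (l < len)
          return(list(improved = TRUE, tree = renumber_tree(En, nTip),
                      length = l))
        if (l == len) ties[[length(ties) + 1L]] <- renumber_tree(En, nTip)
      }
    }
  }
  list(improved = FALSE, ties = ties)
}

# TBR hill climbing: move to a strictly shorter neighbor while one exists;
# at the local optimum also return the equal-length neighbors (the plateau)
tbr_search <- function(E, nTip, masks) {
  len <- sum(fitch_steps_cpp(E, nTip, masks))
  repeat {
    sc <- tbr_scan(E, nTip, masks, len)
    if (sc$improved) {
      E <- sc$tree; len <- sc$length
    } else {
      return(list(tree = E, length = len, ties = sc$ties))
    }
  }
}

#' Heuristic maximum-parsimony search
#'
#' Random-addition-sequence stepwise construction followed by
#' tree-bisection-reconnection (TBR) branch swapping, repeated over
#' `config$n_addition_replicates` replicates. Strictly shorter trees are
#' always accepted; equal-length distinct topologies encountered at each
#' swap optimum are pooled and deduplicated, truncating at
#' `config$maxtrees` (with a flag) while the search for shorter trees
#' continues.
#'
#' @param matrix a [character_matrix()] that already includes the
#'   hypothetical all-immature outgroup (see [add_hypothetical_outgroup()]).
#' @param config a [search_config()].
#' @param outgroup taxon id of the hypothetical embryo; when present in the
#'   matrix it is inserted last in every addition sequence (the ingroup
#'   structure forms first, then the root attaches at its most parsimonious
#'   position). Ignored if absent.
#' @return object of class `mpt_set`: the pool of most parsimonious trees
#'   (internal edge matrices), their length, [score_indices()] scores, and
#'   the truncation flag.
#' @export
heuristic_search <- function(matrix, config = search_config(),
                             outgroup = "HYPOTHETICAL_EMBRYO") {
  nTip <- length(matrix$taxa)
  if (nTip < 4L) stop("heuristic search needs at least 4 taxa")
  og <- match(outgroup, matrix$taxa)
  masks <- state_masks(matrix)
  best_len <- Inf
  pool <- new.env(parent = emptyenv())
  truncated <- FALSE
  n_pool <- 0L
  add_tree <- function(E, len) {
    if (len > best_len) return(invisible())
    if (len < best_len) {
      best_len <<- len
      rm(list = ls(pool), envir = pool)
      n_pool <<- 0L
      truncated <<- FALSE
    }
    key <- tree_key(E, nTip)
    if (!is.null(pool[[key]])) return(invisible())
    if (n_pool >= config$maxtrees) { truncated <<- TRUE; return(invisible()) }
    pool[[key]] <- E
    n_pool <<- n_pool + 1L
  }
  for (r in seq_len(config$n_addition_replicates)) {
    set.seed(replicate_seed(config$seed, r))
    ord <- if (is.na(og)) sample.int(nTip)
           else c(sample(setdiff(seq_len(nTip), og)), og)
    E <- random_addition_tree(nTip, masks, ord)
    res <- tbr_search(E, nTip, masks)
    add_tree(res$tree, res$length)
    if (config$keep_ties && res$length <= best_len)
      for (T in res$ties) add_tree(T, res$length)
  }
  trees <- as.list(pool)
  trees <- trees[order(names(trees))]   # deterministic order
  surcharge <- if (config$polymorphism_mode == "polymorphism")
    polymorphism_surcharge(matrix) else 0L
  structure(list(trees = unname(trees),
                 keys = names(trees),
                 length = as.integer(best_len + surcharge),
                 fitch_length = as.integer(best_len),
                 score = score_indices(best_len, matrix),
                 truncated = truncated,
                 taxa = matrix$taxa,
                 config = config),
            class = "mpt_set")
}

#' @export
print.mpt_set <- function(x, ...) {
  cat("mpt_set:", length(x$trees), "most parsimonious tree(s), length",
      x$length, if (x$truncated) "(pool truncated at maxtrees)" else "", "\n")
  print(x$score)
  invisible(x)
}

#' Nonparametric bootstrap clade support
#'
#' Each replicate resamples characters with replacement (same count), runs a
#' one-addition-replicate TBR search and retains one best tree. Support for
#' each clade of the reference rooted consensus is the percentage of
#' replicate trees containing it.
#'
#' @param matrix a [character_matrix()] including the outgroup.
#' @param config a [search_config()]; `config$seed` drives the per-replicate
#'   streams (resampling and addition order).
#' @param replicates number of bootstrap replicates.
#' @param outgroup taxon id used to root clades.
#' @param reference_clades optional list of clades (integer tip sets) to
#'   score; defaults to the clades of the majority-rule consensus of a fresh
#'   heuristic search.
#' @return named numeric vector of support percentages, names are
#'   comma-separated sorted tip indices of each clade.
#' @export
bootstrap_support <- function(matrix, config = search_config(),
                              replicates = 5000,
                              outgroup = "HYPOTHETICAL_EMBRYO",
                              reference_clades = NULL) {
  nTip <- length(matrix$taxa)
  if (nTip < 4L) stop("bootstrap needs at least 4 taxa")
  og <- match(outgroup, matrix$taxa)
  if (is.na(og)) stop("outgroup '", outgroup, "' not in matrix")
  if (is.null(reference_clades)) {
    ms <- heuristic_search(matrix, config)
    cons <- consensus_tree(ms, matrix, method = "majority", outgroup = outgroup)
    reference_clades <- cons$clades
  }
  keys <- vapply(reference_clades, clade_key, character(1))
  hits <- stats::setNames(numeric(length(keys)), keys)
  masks0 <- state_masks(matrix)
  nc <- ncol(masks0)
  for (r in seq_len(replicates)) {
    set.seed(replicate_seed(config$seed, 100000L + r))
    cols <- sample.int(nc, nc, replace = TRUE)
    masks <- masks0[, cols, drop = FALSE]
    ord <- c(sample(setdiff(seq_len(nTip), og)), og)
    E <- random_addition_tree(nTip, masks, ord)
    res <- tbr_search(E, nTip, masks)
    rep_keys <- vapply(rooted_clades(res$tree, nTip, og), clade_key,
                       character(1))
    hits[keys %in% rep_keys] <- hits[keys %in% rep_keys] + 1
  }
  100 * hits / replicates
}
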