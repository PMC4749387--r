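#' Strict and majority-rule consensus of a tree pool
#'
#' Counts rooted clades (rooting every tree on the hypothetical outgroup)
#' across a pool of equally parsimonious trees. The strict consensus keeps
#' clades present in every tree; the majority-rule consensus keeps clades in
#' more than `cutoff` of the trees and labels each retained node with its
#' percent occurrence.
#'
#' @param trees an `mpt_set` from [heuristic_search()], or a list of
#'   internal edge matrices.
#' @param matrix the analyzed [character_matrix()] (for taxa labels).
#' @param method `"majority"` or `"strict"`.
#' @param cutoff majority fraction (default 0.5; clades must exceed it).
#' @param outgroup taxon id the output is rooted on.
#' @return object of class `consensus_tree`: an ape `phylo` (`$phy`) whose
#'   node labels carry percent occurrence, the retained clades and their
#'   occurrence table.
#' @export
consensus_tree <- function(trees, matrix, method = c("majority", "strict"),
                           cutoff = 0.5, outgroup = "HYPOTHETICAL_EMBRYO") {
  method <- match.arg(method)
  if (inherits(trees, "mpt_set")) trees <- trees$trees
  if (!length(trees)) stop("empty tree set")
  nTip <- length(matrix$taxa)
  og <- match(outgroup, matrix$taxa)
  if (is.na(og)) stop("outgroup '", outgroup, "' not in matrix")
  for (E in trees) {
    if (!identical(which(node_degrees(E) == 1L), seq_len(nTip)))
      stop("trees have mismatched leaf sets")
  }
  counts <- new.env(parent = emptyenv())
  store <- new.env(parent = emptyenv())
  for (E in trees) {
    for (cl in rooted_clades(E, nTip, og)) {
      key <- clade_key(cl)
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
      store[[key]] <- cl
    }
  }
  keys <- ls(counts)
  occ <- vapply(keys, function(k) counts[[k]], integer(1))
  pct <- 100 * occ / length(trees)
  keep <- if (method == "strict") occ == length(trees) else pct > 100 * cutoff
  clades <- lapply(keys[keep], function(k) store[[k]])
  labels <- round(pct[keep], 1)
  names(labels) <- keys[keep]
  phy <- clades_to_phylo(clades, matrix$taxa, node_labels = labels)
  structure(list(phy = phy, clades = clades, occurrence = labels,
                 method = method, cutoff = cutoff, n_trees = length(trees),
                 taxa = matrix$taxa, outgroup = outgroup),
            class = "consensus_tree")
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat(sprintf("%s consensus of %d tree(s): %d clades retained\n",
              x$method, x$n_trees, length(x$clades)))
  invisible(x)
}

#' Write a consensus tree (with support annotations) as Newick
#'
#' Node labels are written as `occ=<percent>` comments, optionally extended
#' with `bs=<percent>` bootstrap values matched by clade.
#'
#' @param cons a [consensus_tree()].
#' @param file output path; when `NULL` the Newick string is returned.
#' @param bootstrap optional named support vector from
#'   [bootstrap_support()].
#' @export
write_consensus_newick <- function(cons, file = NULL, bootstrap = NULL) {
  keys <- names(cons$occurrence)
  lab <- vapply(seq_along(keys), function(i) {
    s <- paste0("occ=", cons$occurrence[i])
    if (!is.null(bootstrap) && keys[i] %in% names(bootstrap))
      s <- paste0(s, ",bs=", round(bootstrap[[keys[i]]], 1))
    paste0("[&", s, "]")   # Newick comment carrying the annotations
  }, character(1))
  txt <- clades_to_newick(cons$clades, cons$taxa,
                          node_labels = stats::setNames(lab, keys))
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}
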