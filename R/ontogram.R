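#' Fit an ontogram to a sutural character matrix
#'
#' The central analysis of the package: a single-species tree obtained by
#' maximum parsimony on ontogenetic characters, rooted on a hypothetical
#' all-immature embryo. The fit runs the heuristic search
#' ([heuristic_search()]), builds strict and majority-rule consensus trees
#' ([consensus_tree()]), optionally computes bootstrap clade support
#' ([bootstrap_support()]), extracts the sutural obliteration sequence
#' ([obliteration_sequence()]) and, when specimen metadata are supplied,
#' quantifies how well the ontogram follows ontogeny
#' ([ontogram_linearity()]).
#'
#' @param matrix a [character_matrix()] of specimens x sutural characters.
#'   The hypothetical outgroup is appended automatically if absent.
#' @param records optional specimen metadata (see [read_specimen_table()])
#'   used for the linearity statistic.
#' @param config a [search_config()].
#' @param bootstrap_replicates bootstrap replicates (0 disables bootstrap).
#' @param consensus_cutoff majority-rule cutoff fraction.
#' @param terminal_state fully mature closure state (3 = obliterated).
#' @param outgroup name for the hypothetical all-immature embryo.
#' @return an object of class `ontogram`.
#' @examples
#' sim <- sim_ontogeny_study(n_specimens = 8, sutures_per_group = c(cranial = 4),
#'                           seed = 7)
#' fit <- ontogram(sim$matrix, sim$records,
#'                 config = search_config(n_addition_replicates = 3, seed = 7))
#' print(fit)
#' @export
ontogram <- function(matrix, records = NULL, config = search_config(),
                     bootstrap_replicates = 0, consensus_cutoff = 0.5,
                     terminal_state = 3L, outgroup = "HYPOTHETICAL_EMBRYO") {
  stopifnot(inherits(matrix, "character_matrix"))
  if (!outgroup %in% matrix$taxa)
    matrix <- add_hypothetical_outgroup(matrix, outgroup)
  search <- heuristic_search(matrix, config, outgroup = outgroup)
  maj <- consensus_tree(search, matrix, method = "majority",
                        cutoff = consensus_cutoff, outgroup = outgroup)
  strict <- consensus_tree(search, matrix, method = "strict",
                           outgroup = outgroup)
  boots <- NULL
  if (bootstrap_replicates > 0)
    boots <- bootstrap_support(matrix, config, replicates = bootstrap_replicates,
                               outgroup = outgroup,
                               reference_clades = maj$clades)
  obl <- obliteration_sequence(search, matrix, terminal_state = terminal_state,
                               outgroup = outgroup)
  lin <- NULL
  if (!is.null(records)) {
    lin <- tryCatch(ontogram_linearity(maj, records, outgroup = outgroup),
                    error = function(e) NULL)
  }
  structure(list(matrix = matrix, records = records, search = search,
                 score = search$score, consensus = maj,
                 consensus_strict = strict, bootstrap = boots,
                 obliteration = obl, linearity = lin,
                 outgroup = outgroup, call = match.call()),
            class = "ontogram")
}

#' @export
print.ontogram <- function(x, ...) {
  cat("ontogram fit:", length(x$matrix$taxa) - 1L, "specimens,",
      nrow(x$matrix$chars), "characters\n")
  cat("  MPTs:", length(x$search$trees),
      if (x$search$truncated) "(truncated)" else "", " length:",
      x$search$length, "\n")
  cat(sprintf("  CI %.2f  HI %.2f  RI %.2f\n",
              x$score$ci, x$score$hi, x$score$ri))
  if (!is.null(x$linearity))
    cat(sprintf("  ontogram linearity (Spearman depth~maturity): %.2f\n",
                x$linearity$rho))
  invisible(x)
}

#' @export
summary.ontogram <- function(object, ...) {
  x <- object
  cat("Ontogram analysis\n=================\n")
  print(x)
  cat("\nMajority-rule consensus:", length(x$consensus$clades),
      "clades; strict:", length(x$consensus_strict$clades), "clades\n")
  if (!is.null(x$bootstrap)) {
    cat("bootstrap support (%): ")
    print(stats::quantile(x$bootstrap))
  }
  cat("\n")
  print(x$obliteration)
  invisible(x)
}

#' @export
plot.ontogram <- function(x, which = c("majority", "strict"), ...) {
  which <- match.arg(which)
  cons <- if (which == "majority") x$consensus else x$consensus_strict
  phy <- cons$phy
  ape::plot.phylo(phy, ...)
  if (!is.null(phy$node.label))
    ape::nodelabels(phy$node.label, frame = "none", adj = c(1.1, -0.3),
                    cex = 0.7)
  invisible(x)
}

#' Ontogram linearity: does tree depth follow ontogeny?
#'
#' Spearman rank correlation between each specimen's root-to-tip node depth
#' on the (consensus) ontogram and its ontogenetic rank (ordered category,
#' or numeric age when supplied). +1 means a perfectly ontogeny-ordered
#' pectinate tree; negative values mean the ontogram runs against ontogeny,
#' as when sutures widen instead of closing.
#'
#' @param tree a [consensus_tree()], ape `phylo`, or `ontogram`.
#' @param records specimen metadata with `specimen_id` and either `category`
#'   or a numeric `age_years`/`rank` column.
#' @param outgroup taxon excluded from the correlation.
#' @return list with `rho`, `n` and the per-specimen depth/rank table.
#' @export
ontogram_linearity <- function(tree, records, outgroup = "HYPOTHETICAL_EMBRYO") {
  phy <- if (inherits(tree, "ontogram")) tree$consensus$phy
         else if (inherits(tree, "consensus_tree")) tree$phy
         else tree
  stopifnot(inherits(phy, "phylo"))
  n <- length(phy$tip.label)
  depth <- tip_depths_phylo(phy)
  ids <- gsub("_", " ", phy$tip.label)
  keep <- canonical_id(ids) != canonical_id(outgroup)
  rk <- specimen_ranks(records)
  idx <- match(canonical_id(ids[keep]), canonical_id(names(rk)))
  ok <- !is.na(idx) & !is.na(rk[idx])
  if (sum(ok) < 3L) stop("need at least 3 ranked specimens on the tree")
  d <- depth[keep][ok]; r <- rk[idx][ok]
  rho <- suppressWarnings(stats::cor(d, r, method = "spearman"))
  list(rho = rho, n = sum(ok),
       table = data.frame(specimen_id = ids[keep][ok], depth = d, rank = r,
                          stringsAsFactors = FALSE))
}

tip_depths_phylo <- function(phy) {
  n <- length(phy$tip.label)
  M <- max(phy$edge)
  parent <- integer(M)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  d <- integer(M); d[root] <- 0L
  # edges in phy are in preorder-compatible order after read.tree
  for (i in seq_len(nrow(phy$edge)))
    d[phy$edge[i, 2]] <- d[phy$edge[i, 1]] + 1L
  d[seq_len(n)]
}

CATEGORY_LEVELS <- c("juvenile", "subadult", "sexually_mature",
                     "skeletally_mature")

specimen_ranks <- function(records) {
  ids <- records$specimen_id
  if (!is.null(records$age_years) && any(!is.na(records$age_years))) {
    return(stats::setNames(as.numeric(records$age_years), ids))
  }
  if (!is.null(records$rank)) return(stats::setNames(records$rank, ids))
  if (!is.null(records$category)) {
    r <- match(records$category, CATEGORY_LEVELS)
    return(stats::setNames(as.numeric(r), ids))
  }
  stop("records need a 'category', 'age_years' or 'rank' column")
}
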