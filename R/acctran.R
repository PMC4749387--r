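#' ACCTRAN ancestral-state reconstruction
#'
#' Assigns one state per internal node and character on a fully binary most
#' parsimonious tree rooted on the hypothetical outgroup. The assignment is
#' a minimum-change labeling (unit-cost dynamic programming); among equally
#' parsimonious labelings, state changes are accelerated, i.e. placed as
#' close to the root as possible: when a child can either inherit its
#' parent's state or change at equal total cost, the change is taken
#' immediately (preferring the more mature state on ties).
#'
#' @param tree an internal edge matrix, ape `phylo`, or a single tree drawn
#'   from an `mpt_set`.
#' @param matrix the scored [character_matrix()].
#' @param outgroup taxon id to root on.
#' @return object of class `state_reconstruction`: `states` is an
#'   (internal node x character) integer matrix, plus the rooted structure
#'   used (`rooting`), node depths and per-character change lists.
#' @export
acctran_reconstruct <- function(tree, matrix, outgroup = "HYPOTHETICAL_EMBRYO") {
  E <- if (inherits(tree, "phylo")) phylo_to_tree(tree, matrix$taxa) else tree
  nTip <- length(matrix$taxa)
  if (!is_binary_unrooted(E, nTip))
    stop("ACCTRAN needs a binary tree; reconstruct on an individual MPT, ",
         "not a consensus with polytomies")
  og <- match(outgroup, matrix$taxa)
  if (is.na(og)) stop("outgroup '", outgroup, "' not in matrix")
  rt <- root_on_leaf(E, og)
  nchar_ <- nrow(matrix$chars)
  nodes <- rt$preorder
  internal <- nodes[nodes > nTip]
  states <- base::matrix(NA_integer_, nrow = length(internal), ncol = nchar_,
                         dimnames = list(as.character(internal),
                                         matrix$chars$char_id))
  changes <- vector("list", nchar_)
  postorder <- rev(rt$preorder)
  for (ch in seq_len(nchar_)) {
    ns <- matrix$chars$max_state[ch] + 1L
    # unit-cost DP: cost[v, s] = min changes in subtree of v given state s
    cost <- base::matrix(0, nrow = max(nodes), ncol = ns)
    for (v in postorder) {
      if (v <= nTip) {
        cell <- matrix$cells[[v, ch]]
        allowed <- if (is_missing_cell(cell)) 0:(ns - 1L) else cell
        cost[v, ] <- ifelse(0:(ns - 1L) %in% allowed, 0, Inf)
      } else {
        for (s in seq_len(ns)) {
          tot <- 0
          for (k in rt$children[[v]])
            tot <- tot + min(cost[k, ] + (seq_len(ns) != s))
          cost[v, s] <- tot
        }
      }
    }
    # top-down assignment, accelerating changes
    assign <- integer(max(nodes))
    ch_list <- list()
    for (v in rt$preorder) {
      if (v == rt$root) {
        s <- which(cost[v, ] == min(cost[v, ]))[1] - 1L  # smallest optimal state
      } else {
        p <- assign[rt$parent[v]] + 1L
        opts <- cost[v, ] + (seq_len(ncol(cost)) != p)
        cand <- which(opts == min(opts)) - 1L
        s <- if (any(cand != p - 1L)) max(cand[cand != p - 1L]) else p - 1L
        if (s != p - 1L)
          ch_list[[length(ch_list) + 1L]] <-
            c(parent = rt$parent[v], node = v, from = p - 1L, to = s)
      }
      assign[v] <- s
      if (v > nTip) states[as.character(v), ch] <- s
    }
    tab <- if (length(ch_list)) do.call(rbind, ch_list) else
      base::matrix(integer(0), ncol = 4,
                   dimnames = list(NULL, c("parent", "node", "from", "to")))
    storage.mode(tab) <- "integer"
    changes[[ch]] <- tab
  }
  structure(list(states = states, rooting = rt, depths = node_depths(rt),
                 changes = changes, taxa = matrix$taxa, outgroup = outgroup,
                 edge = E),
            class = "state_reconstruction")
}

#' Sutural obliteration sequence from a pool of most parsimonious trees
#'
#' For each closure character, finds the most rootward node whose descendant
#' specimens all score exactly the terminal (obliterated) state -- i.e. the
#' clade of specimens in which that suture has fully obliterated. A
#' character enters the sequence only when that clade is identical across
#' all MPTs; the sequence is ordered by backbone rank (clade size, largest
#' first, so obliterations acquired nearest the root come first). Characters
#' whose obliterated specimens do not form a clade on every MPT are flagged
#' inconsistent.
#'
#' @param mpts an `mpt_set` from [heuristic_search()] or list of edge
#'   matrices.
#' @param matrix the scored [character_matrix()].
#' @param terminal_state the fully mature state (3 = obliterated for closure
#'   characters). A polymorphic cell containing the terminal state does not
#'   count: obliteration is categorical.
#' @param outgroup taxon id to root on.
#' @return object of class `obliteration_sequence`: a data frame with one
#'   row per consistently placed character (`rank`, `char_id`, `suture`,
#'   `clade_size`, `n_obliterated`) and the vector of inconsistent
#'   characters.
#' @export
obliteration_sequence <- function(mpts, matrix, terminal_state = 3L,
                                  outgroup = "HYPOTHETICAL_EMBRYO") {
  trees <- if (inherits(mpts, "mpt_set")) mpts$trees else mpts
  if (!length(trees)) stop("empty tree set")
  nTip <- length(matrix$taxa)
  og <- match(outgroup, matrix$taxa)
  if (is.na(og)) stop("outgroup '", outgroup, "' not in matrix")
  closure <- which(matrix$chars$aspect == "closure")
  if (!length(closure))
    return(empty_obliteration_sequence())
  # per character: tips scored exactly {terminal_state}
  term_sets <- lapply(closure, function(j) {
    which(vapply(seq_len(nTip), function(i) {
      cell <- matrix$cells[[i, j]]
      !is_missing_cell(cell) && identical(cell, as.integer(terminal_state))
    }, logical(1)))
  })
  keep <- lengths(term_sets) > 0L
  closure <- closure[keep]; term_sets <- term_sets[keep]
  if (!length(closure)) return(empty_obliteration_sequence())
  clade_sets <- lapply(trees, function(E) {
    vapply(rooted_clades(E, nTip, og), clade_key, character(1))
  })
  consistent <- logical(length(closure))
  for (k in seq_along(closure)) {
    tk <- clade_key(term_sets[[k]])
    consistent[k] <- length(term_sets[[k]]) >= 2L &&
      all(vapply(clade_sets, function(cs) tk %in% cs, logical(1)))
    # a single obliterated specimen is trivially a "clade" on every tree
    if (length(term_sets[[k]]) == 1L) consistent[k] <- TRUE
  }
  ok <- which(consistent)
  if (!length(ok)) {
    out <- empty_obliteration_sequence()
    out$inconsistent <- matrix$chars$char_id[closure[!consistent]]
    return(out)
  }
  sizes <- lengths(term_sets[ok])
  rank <- match(-sizes, sort(unique(-sizes)))  # largest clade = rank 1
  o <- order(rank, matrix$chars$char_id[closure[ok]])
  df <- data.frame(rank = rank[o],
                   char_id = matrix$chars$char_id[closure[ok]][o],
                   suture = matrix$chars$suture[closure[ok]][o],
                   clade_size = sizes[o],
                   n_obliterated = sizes[o],
                   stringsAsFactors = FALSE)
  structure(list(sequence = df,
                 inconsistent = matrix$chars$char_id[closure[!consistent]],
                 terminal_state = as.integer(terminal_state)),
            class = "obliteration_sequence")
}

empty_obliteration_sequence <- function() {
  structure(list(sequence = data.frame(rank = integer(0),
                                       char_id = character(0),
                                       suture = character(0),
                                       clade_size = integer(0),
                                       n_obliterated = integer(0),
                                       stringsAsFactors = FALSE),
                 inconsistent = character(0),
                 terminal_state = 3L),
            class = "obliteration_sequence")
}

#' @export
print.obliteration_sequence <- function(x, ...) {
  if (!nrow(x$sequence)) {
    cat("obliteration sequence: empty\n")
  } else {
    cat("obliteration sequence (rootward first):\n")
    for (r in unique(x$sequence$rank)) {
      rows <- x$sequence[x$sequence$rank == r, ]
      cat(sprintf("  (%d) %s\n", r, paste(rows$suture, collapse = ", ")))
    }
  }
  if (length(x$inconsistent))
    cat("  inconsistent across MPTs:", paste(x$inconsistent, collapse = ", "), "\n")
  invisible(x)
}
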