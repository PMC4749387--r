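# Internal tree representation
#
# Unrooted binary trees are integer edge matrices (one row per edge) over
# node ids: tips 1..nTip (indexing the analyzed matrix's taxa), internal
# nodes > nTip. All search/scoring code works on this representation; ape
# "phylo" objects are produced only at the user-facing boundary.

renumber_tree <- function(E, nTip) {
  ids <- sort(unique(as.integer(E)))
  internal <- ids[ids > nTip]
  if (!length(internal)) return(E)
  map <- integer(max(ids))
  map[seq_len(nTip)] <- seq_len(nTip)
  map[internal] <- nTip + seq_along(internal)
  matrix(map[E], ncol = 2L)
}

node_degrees <- function(E) tabulate(as.integer(E))

# the tree's leaves (degree-1 nodes) must be exactly the taxa 1..nTip
check_tree_tips <- function(E, nTip) {
  deg <- node_degrees(E)
  leaves <- which(deg == 1L)
  if (!identical(leaves, seq_len(nTip)))
    stop("tree tips do not match the matrix taxa")
  invisible(TRUE)
}

is_binary_unrooted <- function(E, nTip) {
  deg <- node_degrees(E)
  all(deg[seq_len(nTip)] == 1L) && all(deg[-seq_len(nTip)][deg[-seq_len(nTip)] > 0] == 3L)
}

# adjacency list for BFS on small trees
adj_list <- function(E) {
  M <- max(E)
  adj <- vector("list", M)
  for (i in seq_len(nrow(E))) {
    a <- E[i, 1]; b <- E[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

component_of <- function(E, start) {
  if (!nrow(E)) return(start)
  adj <- adj_list(E)
  if (start > length(adj) || is.null(adj[[start]])) return(start)
  seen <- integer(0)
  queue <- start
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v %in% seen) next
    seen <- c(seen, v)
    queue <- c(queue, setdiff(adj[[v]], seen))
  }
  seen
}

# splits (tip bipartitions) of an unrooted tree; each split is represented
# by the sorted tip set on the side containing tip 1
tree_splits <- function(E, nTip) {
  lapply(seq_len(nrow(E)), function(i) {
    comp <- component_of(E[-i, , drop = FALSE], E[i, 1])
    tips <- sort(intersect(comp, seq_len(nTip)))
    if (1L %in% tips) tips else sort(setdiff(seq_len(nTip), tips))
  })
}

# canonical key of the unrooted topology (used to deduplicate MPTs)
tree_key <- function(E, nTip) {
  sp <- tree_splits(E, nTip)
  keys <- vapply(sp, paste, character(1), collapse = ",")
  paste(sort(unique(keys)), collapse = ";")
}

# the unique unrooted tree on tips 1..3
three_tip_tree <- function(tips, nTip) {
  x <- nTip + 1L
  cbind(c(x, x, x), tips)
}

# insert leaf on edge i: subdivide (a,b) with new node, attach the leaf
insert_leaf <- function(E, i, leaf, new_internal) {
  a <- E[i, 1]; b <- E[i, 2]
  rbind(E[-i, , drop = FALSE],
        c(a, new_internal), c(new_internal, b), c(new_internal, leaf))
}

# --- TBR neighborhood --------------------------------------------------------

# after deleting an edge, describe one side: its edge set (with the old
# endpoint suppressed if it became degree-2) and, if it is a lone node,
# that node
split_side <- function(E2, v) {
  comp <- component_of(E2, v)
  rows <- E2[E2[, 1] %in% comp & E2[, 2] %in% comp, , drop = FALSE]
  if (!nrow(rows)) return(list(edges = rows, point = v))
  inc <- which(rows[, 1] == v | rows[, 2] == v)
  if (length(inc) == 2L) {   # suppress the degree-2 endpoint
    n1 <- setdiff(as.integer(rows[inc[1], ]), v)
    n2 <- setdiff(as.integer(rows[inc[2], ]), v)
    rows <- rbind(rows[-inc, , drop = FALSE], c(n1, n2))
  } else if (length(inc) == 1L) { # v keeps degree 1: attach back at v
    return(list(edges = rows, point = v))
  }
  list(edges = rows, point = NA_integer_)
}

# attach a dangling stub to a side at a given option; returns list(edges, node)
attach_at <- function(side, opt, fresh) {
  if (!is.na(side$point) && opt == 0L)
    return(list(edges = side$edges, node = side$point))
  e <- side$edges[opt, ]
  list(edges = rbind(side$edges[-opt, , drop = FALSE],
                     c(e[1], fresh), c(fresh, e[2])),
       node = fresh)
}

attach_options <- function(side) {
  if (!is.na(side$point) && !nrow(side$edges)) return(0L)
  opts <- seq_len(nrow(side$edges))
  if (!is.na(side$point)) opts <- c(0L, opts)
  opts
}

# all TBR rearrangements of an unrooted binary tree (includes SPR and NNI);
# returned trees are renumbered; the original topology may reappear and is
# filtered by key upstream
tbr_neighbors <- function(E, nTip) {
  out <- list()
  top <- max(E)
  for (i in seq_len(nrow(E))) {
    a <- E[i, 1]; b <- E[i, 2]
    E2 <- E[-i, , drop = FALSE]
    sideA <- split_side(E2, a)
    sideB <- split_side(E2, b)
    for (oa in attach_options(sideA)) {
      A <- attach_at(sideA, oa, top + 1L)
      for (ob in attach_options(sideB)) {
        B <- attach_at(sideB, ob, top + 2L)
        En <- rbind(A$edges, B$edges, c(A$node, B$node))
        out[[length(out) + 1L]] <- renumber_tree(En, nTip)
      }
    }
  }
  out
}

# --- exhaustive enumeration --------------------------------------------------

#' Enumerate all unrooted binary topologies
#'
#' Generates every unrooted binary tree over `n` tips by recursive leaf
#' insertion (3, 15, 105, 945 ... trees). Used as the exhaustive oracle for
#' the heuristic search on small matrices.
#'
#' @param n number of tips (3--8 is practical).
#' @return list of integer edge matrices (internal representation).
#' @export
all_unrooted_trees <- function(n) {
  stopifnot(n >= 3)
  trees <- list(three_tip_tree(1:3, n))
  for (tip in seq(4L, length.out = max(0L, n - 3L))) {
    nxt <- vector("list", length(trees) * (2L * (tip - 1L) - 3L))
    k <- 0L
    for (E in trees) {
      new_int <- max(E) + 1L
      for (i in seq_len(nrow(E))) {
        k <- k + 1L
        nxt[[k]] <- insert_leaf(E, i, tip, new_int)
      }
    }
    trees <- lapply(nxt, renumber_tree, nTip = n)
  }
  trees
}

# --- rooting and conversion --------------------------------------------------

# root an unrooted tree on a leaf; returns parent vector, children list and
# a preorder of nodes; the root is a fresh node with children {leaf, rest}
root_on_leaf <- function(E, leaf) {
  adj <- adj_list(E)
  root <- max(E) + 1L
  v <- adj[[leaf]]
  stopifnot(length(v) == 1L)
  parent <- integer(root); parent[] <- NA_integer_
  children <- vector("list", root)
  parent[leaf] <- root; parent[v] <- root
  children[[root]] <- c(leaf, v)
  order <- c(root, leaf)
  stack <- v
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    order <- c(order, x)
    kids <- setdiff(adj[[x]], which(!is.na(parent)))  # incl. the root leaf
    children[[x]] <- kids
    for (k in kids) parent[k] <- x
    stack <- c(stack, kids)
  }
  list(root = root, parent = parent, children = children, preorder = order)
}

# rooted clades (ingroup tip sets) of an unrooted tree rooted on `leaf`:
# for every edge, the tip set of the side away from the root leaf
rooted_clades <- function(E, nTip, leaf) {
  cl <- lapply(seq_len(nrow(E)), function(i) {
    comp <- component_of(E[-i, , drop = FALSE], E[i, 1])
    tips <- sort(intersect(comp, seq_len(nTip)))
    if (leaf %in% tips) sort(setdiff(seq_len(nTip), tips)) else tips
  })
  cl[lengths(cl) >= 2L]   # non-trivial clades only
}

clade_key <- function(tips) paste(tips, collapse = ",")

# build a rooted Newick string from a set of mutually compatible clades
# over the full tip set; `labels` are tip labels, `node_labels` named by
# clade key and inserted verbatim after the closing parenthesis
clades_to_newick <- function(clades, labels, node_labels = NULL) {
  n <- length(labels)
  safe <- gsub("[[:space:],;:()]+", "_", labels)
  keys <- vapply(clades, clade_key, character(1))
  dup <- duplicated(keys)
  clades <- clades[!dup]; keys <- keys[!dup]
  o <- order(-lengths(clades))
  clades <- clades[o]; keys <- keys[o]
  lab_of <- function(key) {
    if (is.null(node_labels) || is.na(match(key, names(node_labels)))) ""
    else as.character(node_labels[[key]])
  }
  build <- function(tipset, pool) {
    inside <- pool[vapply(pool, function(cl) all(cl %in% tipset) &&
                            length(cl) < length(tipset), logical(1))]
    parts <- list()
    if (length(inside)) {
      for (ii in seq_along(inside)) {   # maximal clades first (sorted by size)
        cl <- inside[[ii]]
        covered <- any(vapply(parts, function(p) all(cl %in% p$tips), logical(1)))
        if (!covered) parts[[length(parts) + 1L]] <- list(tips = cl)
      }
    }
    used <- unlist(lapply(parts, `[[`, "tips"))
    loose <- setdiff(tipset, used)
    pieces <- character(0)
    for (p in parts) {
      sub <- build(p$tips, inside)
      pieces <- c(pieces, paste0(sub, lab_of(clade_key(p$tips))))
    }
    pieces <- c(pieces, safe[loose])
    if (length(pieces) == 1L) return(pieces)
    paste0("(", paste(pieces, collapse = ","), ")")
  }
  paste0(build(sort(seq_len(n)), clades), ";")
}

# same, but returning an ape phylo (node labels must then be ape-safe)
clades_to_phylo <- function(clades, labels, node_labels = NULL) {
  ape::read.tree(text = clades_to_newick(clades, labels, node_labels))
}

# convert an unrooted internal tree to a rooted ape phylo (rooted on a tip
# when given, else on an arbitrary internal node giving a basal trichotomy)
as_phylo_tree <- function(E, nTip, labels, root_tip = NULL) {
  if (is.null(root_tip)) {
    phy <- clades_to_phylo(tree_splits_as_clades(E, nTip), labels)
    return(phy)
  }
  cl <- rooted_clades(E, nTip, root_tip)
  clades_to_phylo(cl, labels)
}

tree_splits_as_clades <- function(E, nTip) {
  sp <- tree_splits(E, nTip)
  # treat side not containing tip 1 as "clades" (arbitrary rooting on tip 1)
  cl <- lapply(sp, function(s) sort(setdiff(seq_len(nTip), s)))
  cl[lengths(cl) >= 2L]
}

# convert an ape phylo (binary, possibly rooted) to the internal unrooted
# edge matrix, tips matched to `taxa` by label
phylo_to_tree <- function(phy, taxa) {
  lab <- gsub("[[:space:]_]+", "", phy$tip.label)
  ref <- gsub("[[:space:]_]+", "", taxa)
  idx <- match(toupper(lab), toupper(ref))
  if (anyNA(idx))
    stop("tree tips not found in matrix taxa: ",
         paste(phy$tip.label[is.na(idx)], collapse = ", "))
  n <- length(taxa)
  E <- phy$edge
  map <- integer(max(E))
  map[seq_along(idx)] <- idx
  internals <- sort(unique(E[E > length(idx)]))
  map[internals] <- n + seq_along(internals)
  E <- matrix(map[E], ncol = 2L)
  # unroot if the root is degree 2: merge its two edges
  deg <- node_degrees(E)
  r <- which(deg == 2L)
  r <- r[r > n]
  for (v in r) {
    inc <- which(E[, 1] == v | E[, 2] == v)
    nb <- setdiff(as.integer(E[inc, ]), v)
    E <- rbind(E[-inc, , drop = FALSE], nb)
  }
  renumber_tree(E, n)
}

# depth (edges from root) of every node in a rooted structure
node_depths <- function(rt) {
  d <- integer(length(rt$parent))
  for (v in rt$preorder) {
    d[v] <- if (v == rt$root) 0L else d[rt$parent[v]] + 1L
  }
  d
}
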