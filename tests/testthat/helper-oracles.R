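# Independent reference implementations and fixture builders used across the
# suite. The reference Fitch is written recursively over R integer sets, on
# purpose sharing no code with the package's C++ kernel.

# reference Fitch step count for one character on an unrooted tree given as
# an edge matrix (tips 1..nTip); cells: list of integer state vectors
# (NA = missing)
ref_fitch_char <- function(E, nTip, cells, max_state) {
  adj <- list()
  for (r in seq_len(nrow(E))) {
    a <- as.character(E[r, 1]); b <- as.character(E[r, 2])
    adj[[a]] <- c(adj[[a]], E[r, 2])
    adj[[b]] <- c(adj[[b]], E[r, 1])
  }
  steps <- 0L
  down <- function(v, parent) {
    if (v <= nTip) {
      cl <- cells[[v]]
      if (length(cl) == 1L && is.na(cl[1])) return(0:max_state)
      return(cl)
    }
    kids <- setdiff(adj[[as.character(v)]], parent)
    acc <- NULL
    for (k in kids) {
      s <- down(k, v)
      if (is.null(acc)) { acc <- s; next }
      inter <- intersect(acc, s)
      if (length(inter)) acc <- inter
      else { acc <- union(acc, s); steps <<- steps + 1L }
    }
    acc
  }
  root <- max(E)
  if (root <= nTip) root <- E[1, 1]
  invisible(down(root, NA))
  steps
}

ref_fitch_length <- function(E, m) {
  nTip <- length(m$taxa)
  sum(vapply(seq_len(nrow(m$chars)), function(j)
    ref_fitch_char(E, nTip, m$cells[, j], m$chars$max_state[j]), integer(1)))
}

# random small closure-character matrix for oracle tests
random_matrix <- function(n_taxa, n_chars, seed, states = 0:3,
                          poly_prob = 0.15, miss_prob = 0.05) {
  set.seed(seed)
  cells <- matrix(lapply(seq_len(n_taxa * n_chars), function(i) {
    u <- runif(1)
    if (u < miss_prob) return(NA_integer_)
    if (u < miss_prob + poly_prob)
      return(sort(sample(states, 2)))
    sample(states, 1)
  }), n_taxa, n_chars)
  character_matrix(paste0("t", seq_len(n_taxa)), cells)
}

# small fixed unrooted trees over 4 tips
tree_ab_cd <- function() rbind(c(5, 1), c(5, 2), c(5, 6), c(6, 3), c(6, 4))

# exhaustive minimum length over all unrooted topologies
exhaustive_min_length <- function(m) {
  nTip <- length(m$taxa)
  masks <- ontogram:::state_masks(m)
  min(vapply(all_unrooted_trees(nTip), function(E)
    sum(ontogram:::fitch_steps_cpp(E, nTip, masks)), numeric(1)))
}
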