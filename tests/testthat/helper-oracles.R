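# Independent oracles and random-instance generators used across tests.

# Exhaustive minimum-change count: enumerate every assignment of states to
# internal nodes and count mismatching edges. Missing leaves match any
# parent state. Independent of the Fitch/Hartigan dynamic program.
oracle_min_steps <- function(tree, states) {
  tips <- tree$tip.label
  x <- as.character(states[tips])
  x[x %in% c("N", "?", "-")] <- NA_character_
  lev <- sort(unique(x[!is.na(x)]))
  k <- length(lev)
  n <- length(tips)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), tree$Nnode)))
  cost <- integer(nrow(grid))
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    ch <- tree$edge[i, 2]
    pa <- grid[, p - n]
    if (ch <= n) {
      if (is.na(x[ch])) next
      cost <- cost + (lev[pa] != x[ch])
    } else {
      cost <- cost + (pa != grid[, ch - n])
    }
  }
  min(cost)
}

# Brute-force minimum number of disjoint member-only clades covering a
# group: enumerate subsets of candidate clades by increasing size.
oracle_clade_cover <- function(tree, members) {
  n <- length(tree$tip.label)
  sets <- lapply(seq_len(n + tree$Nnode), function(v) {
    tree$tip.label[phangorn::Descendants(tree, v, "tips")[[1]]]
  })
  cand <- Filter(function(s) length(s) > 0 && all(s %in% members), sets)
  cand <- unique(cand)
  for (k in seq_len(length(members))) {
    combos <- utils::combn(length(cand), k, simplify = FALSE)
    for (idx in combos) {
      chosen <- cand[idx]
      u <- unlist(chosen)
      if (!anyDuplicated(u) && setequal(u, members)) return(k)
    }
  }
  stop("no cover found")  # unreachable: singletons always cover
}

# Random rooted tree, optionally with polytomies created by collapsing
# internal edges.
random_tree <- function(n, polytomy_prob = 0) {
  tr <- ape::rtree(n)
  if (polytomy_prob > 0 && !is.null(tr$edge.length)) {
    internal <- tr$edge[, 2] > n
    collapse <- internal & stats::runif(nrow(tr$edge)) < polytomy_prob
    tr$edge.length[collapse] <- 0
    tr <- ape::di2multi(tr)
  }
  tr
}

# Random character over the tips of a tree.
random_character <- function(tree, n_states = 2, missing_prob = 0) {
  n <- length(tree$tip.label)
  x <- sample(c("A", "C", "G", "T")[seq_len(n_states)], n, replace = TRUE)
  if (missing_prob > 0) x[stats::runif(n) < missing_prob] <- NA
  if (all(is.na(x))) x[1] <- "A"
  stats::setNames(x, tree$tip.label)
}

# Small alignment built from explicit columns (list of per-terminal
# character vectors).
aln_from_columns <- function(cols, ids = NULL) {
  m <- do.call(cbind, cols)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(m)))
  rownames(m) <- ids
  as_alignment(m)
}

# Random DNA alignment.
random_alignment <- function(n, L, missing_prob = 0) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  if (missing_prob > 0) {
    m[stats::runif(n * L) < missing_prob] <- sample(c("N", "-", "?"), 1)
  }
  rownames(m) <- paste0("s", seq_len(n))
  as_alignment(m)
}
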