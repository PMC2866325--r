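# Taxonomic congruence: concordance groups (genus, subfamily, family,
# superfamily taxa) are encoded as binary membership characters
# (1 = member, 0 = non-member) and scored on cladograms. Three ensemble
# measures summarise how close the taxa are to monophyly:
#
#   PMT = (number of monophyletic groups) / Mt
#   TCI = Mt / St            (taxon consistency index)
#   TRI = (Gt - St)/(Gt - Mt) (taxon retention index)
#
# with Mt the number of test groups, St the summed minimum number of
# clades each group exhibits on the tree, and Gt the number of terminals
# in the datamatrix. The best possible score is 1; lower values indicate
# taxa further from monophyly.

#' Test a concordance group for monophyly
#'
#' Rooted convention: the group is monophyletic iff some node's exact set
#' of descendant leaves equals the member set (the complement of a group
#' is not accepted as the group). The group of all leaves is monophyletic
#' at the root.
#'
#' @param tree a rooted `phylo` (basal polytomies allowed).
#' @param members character vector of member leaf labels (non-empty).
#' @return logical flag.
#' @export
is_monophyletic <- function(tree, members) {
  clade_count(tree, members) == 1L
}

#' Minimum number of clades a group exhibits on a tree
#'
#' The number of maximal member-only clades, i.e. the minimum number of
#' disjoint clades of the tree whose union is exactly the member set.
#' Equals 1 iff the group is monophyletic; at most the member count
#' (isolated leaves). Equivalent to optimizing the binary membership
#' character on the tree with the root constrained to the non-member
#' state; with `rooted = FALSE` the unrooted ("clan") convention is used
#' instead: `max(1, Fitch steps of the membership character)`, under which
#' a group whose complement is a clade also counts as a single clan.
#'
#' @param tree a `phylo`.
#' @param members member leaf labels (non-empty, subset of the leaves).
#' @param rooted use the rooted convention (default) or the unrooted clan
#'   convention.
#' @return integer count >= 1.
#' @export
clade_count <- function(tree, members, rooted = TRUE) {
  members <- unique(trimws(members))
  if (length(members) == 0L) stop("empty concordance group")
  absent <- setdiff(members, tree$tip.label)
  if (length(absent)) {
    stop("group member(s) absent from tree: ", paste(absent, collapse = ", "))
  }
  if (!rooted) {
    st <- stats::setNames(as.integer(tree$tip.label %in% members),
                          tree$tip.label)
    return(max(1L, steps_on_tree(tree, st)))
  }
  n <- length(tree$tip.label)
  total <- n + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  is_mem <- tree$tip.label %in% members
  # all_mem[v]: every leaf below v is a member; count maximal such nodes
  all_mem <- c(is_mem, rep(TRUE, tree$Nnode))
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]; ch <- tr$edge[i, 2]
    all_mem[p] <- all_mem[p] && all_mem[ch]
  }
  root <- n + 1L
  if (all_mem[root]) return(1L)
  cnt <- 0L
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]; ch <- tr$edge[i, 2]
    if (all_mem[ch] && !all_mem[p]) cnt <- cnt + 1L
  }
  cnt
}

#' Taxonomic congruence of a set of groups on one tree
#'
#' Scores every membership character of `groups` on the tree and computes
#' PMT, TCI and TRI. Gt is the number of leaves of the scored tree; TRI is
#' `NA` when Gt = Mt.
#'
#' @param tree a `phylo`.
#' @param groups a `gg_membership` matrix (see
#'   [build_membership_matrix()]) or a named list of member-id vectors.
#' @param rooted convention passed to [clade_count()].
#' @return list of class `gg_taxon_congruence` with elements `per_group`
#'   (data frame: `group`, `members`, `s_t`, `monophyletic`) and `scores`
#'   (one-row data frame: `M_t`, `S_t`, `G_t`, `n_monophyletic`, `PMT`,
#'   `TCI`, `TRI`).
#' @export
taxon_congruence <- function(tree, groups, rooted = TRUE) {
  groups <- as_group_list(groups)
  if (length(groups) == 0L) stop("no concordance groups supplied")
  s_t <- vapply(groups, function(m) clade_count(tree, m, rooted = rooted),
                integer(1))
  per_group <- data.frame(
    group = names(groups),
    members = lengths(groups),
    s_t = s_t,
    monophyletic = s_t == 1L,
    row.names = NULL
  )
  M_t <- length(groups)
  S_t <- sum(s_t)
  G_t <- length(tree$tip.label)
  n_mono <- sum(per_group$monophyletic)
  scores <- data.frame(
    M_t = M_t, S_t = S_t, G_t = G_t, n_monophyletic = n_mono,
    PMT = n_mono / M_t,
    TCI = M_t / S_t,
    TRI = if (G_t > M_t) (G_t - S_t) / (G_t - M_t) else NA_real_
  )
  structure(list(per_group = per_group, scores = scores),
            class = "gg_taxon_congruence")
}

as_group_list <- function(groups) {
  if (inherits(groups, "gg_membership") ||
      (is.matrix(groups) && !is.null(colnames(groups)))) {
    terminals <- rownames(groups)
    out <- lapply(seq_len(ncol(groups)),
                  function(j) terminals[groups[, j] == 1L])
    names(out) <- colnames(groups)
    return(out)
  }
  if (is.list(groups)) return(groups)
  stop("groups must be a membership matrix or a named list")
}

#' @export
print.gg_taxon_congruence <- function(x, ...) {
  s <- x$scores
  cat(sprintf(
    "Taxonomic congruence: Mt=%d St=%d Gt=%d | PMT=%.3f TCI=%.3f TRI=%s\n",
    s$M_t, s$S_t, s$G_t, s$PMT, s$TCI,
    ifelse(is.na(s$TRI), "NA", sprintf("%.3f", s$TRI))))
  invisible(x)
}

#' Taxonomic congruence across several trees
#'
#' Scores the same groups on each tree (for instance a set of equally
#' parsimonious cladograms) and summarises with the across-tree mean and
#' range per measure. Optionally also scores the strict consensus.
#'
#' @param trees list of `phylo` with identical leaf sets.
#' @param groups as in [taxon_congruence()].
#' @param rooted convention passed to [clade_count()].
#' @param consensus also score the strict consensus of the trees.
#' @return list of class `gg_taxon_congruence_multi` with `per_tree`
#'   (data frame, one row per tree), `summary` (mean / min / max rows) and
#'   optionally `consensus` (the consensus scores row).
#' @export
taxon_congruence_multi <- function(trees, groups, rooted = TRUE,
                                   consensus = FALSE) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0L) stop("no trees supplied")
  leaves <- lapply(trees, `[[`, "tip.label")
  if (!all(vapply(leaves, setequal, logical(1), y = leaves[[1]]))) {
    stop("trees do not share an identical leaf set")
  }
  per_tree <- do.call(rbind, lapply(seq_along(trees), function(i) {
    sc <- taxon_congruence(trees[[i]], groups, rooted = rooted)$scores
    cbind(tree = i, sc)
  }))
  meas <- c("PMT", "TCI", "TRI")
  summary <- data.frame(
    stat = c("mean", "min", "max"),
    rbind(colMeans(per_tree[meas]),
          apply(per_tree[meas], 2, min),
          apply(per_tree[meas], 2, max))
  )
  out <- list(per_tree = per_tree, summary = summary)
  if (consensus && length(trees) > 1L) {
    cons <- ape::consensus(trees, p = 1, rooted = TRUE)
    out$consensus <- taxon_congruence(cons, groups, rooted = rooted)$scores
  }
  structure(out, class = "gg_taxon_congruence_multi")
}
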