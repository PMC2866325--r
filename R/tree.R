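# Tree I/O and subsetting. Trees are ape "phylo" objects; polytomies are
# allowed and branch lengths are never read by any scoring function.

#' Read trees from a Newick file
#'
#' A file may contain several trees (for example a set of equally
#' parsimonious cladograms), one per line or semicolon-separated. Trees are
#' scored as read: a basal trifurcation is kept as a rooted basal polytomy.
#' An optional outgroup reroots each tree on that leaf's pendant edge.
#'
#' @param path path to a Newick file.
#' @param outgroup optional leaf label; when given, every tree is rerooted
#'   on the pendant edge of that leaf.
#' @return a list of `phylo` objects.
#' @export
read_trees <- function(path, outgroup = NULL) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  trees <- ape::read.tree(path)
  if (is.null(trees)) stop("no trees could be parsed from ", path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(unclass(trees), validate_tree)
  if (!is.null(outgroup)) {
    trees <- lapply(trees, function(tr) {
      if (!outgroup %in% tr$tip.label) {
        stop("outgroup '", outgroup, "' is not a leaf of the tree")
      }
      ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
    })
  }
  trees
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  tree$tip.label <- trimws(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  tab <- tabulate(tree$edge[, 1])
  internal <- (length(tree$tip.label) + 1L):(length(tree$tip.label) + tree$Nnode)
  if (any(tab[internal] < 2L)) stop("internal node with fewer than 2 children")
  tree
}

#' Write trees to a Newick file
#'
#' @param trees a `phylo` or list of `phylo`.
#' @param path output path; one tree per line.
#' @return `path`, invisibly.
#' @export
write_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  writeLines(vapply(trees, ape::write.tree, character(1)), path)
  invisible(path)
}

#' Restrict an alignment and tree to a set of terminals
#'
#' The sub-alignment keeps all columns; the induced subtree has any
#' degree-2 internal nodes created by leaf removal suppressed. Used for
#' per-taxon measurement of utility and congruence.
#'
#' @param aln a `gg_alignment`, or `NULL`.
#' @param tree a `phylo`, or `NULL`.
#' @param ids terminal identifiers to keep (non-empty subset).
#' @return a list with elements `alignment` and `tree` (either may be
#'   `NULL` if the corresponding input was `NULL`).
#' @export
restrict_data <- function(aln = NULL, tree = NULL, ids) {
  ids <- unique(trimws(ids))
  if (length(ids) == 0L) stop("empty terminal set")
  out <- list(alignment = NULL, tree = NULL)
  if (!is.null(aln)) {
    missing <- setdiff(ids, rownames(aln))
    if (length(missing)) {
      stop("terminals absent from alignment: ", paste(missing, collapse = ", "))
    }
    sub <- aln[ids, , drop = FALSE]
    class(sub) <- class(aln)
    out$alignment <- sub
  }
  if (!is.null(tree)) {
    missing <- setdiff(ids, tree$tip.label)
    if (length(missing)) {
      stop("terminals absent from tree: ", paste(missing, collapse = ", "))
    }
    out$tree <- if (length(ids) == length(tree$tip.label)) tree
                else ape::keep.tip(tree, ids)
  }
  out
}

# Per-node sets of descendant leaf indices, as a logical matrix
# (rows = nodes in 1..(Ntip+Nnode), cols = tips). Root included.
leaf_descendants <- function(tree) {
  n <- length(tree$tip.label)
  total <- n + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  desc <- matrix(FALSE, total, n)
  desc[cbind(seq_len(n), seq_len(n))] <- TRUE
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]; ch <- tr$edge[i, 2]
    desc[p, ] <- desc[p, ] | desc[ch, ]
  }
  desc
}
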