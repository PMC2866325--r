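# Parsimony step counting and the ensemble character-congruence indices.
#
# Minimum changes on a tree are counted by Fitch's set algorithm at binary
# nodes, generalised to polytomies by Hartigan's frequency rule: at a node
# with children state sets B1..Bd, let k(s) be the number of children whose
# set contains s and K = max_s k(s); the node's set is {s : k(s) = K} and
# d - K changes are added. Polytomies are therefore "soft" (resolvable for
# free). Missing states carry the full state set and never force a change.
# Branch lengths and rootings are never read: the count is invariant under
# rerooting of the same unrooted topology.

#' Minimum state changes of one character on a tree
#'
#' @param tree a `phylo` (polytomies allowed).
#' @param states character or integer vector of leaf states, named by tip
#'   label (or unnamed in `tree$tip.label` order). `NA`, and for character
#'   input any symbol outside `A`,`C`,`G`,`T`,`0`,`1` not listed in
#'   `levels`, is treated as missing.
#' @param levels optional explicit state universe; by default the distinct
#'   non-missing observed states.
#' @return integer count of changes (the tree length contribution s of the
#'   character).
#' @export
steps_on_tree <- function(tree, states, levels = NULL) {
  x <- align_states(tree, states)
  lev <- if (is.null(levels)) sort(unique(x[!is.na(x)])) else as.character(levels)
  if (length(lev) == 0L) stop("all leaf states missing")
  k <- length(lev)
  n <- length(tree$tip.label)
  total <- n + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  sets <- matrix(FALSE, total, k)
  idx <- match(x, lev)
  for (i in seq_len(n)) {
    if (is.na(idx[i])) sets[i, ] <- TRUE else sets[i, idx[i]] <- TRUE
  }
  cost <- 0L
  parents <- unique(tr$edge[, 1])
  for (p in parents) {
    ch <- tr$edge[tr$edge[, 1] == p, 2]
    cnt <- colSums(sets[ch, , drop = FALSE])
    K <- max(cnt)
    cost <- cost + length(ch) - K
    sets[p, ] <- cnt == K
  }
  as.integer(cost)
}

# Normalise a state vector to tree tip order; NA = missing.
align_states <- function(tree, states) {
  tips <- tree$tip.label
  if (!is.null(names(states))) {
    missing <- setdiff(tips, names(states))
    if (length(missing)) {
      stop("no state for leaf: ", paste(missing, collapse = ", "))
    }
    states <- states[tips]
  } else if (length(states) != length(tips)) {
    stop("unnamed state vector must match the number of leaves")
  }
  x <- as.character(states)
  x[x %in% GG_MISSING | x %in% GG_AMBIGUITY] <- NA_character_
  x
}

#' Greatest number of changes of a character on any cladogram
#'
#' Tree-independent: the number of non-missing leaves minus the frequency
#' of the most common state, realised on the star (and on the worst comb)
#' topology.
#'
#' @param states leaf states (missing allowed, ignored).
#' @return integer count g.
#' @export
max_steps <- function(states) {
  x <- as.character(states)
  x[x %in% GG_MISSING | x %in% GG_AMBIGUITY] <- NA_character_
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("all states missing")
  length(x) - max(table(x))
}

#' Per-character step counts (m, s, g) of a matrix on a tree
#'
#' For every variable column: `m` = distinct unambiguous states minus one
#' (minimum on any tree), `s` = minimum changes on the given tree, `g` =
#' greatest changes on any tree. Invariant columns contribute m = s = g = 0
#' and are excluded by default, as is standard for ensemble indices.
#'
#' @param aln a `gg_alignment`.
#' @param tree a `phylo` whose leaves are the alignment terminals.
#' @param include_invariant keep invariant columns in the output (their
#'   zero contributions leave all sums unchanged).
#' @return data frame with columns `column`, `m`, `s`, `g`.
#' @export
character_fits <- function(aln, tree, include_invariant = FALSE) {
  check_leaf_terminals(aln, tree)
  cnt <- column_base_counts(aln)
  k <- colSums(cnt > 0L)
  keep <- if (include_invariant) which(k >= 1L) else which(k >= 2L)
  rows <- lapply(keep, function(j) {
    col <- aln[, j]
    s <- if (k[j] >= 2L) steps_on_tree(tree, stats::setNames(col, rownames(aln)))
         else 0L
    nonmiss <- sum(cnt[, j])
    data.frame(column = j, m = k[j] - 1L, s = s,
               g = nonmiss - max(cnt[, j]))
  })
  if (length(rows) == 0L) {
    return(data.frame(column = integer(0), m = integer(0), s = integer(0),
                      g = integer(0)))
  }
  do.call(rbind, rows)
}

check_leaf_terminals <- function(aln, tree) {
  if (!setequal(tree$tip.label, rownames(aln))) {
    stop("tree leaves and alignment terminals differ")
  }
}

#' Ensemble congruence scores of a matrix on a tree
#'
#' Sums the per-character fits into the tree length S, the minimum M and
#' maximum G, and the ensemble consistency index CI = M/S and retention
#' index RI = (G-S)/(G-M). CI is `NA` when S = 0; RI is `NA` when G = M
#' (no potential synapomorphy).
#'
#' @inheritParams character_fits
#' @return one-row data frame with `S`, `M`, `G`, `CI`, `RI`,
#'   `n_characters`.
#' @export
congruence_scores <- function(aln, tree, include_invariant = FALSE) {
  fits <- character_fits(aln, tree, include_invariant = include_invariant)
  S <- sum(fits$s); M <- sum(fits$m); G <- sum(fits$g)
  data.frame(
    S = S, M = M, G = G,
    CI = if (S > 0L) M / S else NA_real_,
    RI = if (G > M) (G - S) / (G - M) else NA_real_,
    n_characters = nrow(fits)
  )
}

#' Ensemble consistency index CI = M/S
#' @inheritParams character_fits
#' @return ratio in `(0, 1]`, or `NA` when the matrix has no steps on the
#'   tree.
#' @export
ensemble_ci <- function(aln, tree) congruence_scores(aln, tree)$CI

#' Ensemble retention index RI = (G-S)/(G-M)
#' @inheritParams character_fits
#' @return ratio in `[0, 1]`, or `NA` when G = M.
#' @export
ensemble_ri <- function(aln, tree) congruence_scores(aln, tree)$RI

#' Per-taxon congruence profile at one rank
#'
#' For each group at the rank with at least `min_species` members, CI and
#' RI are computed on the row-restricted matrix scored on the induced
#' subtree of `tree` (degree-2 nodes suppressed), plus an unweighted mean
#' row over groups with defined values.
#'
#' @param aln a `gg_alignment`.
#' @param tree a `phylo` over the alignment terminals.
#' @param tax taxonomy data frame.
#' @param rank rank name.
#' @param min_species smallest group size scored (default 3).
#' @return data frame: `rank`, `group`, `n_species`, `S`, `M`, `G`, `CI`,
#'   `RI`, plus a `<mean>` row.
#' @export
congruence_profile <- function(aln, tree, tax, rank, min_species = 3L) {
  check_leaf_terminals(aln, tree)
  groups <- concordance_groups(tax, rank, rownames(aln),
                               min_size = min_species)
  if (length(groups) == 0L) {
    warning("no group at rank '", rank, "' with >= ", min_species,
            " species; empty summary")
    return(data.frame(rank = character(0), group = character(0),
                      n_species = integer(0), S = integer(0), M = integer(0),
                      G = integer(0), CI = numeric(0), RI = numeric(0)))
  }
  rows <- lapply(names(groups), function(g) {
    sub <- restrict_data(aln, tree, groups[[g]])
    sc <- congruence_scores(sub$alignment, sub$tree)
    data.frame(rank = rank, group = g, n_species = length(groups[[g]]),
               S = sc$S, M = sc$M, G = sc$G, CI = sc$CI, RI = sc$RI)
  })
  out <- do.call(rbind, rows)
  mean_row <- data.frame(rank = rank, group = "<mean>",
                         n_species = NA_integer_, S = NA_integer_,
                         M = NA_integer_, G = NA_integer_,
                         CI = mean(out$CI, na.rm = TRUE),
                         RI = mean(out$RI, na.rm = TRUE))
  rbind(out, mean_row)
}

#' Exhaustive minimum steps over all unrooted binary topologies
#'
#' Enumerates every unrooted binary topology on the character's leaves
#' (up to 8, i.e. at most 10395 trees) and minimises [steps_on_tree()]. A
#' small exhaustive stand-in for heuristic tree search, intended for
#' validation on toy instances.
#'
#' @param states named leaf state vector (>= 3 non-missing leaves).
#' @return list with `min_steps` and `best_trees` (the achieving
#'   topologies, a `multiPhylo`).
#' @export
exhaustive_min_steps <- function(states) {
  tips <- names(states)
  if (is.null(tips)) stop("states must be named by leaf")
  n <- length(tips)
  if (n > 8L) stop("exhaustive search limited to 8 leaves")
  if (n < 3L) stop("need at least 3 leaves")
  topos <- phangorn::allTrees(n, rooted = FALSE, tip.label = tips)
  steps <- vapply(topos, function(tr) steps_on_tree(tr, states), integer(1))
  best <- min(steps)
  list(min_steps = best, best_trees = topos[steps == best])
}
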