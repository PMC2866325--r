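# Matrix-intrinsic "phylogenetic utility" statistics, measured before any
# tree inference. Ambiguity codes, gaps and missing codes never count as
# states nor as mismatches, which keeps A, V, PI, M and p mutually
# consistent.

#' Aligned length A
#'
#' Number of columns in the aligned matrix.
#' @param aln a `gg_alignment`.
#' @return integer count.
#' @export
aligned_length <- function(aln) ncol(aln)

# Frequency table of unambiguous bases per column (4 x A integer matrix).
column_base_counts <- function(aln) {
  apply(aln, 2, function(col) {
    tabulate(match(col, GG_UNAMBIGUOUS), nbins = 4L)
  })
}

#' Number of variable columns V
#'
#' Columns with at least two distinct unambiguous states among non-missing
#' cells (A excluding invariant characters).
#' @param aln a `gg_alignment`.
#' @return integer count.
#' @export
count_variable <- function(aln) {
  cnt <- column_base_counts(aln)
  sum(colSums(cnt > 0L) >= 2L)
}

#' Number of parsimony-informative columns PI
#'
#' Columns with at least two unambiguous states each present in at least
#' two terminals (V excluding autapomorphies).
#' @param aln a `gg_alignment`.
#' @return integer count.
#' @export
count_parsimony_informative <- function(aln) {
  cnt <- column_base_counts(aln)
  sum(colSums(cnt >= 2L) >= 2L)
}

#' Minimum number of character-state changes M
#'
#' The tree-independent lower bound on parsimony steps: over columns, the
#' number of distinct unambiguous states minus one.
#' @param aln a `gg_alignment`.
#' @return integer count.
#' @export
min_changes <- function(aln) {
  cnt <- column_base_counts(aln)
  sum(pmax(0L, colSums(cnt > 0L) - 1L))
}

#' Mean uncorrected p-distance
#'
#' Mean over all unordered terminal pairs of the proportion of differing
#' sites, comparing only positions where both cells hold an unambiguous
#' base (pairwise deletion). Pairs with no comparable site are excluded
#' with a warning.
#'
#' @param aln a `gg_alignment` with at least two terminals.
#' @return proportion in `[0, 1]`.
#' @export
mean_p_distance <- function(aln) {
  n <- nrow(aln)
  if (n < 2L) stop("p-distance needs at least two terminals")
  ok <- is_unambiguous(aln)
  dim(ok) <- dim(aln)
  vals <- numeric(0)
  dropped <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0L) {
        dropped <- dropped + 1L
      } else {
        vals <- c(vals, sum(aln[i, comp] != aln[j, comp]) / nc)
      }
    }
  }
  if (dropped > 0L) {
    warning(dropped, " pair(s) with no comparable sites excluded")
  }
  if (length(vals) == 0L) stop("no terminal pair has comparable sites")
  mean(vals)
}

#' Full utility score set for one matrix
#'
#' @param aln a `gg_alignment`.
#' @return a one-row data frame with columns `A`, `V`, `PI`, `M`,
#'   `n_terminals`, `char_taxon_ratio`, `p_mean` and the proportions
#'   `V_prop`, `PI_prop`, `M_prop` (relative to A).
#' @export
utility_scores <- function(aln) {
  A <- aligned_length(aln)
  V <- count_variable(aln)
  PI <- count_parsimony_informative(aln)
  M <- min_changes(aln)
  n <- nrow(aln)
  data.frame(
    A = A, V = V, PI = PI, M = M, n_terminals = n,
    char_taxon_ratio = A / n,
    p_mean = if (n >= 2L) mean_p_distance(aln) else NA_real_,
    V_prop = V / A, PI_prop = PI / A, M_prop = M / A
  )
}

#' Per-taxon utility profile at one rank
#'
#' For each group at the rank with at least `min_species` members, V, PI
#' and M are computed on the row-restricted sub-matrix; proportions are
#' relative to the global aligned length A (A is a property of the full
#' matrix and is not recomputed per group). The per-rank summary row is
#' the unweighted mean of the group proportions.
#'
#' @param aln a `gg_alignment`.
#' @param tax taxonomy data frame covering the alignment terminals.
#' @param rank rank name.
#' @param min_species smallest group size measured (default 3: taxa
#'   represented by three or more species).
#' @return data frame with one row per group plus a `mean` row (`group`
#'   column `"<mean>"`); columns `rank`, `group`, `n_species`, `V`, `PI`,
#'   `M`, `V_prop`, `PI_prop`, `M_prop`, `p_mean`.
#' @export
utility_profile <- function(aln, tax, rank, min_species = 3L) {
  A <- aligned_length(aln)
  groups <- concordance_groups(tax, rank, rownames(aln),
                               min_size = min_species)
  if (length(groups) == 0L) {
    warning("no group at rank '", rank, "' with >= ", min_species,
            " species; empty summary")
    return(empty_profile())
  }
  rows <- lapply(names(groups), function(g) {
    sub <- restrict_data(aln = aln, ids = groups[[g]])$alignment
    p <- tryCatch(mean_p_distance(sub), error = function(e) NA_real_)
    data.frame(rank = rank, group = g, n_species = nrow(sub),
               V = count_variable(sub),
               PI = count_parsimony_informative(sub),
               M = min_changes(sub),
               V_prop = count_variable(sub) / A,
               PI_prop = count_parsimony_informative(sub) / A,
               M_prop = min_changes(sub) / A,
               p_mean = p)
  })
  out <- do.call(rbind, rows)
  mean_row <- data.frame(
    rank = rank, group = "<mean>", n_species = NA_integer_,
    V = NA_integer_, PI = NA_integer_, M = NA_integer_,
    V_prop = mean(out$V_prop), PI_prop = mean(out$PI_prop),
    M_prop = mean(out$M_prop),
    p_mean = mean(out$p_mean, na.rm = TRUE)
  )
  rbind(out, mean_row)
}

empty_profile <- function() {
  data.frame(rank = character(0), group = character(0),
             n_species = integer(0), V = integer(0), PI = integer(0),
             M = integer(0), V_prop = numeric(0), PI_prop = numeric(0),
             M_prop = numeric(0), p_mean = numeric(0))
}
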