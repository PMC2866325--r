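# Rank-structured censuses and per-gene score tables, and the side-by-side
# comparison of several gene regions over a shared taxonomy.

#' Taxonomic census of a terminal set
#'
#' For each rank: the number of taxa, the number of concordance groups
#' (taxa containing more than one species) and the number of taxa with
#' more than two species (those entering the per-taxon measurements).
#'
#' @param tax taxonomy data frame.
#' @param terminals terminal ids (default all in `tax`).
#' @param ranks rank names (default the taxonomy's rank columns).
#' @return data frame: `rank`, `n_taxa`, `n_with_gt1`, `n_with_gt2`.
#' @export
rank_census <- function(tax, terminals = tax$terminal,
                        ranks = setdiff(names(tax), "terminal")) {
  rows <- lapply(ranks, function(r) {
    sizes <- lengths(suppressWarnings(
      concordance_groups(tax, r, terminals, min_size = 1L)))
    data.frame(rank = r, n_taxa = length(sizes),
               n_with_gt1 = sum(sizes > 1L),
               n_with_gt2 = sum(sizes > 2L))
  })
  do.call(rbind, rows)
}

#' Full report for one gene region
#'
#' Bundles, per rank: the per-taxon utility profile, the per-taxon
#' character-congruence (CI/RI) profile, and the taxonomic-congruence
#' scores of the rank's concordance groups on the tree(s). Undefined
#' ratios are reported as `NA`, never as zero.
#'
#' @param name gene region label.
#' @param aln a `gg_alignment`.
#' @param trees a `phylo` or list of `phylo` over the same terminals.
#' @param tax taxonomy data frame.
#' @param ranks rank names to analyse.
#' @param min_species smallest group measured per taxon (default 3).
#' @param signal_min_size smallest group used as a concordance group for
#'   PMT/TCI/TRI (default `min_species`).
#' @param rooted monophyly convention, see [clade_count()].
#' @return list of class `gg_gene_report` with elements `name`, `census`,
#'   `utility` (full-matrix scores), `utility_by_rank`,
#'   `congruence_by_rank`, `signal_by_rank` (one row per rank: mean
#'   PMT/TCI/TRI across trees).
#' @export
gene_report <- function(name, aln, trees, tax, ranks = GG_RANKS,
                        min_species = 3L, signal_min_size = min_species,
                        rooted = TRUE) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  lapply(trees, function(tr) check_leaf_terminals(aln, tr))
  utility_by_rank <- do.call(rbind, lapply(ranks, function(r) {
    utility_profile(aln, tax, r, min_species = min_species)
  }))
  congruence_by_rank <- do.call(rbind, lapply(ranks, function(r) {
    congruence_profile(aln, trees[[1]], tax, r, min_species = min_species)
  }))
  signal_by_rank <- do.call(rbind, lapply(ranks, function(r) {
    groups <- suppressWarnings(
      build_membership_matrix(tax, r, rownames(aln),
                              min_size = signal_min_size))
    if (ncol(groups) == 0L) {
      return(data.frame(rank = r, M_t = 0L, PMT = NA_real_,
                        TCI = NA_real_, TRI = NA_real_))
    }
    multi <- taxon_congruence_multi(trees, groups, rooted = rooted)
    mean_row <- multi$summary[multi$summary$stat == "mean", ]
    data.frame(rank = r, M_t = ncol(groups), PMT = mean_row$PMT,
               TCI = mean_row$TCI, TRI = mean_row$TRI)
  }))
  structure(list(
    name = name,
    census = rank_census(tax, rownames(aln), ranks),
    utility = utility_scores(aln),
    utility_by_rank = utility_by_rank,
    congruence_by_rank = congruence_by_rank,
    signal_by_rank = signal_by_rank
  ), class = "gg_gene_report")
}

#' @export
print.gg_gene_report <- function(x, ...) {
  cat("Gene report:", x$name, "\n")
  cat(" terminals:", x$utility$n_terminals, " A:", x$utility$A, "\n")
  print(x$signal_by_rank)
  invisible(x)
}

# Mean (summary) rows of a per-rank profile, wide by measure.
profile_means <- function(profile, measures) {
  means <- profile[profile$group == "<mean>", c("rank", measures)]
  rownames(means) <- NULL
  means
}

#' Compare several gene regions
#'
#' Builds a side-by-side table of the per-rank mean measures of each gene
#' and a dense ranking of the genes per (rank, measure); higher values
#' rank first and ties share a rank. Missing measures stay missing and are
#' flagged with rank `NA`.
#'
#' @param reports list of `gg_gene_report` over a shared taxonomy (the
#'   rank sets must match).
#' @return list of class `gg_gene_comparison` with `values` (long data
#'   frame: `rank`, `measure`, one column per gene) and `ranking` (same
#'   shape, dense ranks).
#' @export
compare_genes <- function(reports) {
  if (length(reports) < 2L) stop("need at least two gene reports")
  names_ <- vapply(reports, `[[`, character(1), "name")
  if (anyDuplicated(names_)) stop("gene report names must be unique")
  rank_sets <- lapply(reports, function(r) r$signal_by_rank$rank)
  if (!all(vapply(rank_sets, identical, logical(1), y = rank_sets[[1]]))) {
    stop("gene reports cover different rank sets")
  }
  ranks <- rank_sets[[1]]
  per_gene <- lapply(reports, function(r) {
    u <- profile_means(r$utility_by_rank, c("V_prop", "PI_prop", "M_prop"))
    cg <- profile_means(r$congruence_by_rank, c("CI", "RI"))
    sig <- r$signal_by_rank[, c("rank", "PMT", "TCI", "TRI")]
    m <- merge(merge(u, cg, by = "rank", all = TRUE), sig, by = "rank",
               all = TRUE)
    m[match(ranks, m$rank), ]
  })
  measures <- c("V_prop", "PI_prop", "M_prop", "CI", "RI",
                "PMT", "TCI", "TRI")
  values <- do.call(rbind, lapply(ranks, function(rk) {
    do.call(rbind, lapply(measures, function(ms) {
      vals <- vapply(per_gene, function(g) g[g$rank == rk, ms][1],
                     numeric(1))
      out <- data.frame(rank = rk, measure = ms)
      out[names_] <- as.list(vals)
      out
    }))
  }))
  ranking <- values
  for (i in seq_len(nrow(ranking))) {
    v <- as.numeric(ranking[i, names_])
    ranking[i, names_] <- as.list(dense_rank_desc(v))
  }
  structure(list(values = values, ranking = ranking),
            class = "gg_gene_comparison")
}

# Dense descending ranks; NA stays NA and shares no rank.
dense_rank_desc <- function(v) {
  out <- rep(NA_real_, length(v))
  ok <- !is.na(v)
  if (any(ok)) {
    u <- sort(unique(v[ok]), decreasing = TRUE)
    out[ok] <- match(v[ok], u)
  }
  out
}
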