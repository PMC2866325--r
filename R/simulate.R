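# Synthetic (alignment, tree, taxonomy) bundles with recorded ground
# truth. The generator emulates the structure of a multi-rank molecular
# datamatrix: a Yule tree, sequences evolved under JC69 or K2P with
# optional gamma rate heterogeneity and missing data, and a nested
# taxonomy obtained by cutting the tree at increasing node-age quantiles
# so that, before perturbation, every named group is a clade of the
# generating tree.

GG_BASES <- c("A", "C", "G", "T")
# transition partners in A,C,G,T order: A<->G, C<->T
GG_TS_PARTNER <- c(3L, 4L, 1L, 2L)

#' Scenario configuration for the synthetic-data generator
#'
#' Defaults describe a desk-scale analogue of a multi-rank barcode
#' matrix: 64 species, 658 aligned sites (the COI barcode length), a Yule
#' tree of unit birth rate, and a substitution rate of 0.015 per site per
#' unit time, which places the matrix in the moderate-divergence regime
#' (roughly a third to a half of sites parsimony-informative). Rank
#' depths are node-age quantiles of the generating tree; higher values
#' cut deeper and give fewer, larger groups.
#'
#' @param n_species number of terminals (>= 4).
#' @param seq_length aligned sites.
#' @param birth_rate Yule speciation rate (events per unit time).
#' @param subst_model `"JC69"` or `"K2P"`.
#' @param subst_rate expected substitutions per site per unit time.
#' @param kappa transition/transversion rate ratio (K2P; ignored for
#'   JC69).
#' @param gamma_shape shape of the per-site gamma rate multipliers (mean
#'   1), or `NULL` for uniform rates.
#' @param rank_depths named, strictly increasing node-age quantiles in
#'   (0, 1) for `genus`, `subfamily`, `family`, `superfamily`.
#' @param perturb_fraction proportion of tips whose taxonomy rows are
#'   swapped pairwise between distinct genera.
#' @param missing_fraction proportion of alignment cells masked to `N`.
#' @param homoplasy_free evolve each column by exactly one change on one
#'   branch (unique derived state), so that the matrix is free of
#'   homoplasy on the generating tree.
#' @param seed integer seed driving all randomness of the scenario.
#' @return list of class `gg_scenario_config`.
#' @export
scenario_config <- function(n_species = 64L, seq_length = 658L,
                            birth_rate = 1, subst_model = c("JC69", "K2P"),
                            subst_rate = 0.015, kappa = 2,
                            gamma_shape = NULL,
                            rank_depths = c(genus = 0.75, subfamily = 0.88,
                                            family = 0.95,
                                            superfamily = 0.98),
                            perturb_fraction = 0, missing_fraction = 0,
                            homoplasy_free = FALSE, seed = 1L) {
  subst_model <- match.arg(subst_model)
  stopifnot(n_species >= 4L, seq_length >= 1L, birth_rate > 0,
            subst_rate >= 0, perturb_fraction >= 0, perturb_fraction <= 1,
            missing_fraction >= 0, missing_fraction <= 1)
  if (is.null(names(rank_depths)) || any(diff(rank_depths) <= 0)) {
    stop("rank_depths must be named and strictly increasing")
  }
  if (any(rank_depths <= 0) || any(rank_depths >= 1)) {
    stop("rank_depths must lie strictly inside (0, 1)")
  }
  structure(list(
    n_species = as.integer(n_species), seq_length = as.integer(seq_length),
    birth_rate = birth_rate, subst_model = subst_model,
    subst_rate = subst_rate, kappa = kappa, gamma_shape = gamma_shape,
    rank_depths = rank_depths, perturb_fraction = perturb_fraction,
    missing_fraction = missing_fraction, homoplasy_free = homoplasy_free,
    seed = as.integer(seed)
  ), class = "gg_scenario_config")
}

#' Simulate a Yule tree
#'
#' Pure-birth tree with `n_species` extant leaves and ultrametric branch
#' lengths (node heights drive the clade-based taxonomy assignment).
#'
#' @param n_species leaf count.
#' @param birth_rate speciation rate.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return a `phylo` with tip labels `t001`, `t002`, ...
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("t%03d", seq_len(n_species))
  tree
}

#' Evolve an alignment along a tree
#'
#' The root sequence is uniform over the four bases; each branch places a
#' Poisson number of substitution events per site (expected
#' `subst_rate * branch length * site rate`), each event jumping to a
#' different base. Under K2P a jump is a transition with probability
#' `kappa/(kappa + 2)` and each transversion with probability
#' `1/(kappa + 2)`; JC69 is the `kappa = 1` case. In homoplasy-free mode
#' each column instead changes exactly once, on one uniformly chosen
#' branch, to a distinct derived state. The truth record counts every
#' realised event per column, so observed event counts are an upper bound
#' on the parsimony steps of the column on the generating tree.
#'
#' @param tree a `phylo` with branch lengths.
#' @param seq_length number of sites.
#' @param subst_rate substitutions per site per unit branch length.
#' @param subst_model `"JC69"` or `"K2P"`.
#' @param kappa transition/transversion rate ratio for K2P.
#' @param gamma_shape gamma shape for per-site rate multipliers, or
#'   `NULL`.
#' @param missing_fraction proportion of cells masked to `N` uniformly at
#'   random.
#' @param block_missing optional `list(terminal_fraction=, column_fraction=)`
#'   masking one contiguous column block for a random subset of
#'   terminals (emulates a gene fragment never sequenced for part of the
#'   taxa).
#' @param homoplasy_free see [scenario_config()].
#' @param seed optional seed.
#' @return list with `alignment` (a `gg_alignment`, after masking),
#'   `events` (integer vector, realised substitution events per column)
#'   and `unmasked` (the alignment before masking).
#' @export
evolve_alignment <- function(tree, seq_length, subst_rate = 0.015,
                             subst_model = c("JC69", "K2P"), kappa = 2,
                             gamma_shape = NULL, missing_fraction = 0,
                             block_missing = NULL, homoplasy_free = FALSE,
                             seed = NULL) {
  subst_model <- match.arg(subst_model)
  if (seq_length < 1L) stop("alignment must have at least one column")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  L <- as.integer(seq_length)
  kap <- if (subst_model == "JC69") 1 else kappa
  tr <- ape::reorder.phylo(tree, "postorder")
  states <- matrix(0L, n + tree$Nnode, L)
  events <- integer(L)
  states[n + 1L, ] <- sample.int(4L, L, replace = TRUE)
  if (homoplasy_free) {
    edge_of <- sample.int(nrow(tr$edge), L, replace = TRUE)
    derived <- (states[n + 1L, ] + sample.int(3L, L, replace = TRUE) - 1L) %% 4L + 1L
    events[] <- 1L
    for (i in rev(seq_len(nrow(tr$edge)))) {
      p <- tr$edge[i, 1]; ch <- tr$edge[i, 2]
      states[ch, ] <- states[p, ]
      hit <- which(edge_of == i)
      if (length(hit)) states[ch, hit] <- derived[hit]
    }
  } else {
    rates <- if (is.null(gamma_shape)) rep(1, L)
             else stats::rgamma(L, shape = gamma_shape, rate = gamma_shape)
    for (i in rev(seq_len(nrow(tr$edge)))) {
      p <- tr$edge[i, 1]; ch <- tr$edge[i, 2]
      elen <- tr$edge.length[i]
      s <- states[p, ]
      nev <- stats::rpois(L, subst_rate * elen * rates)
      for (j in which(nev > 0L)) {
        for (e in seq_len(nev[j])) s[j] <- jump_base(s[j], kap)
        events[j] <- events[j] + nev[j]
      }
      states[ch, ] <- s
    }
  }
  m <- matrix(GG_BASES[states[seq_len(n), ]], n, L,
              dimnames = list(tree$tip.label, NULL))
  unmasked <- as_alignment(m)
  if (!is.null(block_missing)) {
    n_tax <- max(1L, round(block_missing$terminal_fraction * n))
    n_col <- max(1L, round(block_missing$column_fraction * L))
    taxa <- sample.int(n, n_tax)
    start <- sample.int(L - n_col + 1L, 1L)
    m[taxa, start:(start + n_col - 1L)] <- "N"
  }
  if (missing_fraction > 0) {
    mask <- which(stats::runif(length(m)) < missing_fraction)
    m[mask] <- "N"
  }
  list(alignment = as_alignment(m), events = events, unmasked = unmasked)
}

# One substitution event: transition with prob kappa/(kappa+2), otherwise
# one of the two transversions.
jump_base <- function(s, kappa) {
  if (stats::runif(1) < kappa / (kappa + 2)) {
    GG_TS_PARTNER[s]
  } else {
    tv <- setdiff(1:4, c(s, GG_TS_PARTNER[s]))
    tv[sample.int(2L, 1L)]
  }
}

#' Assign a nested clade-based taxonomy from a tree
#'
#' Cuts the (ultrametric) tree at the node-age quantile of each rank; the
#' leaves of each subtree hanging below a cut form one named group.
#' Deeper cuts give fewer, larger groups, and every group is a clade of
#' the tree, so the taxonomy is perfectly congruent with it by
#' construction.
#'
#' @param tree ultrametric `phylo`.
#' @param rank_depths named strictly increasing quantiles in (0, 1).
#' @return taxonomy data frame (`terminal` + one column per rank).
#' @export
assign_taxonomy <- function(tree, rank_depths = c(genus = 0.75,
                                                  subfamily = 0.88,
                                                  family = 0.95,
                                                  superfamily = 0.98)) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  age <- max(depth[seq_len(n)]) - depth
  internal_ages <- age[(n + 1L):(n + tree$Nnode)]
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  tax <- data.frame(terminal = tree$tip.label)
  below <- leaf_descendants(tree)
  for (r in names(rank_depths)) {
    cut_age <- stats::quantile(internal_ages, rank_depths[[r]], names = FALSE)
    root <- n + 1L
    if (age[root] < cut_age) {
      seeds <- root
    } else {
      seeds <- which(age < cut_age & seq_along(age) != root &
                       age[pmax(parent, 1L)] >= cut_age & parent > 0L)
    }
    if (length(seeds) == 1L && r == names(rank_depths)[1]) {
      warning("cut at rank '", r, "' yields a single group (degenerate)")
    }
    seeds <- seeds[order(apply(below[seeds, , drop = FALSE], 1,
                               function(z) which(z)[1]))]
    labels <- rep(NA_character_, n)
    for (i in seq_along(seeds)) {
      labels[below[seeds[i], ]] <- sprintf("%s_%02d", r, i)
    }
    tax[[r]] <- labels
  }
  tax
}

#' Swap taxonomy labels of a fraction of tips
#'
#' A seeded random sample of `floor(fraction * n)` tips (rounded down to
#' an even count) is paired across distinct genera and each pair swaps
#' its complete taxonomy row (genus and all higher ranks). Swapping, as
#' opposed to relabelling, preserves every group's size, so censuses and
#' Gt bookkeeping are unchanged while congruence degrades.
#'
#' @param tax taxonomy data frame.
#' @param fraction proportion of tips to involve.
#' @param seed optional seed.
#' @return list with `taxonomy` (perturbed data frame) and `perturbed`
#'   (character vector of the tips whose rows changed).
#' @export
perturb_taxonomy <- function(tax, fraction, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(tax)
  k <- floor(fraction * n)
  if (k %% 2L == 1L) {
    message("perturbation count ", k, " is odd; using ", k - 1L)
    k <- k - 1L
  }
  if (k < 2L) return(list(taxonomy = tax, perturbed = character(0)))
  picked <- sample.int(n, k)
  # order by genus and pair with a half-shift so pairs straddle genera
  genus_col <- setdiff(names(tax), "terminal")[1]
  picked <- picked[order(tax[[genus_col]][picked])]
  first <- picked[seq_len(k / 2L)]
  second <- picked[(k / 2L + 1L):k]
  ranks <- setdiff(names(tax), "terminal")
  swapped <- logical(n)
  for (i in seq_along(first)) {
    a <- first[i]; b <- second[i]
    if (tax[[genus_col]][a] == tax[[genus_col]][b]) next
    tmp <- tax[a, ranks]
    tax[a, ranks] <- tax[b, ranks]
    tax[b, ranks] <- tmp
    swapped[c(a, b)] <- TRUE
  }
  if (sum(swapped) < k) {
    warning(k - sum(swapped), " tip(s) could not be paired across",
            " distinct genera and were left unchanged")
  }
  list(taxonomy = tax, perturbed = tax$terminal[swapped])
}

#' Generate a coherent synthetic scenario
#'
#' Runs the full generator under one seed: tree, alignment, clade-based
#' taxonomy and its perturbed version. With `perturb_fraction = 0` every
#' concordance group is a clade of the generating tree, so PMT, TCI and
#' TRI all equal 1 on it at every rank.
#'
#' @param config a [scenario_config()].
#' @return list of class `gg_scenario` with elements `config`,
#'   `alignment`, `tree`, `taxonomy` and `truth` (generating tree,
#'   unperturbed taxonomy, per-column event counts, unmasked alignment,
#'   perturbed tip list).
#' @export
simulate_scenario <- function(config = scenario_config()) {
  set.seed(config$seed)
  tree <- simulate_tree(config$n_species, config$birth_rate)
  evo <- evolve_alignment(tree, config$seq_length,
                          subst_rate = config$subst_rate,
                          subst_model = config$subst_model,
                          kappa = config$kappa,
                          gamma_shape = config$gamma_shape,
                          missing_fraction = config$missing_fraction,
                          homoplasy_free = config$homoplasy_free)
  tax_true <- assign_taxonomy(tree, config$rank_depths)
  pert <- perturb_taxonomy(tax_true, config$perturb_fraction)
  structure(list(
    config = config,
    alignment = evo$alignment,
    tree = tree,
    taxonomy = pert$taxonomy,
    truth = list(tree = tree, taxonomy = tax_true,
                 column_events = evo$events, unmasked = evo$unmasked,
                 perturbed = pert$perturbed)
  ), class = "gg_scenario")
}

#' Write a scenario bundle to disk
#'
#' Writes `alignment.fasta`, `tree.nwk`, `taxonomy.tsv` and `truth.json`
#' into a directory.
#'
#' @param scenario a `gg_scenario`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_alignment(scenario$alignment, file.path(dir, "alignment.fasta"))
  write_trees(scenario$tree, file.path(dir, "tree.nwk"))
  write_taxonomy(scenario$taxonomy, file.path(dir, "taxonomy.tsv"))
  truth <- list(
    seed = scenario$config$seed,
    newick = ape::write.tree(scenario$truth$tree),
    taxonomy = scenario$truth$taxonomy,
    column_events = scenario$truth$column_events,
    perturbed = scenario$truth$perturbed
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(dir)
}
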