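# Synthetic-data generator: determinism, limit cases, recorded truth.

test_that("scenario generation is byte-deterministic given the seed", {
  cfg <- scenario_config(n_species = 16, seq_length = 60,
                         perturb_fraction = 0.25, missing_fraction = 0.05,
                         seed = 101)
  s1 <- simulate_scenario(cfg)
  s2 <- simulate_scenario(cfg)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_identical(unclass(s1$alignment), unclass(s2$alignment))
  expect_identical(s1$taxonomy, s2$taxonomy)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_scenario(s1, d1); write_scenario(s2, d2)
  for (f in c("alignment.fasta", "tree.nwk", "taxonomy.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("simulated trees have the requested size and shape", {
  tr <- simulate_tree(64, seed = 102)
  expect_equal(length(tr$tip.label), 64)
  expect_equal(tr$Nnode, 63)  # binary
  expect_identical(ape::write.tree(simulate_tree(4, seed = 5)),
                   ape::write.tree(simulate_tree(4, seed = 5)))
})

test_that("zero substitution rate gives an invariant matrix", {
  tr <- simulate_tree(10, seed = 103)
  evo <- evolve_alignment(tr, 50, subst_rate = 0, seed = 103)
  expect_equal(count_variable(evo$alignment), 0)
  expect_true(all(evo$events == 0))
})

test_that("homoplasy-free columns score CI = RI = 1 on the generating tree", {
  tr <- simulate_tree(24, seed = 104)
  evo <- evolve_alignment(tr, 80, homoplasy_free = TRUE, seed = 104)
  expect_true(all(evo$events == 1))
  expect_equal(ensemble_ci(evo$alignment, tr), 1)
  expect_equal(ensemble_ri(evo$alignment, tr), 1)
})

test_that("realised event counts bound the parsimony steps from above", {
  for (s in 1:8) {
    tr <- simulate_tree(12, seed = 200 + s)
    evo <- evolve_alignment(tr, 40, subst_rate = 0.05, seed = 200 + s)
    fits <- character_fits(evo$alignment, tr, include_invariant = TRUE)
    expect_true(all(fits$s <= evo$events[fits$column]))
  }
})

test_that("clade-cut taxonomy is nested and partitions the tips", {
  tree <- simulate_tree(48, seed = 105)
  tax <- assign_taxonomy(tree)
  cen <- rank_census(tax)
  counts <- stats::setNames(cen$n_taxa, cen$rank)
  expect_true(counts["superfamily"] <= counts["family"])
  expect_true(counts["family"] <= counts["subfamily"])
  expect_true(counts["subfamily"] <= counts["genus"])
  for (r in cen$rank) {
    groups <- concordance_groups(tax, r)
    expect_equal(sum(lengths(groups)), 48)
    for (g in groups) expect_true(is_monophyletic(tree, g))
  }
  # ranks nest: each genus lies inside exactly one subfamily
  nested <- tapply(tax$subfamily, tax$genus,
                   function(x) length(unique(x)))
  expect_true(all(nested == 1))
})

test_that("perturbation swaps preserve group sizes and record the tips", {
  tree <- simulate_tree(32, seed = 106)
  tax <- assign_taxonomy(tree)
  id0 <- perturb_taxonomy(tax, 0, seed = 106)
  expect_identical(id0$taxonomy, tax)
  expect_length(id0$perturbed, 0)

  pert <- perturb_taxonomy(tax, 0.5, seed = 106)
  expect_true(length(pert$perturbed) > 0)
  expect_true(length(pert$perturbed) %% 2 == 0)
  for (r in c("genus", "subfamily", "family", "superfamily")) {
    expect_equal(table(pert$taxonomy[[r]]), table(tax[[r]]))
  }
  changed <- tax$terminal[tax$genus != pert$taxonomy$genus]
  expect_setequal(changed, pert$perturbed)

  # an odd swap count is rounded down to even
  expect_message(p9 <- perturb_taxonomy(tax, 9 / 32, seed = 106), "odd")
  expect_lte(length(p9$perturbed), 8)
})

test_that("cross-genus swaps can reach the scenario's minimum PMT", {
  # 4 tips, 2 equal genera. A complete pairing of all four tips across
  # genera merely relabels the two groups, so PMT stays 1; the minimum
  # (PMT = 0, both groups mixed) is reached by swapping one tip pair,
  # i.e. fraction 0.5.
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tax <- data.frame(terminal = c("a", "b", "c", "d"),
                    genus = c("gX", "gX", "gY", "gY"))
  pmt_at <- function(fraction, seeds) {
    sapply(seeds, function(s) {
      pert <- suppressWarnings(perturb_taxonomy(tax, fraction, seed = s))
      taxon_congruence(tr, concordance_groups(pert$taxonomy,
                                              "genus"))$scores$PMT
    })
  }
  expect_true(all(pmt_at(1, 1:10) == 1))
  expect_true(any(pmt_at(0.5, 1:10) == 0))
})

test_that("doubling the substitution rate does not lower expected V or PI", {
  stats_at <- function(rate) {
    vals <- sapply(1:20, function(s) {
      tr <- simulate_tree(16, seed = 300 + s)
      evo <- evolve_alignment(tr, 100, subst_rate = rate, seed = 300 + s)
      c(V = count_variable(evo$alignment),
        PI = count_parsimony_informative(evo$alignment))
    })
    rowMeans(vals)
  }
  lo <- stats_at(0.01); hi <- stats_at(0.02)
  expect_gte(hi["V"], lo["V"])
  expect_gte(hi["PI"], lo["PI"])
})

test_that("K2P jumps favour transitions and gamma rates stay valid", {
  tr <- simulate_tree(16, seed = 107)
  evo <- evolve_alignment(tr, 300, subst_model = "K2P", kappa = 8,
                          gamma_shape = 0.5, subst_rate = 0.02,
                          seed = 107)
  aln <- evo$alignment
  # among segregating 2-state columns, transition pairs should dominate
  pair_type <- apply(unclass(aln), 2, function(col) {
    u <- sort(unique(col[col %in% c("A", "C", "G", "T")]))
    if (length(u) != 2) return(NA_character_)
    if (paste(u, collapse = "") %in% c("AG", "CT")) "ts" else "tv"
  })
  tab <- table(pair_type)
  expect_gt(tab["ts"], tab["tv"])
})

test_that("missing-data masking hits the requested proportion", {
  tr <- simulate_tree(16, seed = 108)
  evo <- evolve_alignment(tr, 200, subst_rate = 0.01,
                          missing_fraction = 0.2, seed = 108)
  frac <- mean(unclass(evo$alignment) == "N")
  expect_gt(frac, 0.15); expect_lt(frac, 0.25)
  expect_true(all(unclass(evo$unmasked) %in% c("A", "C", "G", "T")))

  blk <- evolve_alignment(tr, 200, subst_rate = 0.01,
                          block_missing = list(terminal_fraction = 0.25,
                                               column_fraction = 0.3),
                          seed = 108)
  n_cells <- sum(unclass(blk$alignment) == "N")
  expect_equal(n_cells, 4 * 60)
})
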