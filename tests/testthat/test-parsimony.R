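# Fitch/Hartigan step counting, max steps, and the ensemble indices.

tree4 <- function() ape::read.tree(text = "((a,b),(c,d));")

test_that("step counts on hand-checked characters", {
  tr <- tree4()
  expect_equal(steps_on_tree(tr, c(a = "A", b = "A", c = "A", d = "A")), 0)
  expect_equal(steps_on_tree(tr, c(a = "0", b = "0", c = "1", d = "1")), 1)
  expect_equal(steps_on_tree(tr, c(a = "1", b = "0", c = "1", d = "0")), 2)
  # missing carries the full state set and never forces a change
  expect_equal(steps_on_tree(tr, c(a = "A", b = "N", c = "A", d = "C")), 1)
  expect_error(steps_on_tree(tr, c(a = "N", b = "?", c = "-", d = "N")),
               "missing")
  # polytomies are soft: resolvable for free
  star <- ape::read.tree(text = "(a,b,c,d,e);")
  expect_equal(steps_on_tree(star, c(a = "0", b = "0", c = "1", d = "1",
                                     e = "1")), 2)
})

test_that("Hartigan counts equal exhaustive labeling minimisation", {
  set.seed(61)
  for (i in 1:200) {
    tr <- random_tree(sample(4:7, 1), polytomy_prob = 0.35)
    states <- random_character(tr, n_states = sample(2:4, 1),
                               missing_prob = 0.2)
    expect_equal(steps_on_tree(tr, states), oracle_min_steps(tr, states),
                 info = paste("instance", i))
  }
})

test_that("step counts are invariant under rerooting", {
  set.seed(62)
  for (i in 1:25) {
    tr <- ape::rtree(7)
    states <- random_character(tr, n_states = 3, missing_prob = 0.15)
    s0 <- steps_on_tree(tr, states)
    for (tip in sample(tr$tip.label, 3)) {
      rerooted <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
      expect_equal(steps_on_tree(rerooted, states), s0)
    }
  }
})

test_that("max_steps is the minority count, realised on some topology", {
  expect_equal(max_steps(c("1", "1", "1", "0", "0", "0", "0", "0")), 3)
  expect_equal(max_steps(rep("A", 5)), 0)
  expect_equal(max_steps(c("A", "C", "G", "N", "?")), 2)
  set.seed(63)
  for (i in 1:15) {
    tr <- ape::rtree(6)
    states <- random_character(tr, n_states = sample(2:3, 1))
    topos <- phangorn::allTrees(6, rooted = FALSE,
                                tip.label = tr$tip.label)
    worst <- max(vapply(topos, function(t) steps_on_tree(t, states),
                        integer(1)))
    expect_equal(max_steps(states), worst)
  }
})

test_that("per-character bounds m <= s <= g hold on random instances", {
  set.seed(64)
  for (i in 1:15) {
    tr <- random_tree(8, polytomy_prob = 0.3)
    aln <- random_alignment(8, 25, missing_prob = 0.2)
    rownames(aln) <- tr$tip.label
    fits <- character_fits(aln, tr)
    expect_true(all(fits$m <= fits$s))
    expect_true(all(fits$s <= fits$g))
    expect_true(all(fits$m >= 0))
  }
})

test_that("ensemble CI and RI follow the defining formulas", {
  tr <- tree4()
  # single informative column with members a,c: s=2, m=1, g=1 -> CI=0.5
  aln <- aln_from_columns(list(c("A", "C", "A", "C")),
                          ids = c("a", "b", "c", "d"))
  fits <- character_fits(aln, tr)
  expect_equal(fits$s, 2)
  expect_equal(fits$m, 1)
  expect_equal(ensemble_ci(aln, tr), 0.5)
  expect_equal(ensemble_ri(aln, tr), 0)  # S = G: worst case

  # homoplasy-free columns on the scoring tree: CI = RI = 1
  aln2 <- aln_from_columns(list(c("A", "A", "C", "C"),
                                c("G", "T", "T", "T")),
                           ids = c("a", "b", "c", "d"))
  expect_equal(ensemble_ci(aln2, tr), 1)
  expect_equal(ensemble_ri(aln2, tr), 1)

  # all-invariant matrix: S = 0 and G = M, both indices undefined
  inv <- aln_from_columns(list(rep("A", 4)), ids = c("a", "b", "c", "d"))
  expect_true(is.na(ensemble_ci(inv, tr)))
  expect_true(is.na(ensemble_ri(inv, tr)))

  # invariant columns contribute nothing either way
  aln3 <- aln_from_columns(list(c("A", "C", "A", "C"), rep("G", 4)),
                           ids = c("a", "b", "c", "d"))
  expect_equal(congruence_scores(aln3, tr)$CI,
               congruence_scores(aln3, tr, include_invariant = TRUE)$CI)

  bad <- aln_from_columns(list(rep("A", 4)), ids = c("w", "x", "y", "z"))
  expect_error(ensemble_ci(bad, tr), "differ")
})

test_that("CI and RI agree with direct formulas from oracle counts", {
  set.seed(65)
  for (i in 1:10) {
    tr <- random_tree(6, polytomy_prob = 0.3)
    aln <- random_alignment(6, 12, missing_prob = 0.1)
    rownames(aln) <- tr$tip.label
    ks <- apply(unclass(aln), 2, function(col) {
      tab <- table(col[col %in% c("A", "C", "G", "T")])
      tab
    })
    S <- 0; M <- 0; G <- 0
    for (j in seq_len(ncol(aln))) {
      tab <- table(aln[, j][aln[, j] %in% c("A", "C", "G", "T")])
      if (length(tab) < 2) next
      states <- stats::setNames(unclass(aln)[, j], rownames(aln))
      S <- S + oracle_min_steps(tr, states)
      M <- M + length(tab) - 1
      G <- G + sum(tab) - max(tab)
    }
    sc <- congruence_scores(aln, tr)
    expect_equal(sc$S, S)
    expect_equal(sc$CI, if (S > 0) M / S else NA_real_)
    expect_equal(sc$RI, if (G > M) (G - S) / (G - M) else NA_real_)
  }
})

test_that("ensemble CI does not increase as label-permutation noise grows", {
  set.seed(66)
  levels <- c(0, 0.25, 0.5)
  mean_ci <- sapply(levels, function(f) {
    mean(sapply(1:12, function(s) {
      set.seed(1000 + s)
      tr <- simulate_tree(16)
      evo <- evolve_alignment(tr, 120, subst_rate = 0.03)
      aln <- evo$alignment
      k <- floor(f * 16)
      if (k >= 2) {
        ids <- sample(rownames(aln), k)
        rownames(aln)[match(ids, rownames(aln))] <- ids[c(seq_along(ids)[-1],
                                                          1)]
      }
      ensemble_ci(aln, tr)
    }))
  })
  expect_true(all(diff(mean_ci) <= 1e-9))
})

test_that("exhaustive topology search attains the tree-independent minimum", {
  set.seed(67)
  for (i in 1:8) {
    tr <- ape::rtree(6)
    states <- random_character(tr, n_states = sample(2:4, 1))
    res <- exhaustive_min_steps(states)
    k <- length(unique(states[!is.na(states)]))
    expect_equal(res$min_steps, max(0, k - 1))
    expect_lte(res$min_steps, steps_on_tree(tr, states))
  }
  two <- stats::setNames(c("0", "1", "0", "1", "1"), paste0("t", 1:5))
  expect_equal(exhaustive_min_steps(two)$min_steps, 1)
  expect_error(exhaustive_min_steps(stats::setNames(rep("A", 9),
                                                    paste0("t", 1:9))),
               "8 leaves")
})
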