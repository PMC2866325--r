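---
title: "Scoring gene regions: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring gene regions: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genegauge)
```

## The problem

Sequencing budgets force a choice among candidate gene regions, and the
qualities that make a region attractive do not coincide. A region can be
variable yet phylogenetically misleading; it can recover genera cleanly
and still scramble families. `genegauge` separates two measurable
categories and structures both by taxonomic rank, so that the temporal
range over which a region is informative becomes visible:

* **utility** — what the aligned matrix offers before any analysis;
* **signal** — how well trees inferred from the matrix agree with the
  current classification, and how internally consistent the characters
  are on those trees.

## Utility statistics

For an aligned matrix with $A$ columns over $G^t$ terminals the package
reports $A$, the variable-column count $V$, the parsimony-informative
count $PI$ (columns with at least two unambiguous states each in at
least two terminals), the minimum number of state changes
$M = \sum_c \max(0, k_c - 1)$ with $k_c$ the number of distinct
unambiguous states in column $c$, the character–taxon ratio $A/G^t$, and
the mean uncorrected p-distance over all unordered terminal pairs with
pairwise deletion. The chain $PI \le V \le M \le 3A$ holds on every
matrix and is enforced by property tests.

Two conventions matter and are applied uniformly:

* **Missing and ambiguous symbols.** IUPAC ambiguity codes, `-`, `N` and
  `?` are all treated as missing by every statistic: they never
  contribute a state to $V$, $PI$ or $M$, never enter a p-distance
  comparison, and carry the full state set in parsimony optimization.
  This is the stricter of the defensible choices; counting partial
  matches for ambiguity codes would raise $V$ and $PI$ slightly and make
  them inconsistent with the step-count statistics.
* **Per-taxon aggregation.** Statistics are measured within each taxon
  represented by `min_species` or more terminals (default 3) and
  averaged *unweighted* across taxa at each rank. Pooling terminals
  before averaging would weight large genera more and is a different
  statistic. Proportions always use the global $A$, not a per-group
  column count, so values are comparable across groups and ranks.

## Parsimony engine

The minimum number of changes of a character on a tree is computed by
Fitch's set dynamic program, generalised to multifurcations with
Hartigan's frequency rule: at a node whose children carry optimal state
sets $B_1 \dots B_d$, let $k(s)$ be the number of children whose set
contains $s$ and $K = \max_s k(s)$; the node's set is
$\{s : k(s) = K\}$ and $d - K$ changes are added. For binary nodes this
reduces to the familiar intersection/union rule. Consequences of this
choice:

* polytomies are **soft** — a polytomy can be resolved at no cost, the
  default behaviour of standard parsimony software;
* missing leaves start with the full state set and never force a change;
* counts are invariant under rerooting, so the rooting convention of the
  input Newick never affects $S$, CI or RI;
* only counts are returned; ancestral reconstructions and ties among
  them are irrelevant to every index in the package.

The engine is validated against an exhaustive minimizer that enumerates
every assignment of states to internal nodes on a thousand random
instances (trees of up to 7 leaves with polytomies, up to 4 states,
missing data), and `max_steps` — the greatest change count on any
cladogram, `non-missing leaves − modal state frequency` — against the
maximum of the engine over all 105 unrooted topologies on six leaves.

Ensemble CI and RI sum the per-character $m$, $s$, $g$ over variable
columns. Invariant columns contribute $0$ to each sum, so including them
(`include_invariant = TRUE`) changes nothing numerically; the flag
exists to make the census explicit. CI is undefined (reported `NA`) when
$S = 0$, RI when $G = M$; undefined values propagate as `NA`, never as
zeros.

## Taxonomic congruence

Each named taxon at a rank becomes a *concordance group*, encoded as a
binary membership character. On a tree the group exhibits a minimum
number of clades $s_t$; summing over the $M^t$ test groups gives $S^t$,
and with $G^t$ terminals:

$$\mathrm{PMT} = \frac{\#\{\text{monophyletic}\}}{M^t}, \qquad
  \mathrm{TCI} = \frac{M^t}{S^t}, \qquad
  \mathrm{TRI} = \frac{G^t - S^t}{G^t - M^t}.$$

All three equal 1 exactly when every group is a clade, and TCI = 1,
TRI = 1 and PMT = 1 are equivalent; TCI and PMT are otherwise not
ordered relative to one another.

**Counting clades under the rooted convention.** `clade_count` returns
the number of *maximal member-only clades* — the unique decomposition of
the group into fewest disjoint clades of the rooted tree. This equals
optimizing the membership character with the root held in the non-member
state, and it satisfies two identities that anchor the other
definitions: $s_t = 1$ iff the group is monophyletic (a node's exact
leaf set equals the member set), and $s_t$ equals the brute-force
minimum member-only clade cover, which the test suite verifies by
enumeration on 500 random instances. A plain (unconstrained) Fitch count
of the membership character would differ exactly when the group's
complement forms a clade: the unrooted optimization may place the
derived state on the complement side, so a paraphyletic "all but one
subtree" group would count as a single clan. That unrooted convention is
available via `rooted = FALSE` for users who prefer clan-based scoring
of unrooted trees, but rooted scoring is the default because concordance
groups are statements about rooted monophyly. The degenerate
group-of-all-leaves counts as one clade (the root), never zero.

$G^t$ is the number of terminals of the scored tree, not the summed
group sizes; the two coincide when the rank's groups partition the
terminals. Groups at different ranks are scored independently — nesting
is read from the taxonomy table, never assumed. With several equally
parsimonious input trees the default report is the across-tree mean,
with per-tree values retained; a strict-consensus score is optional and
can only be as good as the best component tree.

## Synthetic scenarios

The generator produces coherent bundles whose ground truth is known, so
every index can be tested without external data.

* **Tree**: pure-birth (Yule) with `birth_rate` 1 and `n_species` 64 by
  default. Birth–death shape realism is not needed to exercise the
  measures and extinction would add parameters no test exploits.
* **Sequences**: `seq_length` 658 sites (the COI barcode length), root
  drawn uniformly, a Poisson number of substitution events per site per
  branch with rate `subst_rate` 0.015 substitutions/site/unit time,
  optionally gamma-distributed site rates and K2P
  transition/transversion bias (`kappa`; JC69 is the `kappa = 1` case).
  The default rate was fixed once, by a pilot under an independent
  simulator, to put the matrix in the moderate-divergence regime where
  roughly a third to a half of sites are parsimony-informative —
  the regime reported for widely used nuclear phylogenetic markers —
  and the acceptance suite confirms the measured $PI/A$ agrees with the
  generator's own recorded truth. A `homoplasy_free` mode gives each
  column exactly one change on one branch, so CI = RI = 1 on the
  generating tree by construction.
* **Taxonomy**: the ultrametric tree is cut at node-age quantiles
  (defaults genus 0.75, subfamily 0.88, family 0.95, superfamily 0.98,
  chosen to give a nested census of roughly 17/9/4/2 groups at 64 tips,
  i.e. a few species per genus and a few genera per subfamily, echoing
  the shape of real multi-rank samples). Every group is a clade of the
  generating tree, so with zero perturbation PMT = TCI = TRI = 1 at
  every rank — the analytic optimum used as the package's primary
  acceptance check.
* **Perturbation**: a fraction of tips (rounded down to an even count)
  swap complete taxonomy rows pairwise across distinct genera. Swapping
  rather than relabelling preserves every group's size, so censuses and
  $G^t$ stay fixed while congruence degrades; mean PMT/TCI/TRI are
  non-increasing in the fraction. One boundary case is worth noting: in
  a scenario of two equal-sized genera, a *complete* pairing of all tips
  across the genera merely exchanges the two group labels and leaves
  monophyly intact; the congruence minimum is reached at intermediate
  fractions, and the tests assert exactly that.
* **Missing data**: uniform per-cell masking to `N`, or a contiguous
  column block for a subset of taxa (emulating a marker for which part
  of the taxa were sequenced over a non-overlapping fragment).

All randomness flows from one seed per scenario; identical
configurations produce byte-identical FASTA/Newick/TSV/JSON outputs.

What the generator does *not* emulate: gene-tree/species-tree
discordance, indels and alignment error, base-composition heterogeneity
across lineages, and rate variation across clades. Passing tests
therefore demonstrate that the measures compute what they claim on data
whose truth is known — not that any particular real gene region will
score well.

## Numerical and degenerate-input choices

* Tolerances: the optimum checks (PMT/TCI/TRI = 1, CI/RI = 1) are exact
  identities, not approximate ones, because the quantities are ratios of
  small integers.
* A pairwise distance with no mutually unambiguous site excludes the
  pair with a warning; a matrix where all pairs are excluded is an
  error.
* All-missing characters are an error for step counting; all-invariant
  matrices yield `NA` indices.
* Tie-breaks: ranking of genes uses dense ranks (ties share a rank);
  equally parsimonious labelings are never materialised.
* Identifier matching across alignment, tree and taxonomy is exact after
  whitespace trimming; silent fuzzy matching would corrupt congruence
  scores.

## Problem sizes

The shipped tests run scenarios of 16–64 terminals and 50–658 sites, the
oracle comparisons use trees of up to 10 leaves, and the full suite plus
the acceptance script complete in well under a minute each on one core.
The implementation itself is not limited to these sizes: all scoring is
linear in terminals × columns, and matrices of several hundred terminals
score in seconds.

## Known limitations

* Only aligned FASTA, Newick and TSV taxonomies are read; no NEXUS or
  PHYLIP dialects, and no alignment or tree search at scale is
  performed (an exhaustive topology search up to 8 leaves exists for
  validation).
* Distances are uncorrected p-distances by design; model-corrected
  distances are a different utility notion.
* The indices are descriptive; the package deliberately offers no
  significance test of congruence.
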