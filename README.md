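# genegauge

Which gene region is worth sequencing for a molecular phylogenetics
project? `genegauge` scores candidate regions (DNA barcodes, nuclear
markers, ...) along two axes that systematists routinely argue about but
rarely quantify:

- **Phylogenetic utility** — intrinsic properties of the aligned
  datamatrix, measured *before* any tree inference: the aligned length
  *A*, the number of variable sites *V*, parsimony-informative sites
  *PI* (at least two states each in at least two terminals), the
  tree-independent minimum number of state changes
  *M* = Σ<sub>columns</sub>(states − 1), the character–taxon ratio
  *A*/*G*<sup>t</sup>, and the mean uncorrected p-distance over all
  terminal pairs (pairwise deletion of non-unambiguous sites).
- **Phylogenetic signal** — measured *after* inference, against
  cladograms. Character congruence uses the ensemble consistency and
  retention indices, CI = *M*/*S* and RI = (*G*−*S*)/(*G*−*M*), where
  *S* is the tree length under parsimony and *G* the greatest number of
  changes possible on any tree. Taxonomic congruence encodes each named
  taxon (genus, subfamily, family, superfamily) as a binary
  group-membership character (1 = member, 0 = non-member) and scores it
  on the tree, yielding the proportion of monophyletic taxa
  PMT, the taxon consistency index TCI = *M*<sup>t</sup>/*S*<sup>t</sup>
  and the taxon retention index
  TRI = (*G*<sup>t</sup>−*S*<sup>t</sup>)/(*G*<sup>t</sup>−*M*<sup>t</sup>),
  with *M*<sup>t</sup> the number of test taxa, *S*<sup>t</sup> the
  summed minimum number of clades each taxon exhibits on the tree, and
  *G*<sup>t</sup> the number of terminals. The best possible score of
  each is 1.

Step counts are obtained with a Fitch set algorithm generalised to
polytomies by Hartigan's frequency rule (soft polytomies, missing states
free). Values are aggregated per taxon, for taxa with three or more
sampled species, at four nested ranks. A synthetic-data generator (Yule
trees, JC69/K2P sequence evolution, clade-cut taxonomies with controlled
label perturbation and missing data) provides coherent
alignment/tree/taxonomy bundles with recorded ground truth.

## Worked example

```r
library(genegauge)

# a 64-species, 658-site scenario whose taxonomy is cut from clades of
# the generating tree, with 10% missing cells
sc <- simulate_scenario(scenario_config(missing_fraction = 0.1, seed = 601))

utility_scores(sc$alignment)
#>     A   V  PI   M n_terminals char_taxon_ratio     p_mean    V_prop   PI_prop    M_prop
#> 1 658 371 243 483          64         10.28125 0.07056224 0.5638298 0.3693009 0.7340426
```

Roughly 37% of sites are parsimony-informative and the mean pairwise
distance is about 7% — a moderately diverged matrix, comparable to a
mitochondrial barcode sampled across genera to superfamilies. Scoring
signal on the generating tree:

```r
groups <- build_membership_matrix(sc$taxonomy, "genus", min_size = 3)
taxon_congruence(sc$tree, groups)
#> Taxonomic congruence: Mt=9 St=9 Gt=64 | PMT=1.000 TCI=1.000 TRI=1.000

congruence_scores(sc$alignment, sc$tree)[, c("S", "M", "G", "CI", "RI")]
#>     S   M    G        CI        RI
#> 1 546 483 1497 0.8846154 0.9378698
```

Every genus is recovered as a clade (the taxonomy was unperturbed, so
PMT = TCI = TRI = 1, the analytic optimum), while the sequence
characters themselves show mild homoplasy (CI ≈ 0.88). With
`perturb_fraction > 0` the taxonomic indices degrade monotonically.

The same analyses run from a shell via the installed `exec/genegauge`
script or `Rscript -e 'genegauge::gg_cli()' --args ...`:

```sh
genegauge simulate --n-species 64 --seed 601 --out bundle/
genegauge signal --tree bundle/tree.nwk --taxonomy bundle/taxonomy.tsv --out signal.tsv
genegauge utility --alignment bundle/alignment.fasta --taxonomy bundle/taxonomy.tsv --out utility.tsv
genegauge report --config run.yaml --out report/   # multi-gene comparison
```

Every tabular output is TSV with a JSON mirror.

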