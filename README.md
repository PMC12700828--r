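# foldtree

Structure-based phylogenetics in R: from an all-versus-all structural
alignment table to a rooted, quality-scored phylogeny.

Protein folds diverge more slowly than sequences, so structural similarity
carries phylogenetic signal beyond sequence saturation. `foldtree` is for
anyone who has run an exhaustive all-versus-all structural comparison of a
protein family (the tabular output with `query`, `target`, `fident`,
`lddt`, `alntmscore`, span and length columns) and wants a tree out of it,
along with honest ways to judge that tree when no reference phylogeny
exists.

The pipeline:

1. **Similarity matrix** — per-pair mean of the chosen score (`fident`,
   `lddt` or `tm`) over both alignment directions; diagonal 1.
2. **Distance correction** — either the raw complement `d = 1 − s` or the
   default saturation-inverting transform `d = −ln(max(s, ε))`, ε = 1e-4,
   so distances grow linearly with divergence rather than flattening as
   scores saturate (a fitted per-metric transform can be plugged in).
3. **Neighbor joining** — canonical Saitou–Nei NJ; exact on additive
   matrices; negative branch estimates clamped to 0. An externally built
   tree (e.g. from the exported PHYLIP matrix) can be swapped in.
4. **MAD rooting** — the root minimises the RMS relative deviation
   `|2·d(ρ,b)/d(b,c) − 1|` over leaf pairs straddling the candidate
   position ρ; per-branch optima in closed form, scale-invariant, zero on
   ultrametric trees.
5. **Quality scores** — the Taxonomic Congruence Score (TCS: bottom-up
   lineage-set intersections; node score = intersection size; leaf score =
   sum of node scores on the root-to-leaf path; tree score = mean leaf
   score) and the variance of mean-normalised root-to-tip distances
   (0 ⇔ strict molecular clock).

Also included: **corecut** (trim every member of a family to the contiguous
region where >80% of the other members' alignments map, then single-linkage
cluster the cut-off termini for tree annotation), a pLDDT ≥ 40 model
filter, benchmark tabulation with multinomial error bars, and a seeded
synthetic-data generator (Yule/clock-noise trees, congruent 7-rank
taxonomies, exhaustive alignment tables with planted domain architectures)
so the whole pipeline runs and is testable offline.

## Worked example

Simulate a 16-protein family with mild clock violation and score noise,
then fit and evaluate the tree:

```r
library(foldtree)

truth <- simulate_tree(16, "clock_noise", sigma = 0.05, seed = 42)
hits  <- similarity_table_from_tree(truth, noise_sd = 0.01, seed = 42)
tax   <- simulate_taxonomy(truth)

fit <- foldtree(hits, metric = "fident", mode = "corrected", lineages = tax)
fit
#> Structure-based phylogeny (fident, corrected distances)
#>   leaves:      16
#>   MAD root:    branch 22->28, deviation 0.01626
#>   rtt variance: 0.0005603
#>   TCS:         12.44

robinson_foulds(fit$tree, truth)
#> [1] 2
tcs(truth, tax)$tree_score
#> [1] 12.4375
```

Reading the numbers: the MAD deviation (0.016) and root-to-tip variance
(0.00056) say the rooted tree is nearly clock-like, as it should be for a
mildly perturbed clock simulation. The fitted tree's TCS (12.44) is
essentially the true tree's own score (12.4375) — with 0.01 score noise the
reconstruction differs from the truth by a single internal branch
(Robinson–Foulds distance 2). At `noise_sd = 0` the pipeline is exactly
invertible: RF = 0 and zero residuals (`residuals(fit)` gives input
distances minus the tree's patristic distances).

On real data, start from `read_alignment_tsv()`, optionally
`filter_by_plddt()` / `trim_set()`, and the same `foldtree()` call; the
fitted object has `print`, `summary`, `plot`, `residuals` and `simulate`
methods, and `run_foldtree()` writes Newick/PHYLIP/JSON artefacts for a
whole run. A thin command-line wrapper with `run`, `simulate`, `corecut`,
`tcs`, `rttvar`, `root` and `benchmark` subcommands is installed at
`system.file("scripts", "foldtree.R", package = "foldtree")`.

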