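---
title: "Structure-based phylogenetics with foldtree: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based phylogenetics with foldtree: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(foldtree)
```

## The problem

Protein folds evolve more slowly than the underlying amino-acid sequences,
so pairwise structural similarity retains phylogenetic signal long after
sequence identity has saturated. With predicted structures now available
for essentially any protein family, a practical question arises: how do you
turn a table of all-versus-all structural-alignment scores into a usable,
rooted phylogeny — and how do you tell whether that phylogeny is any good
without a known true tree?

`foldtree` implements the full chain: similarity scores to corrected
distances, distances to a neighbor-joining tree, minimal-ancestor-deviation
rooting, and two reference-free quality scores (taxonomic congruence and a
molecular-clock diagnostic). It also implements "corecut", a consensus-core
trimming step that removes variable terminal domains before tree building,
and a seeded synthetic-data generator so that every stage can be exercised
and validated without any external database or aligner.

The structural aligner itself is *not* wrapped: its exhaustive
all-versus-all tabular output (columns `query`, `target`, `fident`, `lddt`,
`alntmscore`, spans and lengths) is the package's input format. Three score
columns are supported as distance sources: `fident` (fraction of identical
residues in a combined structural-alphabet + amino-acid alignment), `lddt`
(superposition-free local agreement) and `tm` (rigid-body similarity,
alignment-length normalised).

## From similarity to distance

Each unordered pair's similarity is the mean of the selected score over all
hits between the two proteins in either direction. Exhaustive searches
report both directions; averaging is symmetric and unbiased, and the paperwork
of direction handling disappears. The diagonal is fixed at 1 and missing
pairs are an error by default — an exhaustive search should produce every
pair, so a hole usually means upstream breakage. Opt-in imputation with the
matrix minimum is available for deliberately sparse tables.

Two similarity-to-distance modes exist:

* `raw`: \(d = 1 - s\). Simple, bounded, but compresses deep divergences:
  once scores saturate near their floor, equal increments of time no longer
  produce equal increments of distance.
* `corrected` (default): a saturation-inverting transform intended to make
  distances grow linearly with divergence time. The default form is
  \(d = -\ln(\max(s, \varepsilon))\) with \(\varepsilon = 10^{-4}\). A
  fitted per-metric correction can be supplied via the `transform` argument
  of `correct_similarity()`; the log fallback keeps the pipeline runnable
  (and exactly invertible against the synthetic generator) when no fitted
  constants are configured.

The \(\varepsilon\) clip bounds the largest distance at
\(-\ln(10^{-4}) \approx 9.2\). This matters: neighbor joining is happy with
large finite distances but not with infinities, and a single zero score
would otherwise dominate the tree. Clipping triggers a warning so silent
saturation cannot pass unnoticed. The inversion property — similarities
generated as \(e^{-d}\) recover \(d\) exactly — therefore holds on the
domain \(s > \varepsilon\), i.e. pairwise distances below ~9.2; the test
suite normalises its random trees to unit height to stay comfortably inside
that range.

Predicted models with mean per-residue pLDDT below 40 can be removed before
matrix assembly (`filter_by_plddt()`, or `plddt_threshold = 40` in
`foldtree()`). The cutoff is applied to the mean of the B-factor column of
the model PDB; experimental structures carry no pLDDT and are never
filtered. Filtering happens *before* the similarity matrix is built so the
label set shrinks consistently through the pipeline.

## Tree inference and rooting

Distance trees are built with canonical Saitou–Nei neighbor joining (via
`ape::nj`). NJ is statistically consistent: on an additive matrix it
returns the generating topology and branch lengths exactly, which is both a
theoretical anchor and a strong end-to-end test (see below). Because labels
are sorted lexicographically during matrix assembly, output is
deterministic. Negative branch-length estimates, which appear under noise,
are clamped to zero with a message; no length is transferred to adjacent
branches. Users who prefer an external distance program can export the
matrix with `write_phylip_dist()` and re-enter the pipeline via the
`external_tree` argument — the rooting and scoring stages are agnostic to
where the unrooted tree came from.

Rooting uses minimal ancestor deviation (MAD). For a candidate root
position \(\rho\) on a branch, every leaf pair \((b, c)\) whose path
crosses \(\rho\) would have its ancestor at the pair midpoint under a
strict clock; the relative deviation is
\(\left| 2\,d(\rho, b)/d(b, c) - 1 \right|\), and the branch score is the
root-mean-square of these deviations over all straddling pairs at the
branch's optimal \(\rho\). Since the objective is a convex quadratic in
\(\rho\), the per-branch optimum is computed in closed form and clamped to
the branch; a grid-search oracle is used only in the test suite. The root
goes on the globally best branch. Deviations are ratios of path lengths, so
the placement is invariant to rescaling the whole tree, and on an
ultrametric tree the minimum is exactly zero at the true root. Ties between
branches are broken toward the most balanced leaf split and then
lexicographically, keeping output deterministic. Leaf pairs at zero
distance carry no signal for the ratio and are skipped with a warning;
trees whose branch lengths are all zero are rejected.

## Tree quality without a reference tree

**Taxonomic Congruence Score (TCS).** Each leaf carries the set of taxa in
its lineage (up to seven ranks, kingdom to species). Bottom-up, every
internal node's set is the intersection of its children's sets
(multifurcations intersect over all children), and its score is the
cardinality of that set. A leaf's score is the sum of internal-node scores
along its root-to-leaf path; the tree score is the mean leaf score. Deep
congruence is thus weighted heavily: a correct basal split contributes to
every leaf below it. Three conventions worth making explicit:

* Unknown (empty) ranks are dropped from the leaf's set rather than treated
  as wildcards — missing annotation must not inflate intersections.
* Taxa are compared as (rank, name) pairs, so a genus and a species that
  happen to share a name never spuriously intersect.
* TCS reflects the density of taxonomic information in the input set, so it
  is comparable only between trees over the *same* leaves (alternative
  reconstructions of one family), never across families. The benchmark
  tabulation below respects this.

The per-node scoring is pluggable (`node_score` argument) should a
depth-normalised variant be wanted; the default is the raw cardinality,
which is the direct set-based reading of the recursion.

**Clock diagnostic.** `rtt_variance()` divides root-to-tip path lengths by
their mean and returns the population variance of the normalised values —
the squared coefficient of variation. It is zero exactly for ultrametric
trees and invariant to global rescaling, so trees of different depths are
comparable. Population (divide-by-n) variance is used: the leaves are the
whole population of root-to-tip paths of the tree under study, not a sample
from a larger one.

**Benchmark tabulation.** `winner_proportions()` takes a families-by-methods
score table, awards each family's win to its best-scoring method (k-way
ties split 1/k so proportions always sum to one), and attaches the standard
error of a multinomial proportion \(\sqrt{p(1-p)/n}\). Tie handling is a
convention choice; the fractional split was chosen because it keeps the
proportions a proper distribution.

## Corecut: consensus-core trimming

Families with domain-architecture changes (extra N- or C-terminal domains
in some members) confound whole-chain comparisons. Corecut maps all pairwise
alignments onto each protein and computes, per residue, the fraction of the
*other* proteins with at least one alignment covering it. Distinct partner
proteins are counted, not alignment rows, so duplicated reciprocal hits do
not double-count. The core is the single continuous span from the first to
the last residue whose coverage strictly exceeds the threshold (default
0.8); interior dips are retained by construction — the core is one region,
not a union of islands. The denominator is the number of other proteins in
the set (`n_total = n - 1`); a different denominator (e.g. only proteins
with at least one hit) can be passed explicitly to `coverage_profile()`.

Proteins whose coverage never exceeds the threshold have no core and are
excluded with a warning. The trimmed-off termini are clustered by
single-linkage on their pairwise alignment similarity (default: `fident`
at 0.3, fragments shorter than 10 residues labelled `"none"`), with each
cluster deterministically named after its lexicographically smallest
member. Single linkage was chosen because it is the minimal deterministic
choice consistent with "chains of similarity" and needs no cluster-count
parameter. After trimming, similarities must be recomputed on the cores
(the trimmed PDBs are written for exactly that purpose) before building the
core tree.

## The synthetic generator: what it does and does not emulate

`simulate_tree()` draws Yule (pure-birth) trees, ultrametric by
construction; the `clock_noise` model multiplies each branch by independent
lognormal(0, σ) noise, breaking the clock but not the topology.
`similarity_table_from_tree()` emits an exhaustive all-versus-all table in
which every score decays as \(e^{-d_{\text{patristic}}}\) plus optional
i.i.d. Gaussian noise, clipped to [0, 1], and self-hits score 1. The
\(e^{-d}\) decay is deliberately paired with the \(-\ln\) corrected
transform so the noise-free pipeline is *exactly* invertible — that is a
test convention that makes correctness failures unambiguous, not a claim
about the empirical score–time relation of real aligners.
`simulate_taxonomy()` cuts the species tree at seven increasing depths
(default: 5%–95% of tree height) and names each rank's taxa by the subtree
they descend from, yielding lineages fully congruent with the tree;
`permute_leaves()` provides the matching negative control. The optional
`domain_architecture()` gives some members an extra N-terminal stretch or
C-terminal domain and restricts alignment spans to the shared core, which
is what makes corecut testable end to end.

What the generator does *not* emulate: real 3D geometry or structural
alphabets (scores are derived from the tree, not from folds); correlated
noise between the three score columns or across pairs sharing a protein;
alignment-length effects on score reliability; horizontal transfer,
duplication or incomplete lineage sorting (gene trees always match the
species tree, so congruence controls are clean); and structure-prediction
error beyond a scalar per-residue pLDDT. Consequently, passing tests
demonstrate that the algorithms are implemented correctly and behave as
their theory predicts under the stated noise model — they do not certify
accuracy on real structural data, which depends on aligner behaviour the
package intentionally treats as an external input.

## Numerical choices and degenerate inputs

* Similarity clip \(\varepsilon = 10^{-4}\) (max corrected distance ~9.2);
  clipping warns.
* NJ negative branch lengths clamped to 0, with a message; never
  transferred.
* MAD: per-branch closed-form minimiser clamped to the branch; branch ties
  broken by balance then lexicographically; zero-distance leaf pairs
  skipped; all-zero-length trees rejected. Two-leaf trees cannot be MAD
  rooted (no straddling triples); the fit requires n ≥ 3.
* Newick output uses 9 significant digits, so write-then-read round trips
  agree to ~1e-9 relative.
* Alignment coordinates are 1-based inclusive everywhere, matching the
  input dialect; no internal conversions.
* Rows of the alignment table are validated on read (scores in [0, 1],
  ordered spans within protein lengths) with the offending row number in
  the error.
* `n = 2` distance input returns the single split as a cherry; there is no
  unrooted two-leaf topology.
* Test-suite problem sizes: tree recovery on 8–32 leaves (100 replicates),
  MAD grid cross-checks on 8–10 leaves, TCS oracle equivalence on 200
  8-leaf trees, and a 100-family, 16-leaf benchmark harness run — sizes at
  which every property is decisive for correctness while the whole suite
  stays quick to run.

## Known limitations

* The corrected transform's fitted per-metric constants are a configuration
  hook (`transform`); out of the box the log fallback is used for all three
  metrics.
* MAD scores all branches but the package offers no midpoint or outgroup
  rooting modes.
* PDB ingestion is deliberately minimal: first model, first altloc, one
  chain, CA atoms only; mmCIF and multi-chain complexes are out of scope.
* TCS presumes the taxonomy is trustworthy; a wrong lineage table lowers
  scores of correct trees and can invert within-family rankings.
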