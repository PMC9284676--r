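---
title: "Methods: comparative repeatome analysis in repeatomeKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative repeatome analysis in repeatomeKit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

repeatomeKit analyses the *repeatome* — the repetitive DNA fraction of a
genome — as quantified by similarity-based clustering of low-coverage
genome-skimming reads. Read clusters stand in for repeat families; a
cluster's read count is proportional to the family's genomic abundance.
This vignette documents the models, the tunable parameters, the
synthetic-data generator, and the numerical choices made where the design
was genuinely open. It states no empirical result that the package's
tests and acceptance script do not themselves compute.

## Data model

Five containers carry the analysis (all S4, with validity checks):

* `RepeatAbundanceTable` — samples × repeat families, entries in percent
  of the holoploid genome (1C). `NA` means *not assayed*; an explicit `0`
  means *measured as zero*. The distinction matters because cluster
  filtering treats zeros as informative (a repeat truly absent in one
  species) while `NA` is missing information.
* `GenomeSizeTable` — 2C (pg), ploidy, and derived monoploid sizes
  1Cx = 2C/ploidy in pg and Mbp (1 pg = 978 Mbp, the standard conversion
  constant). Consistency between printed and derived values is enforced
  at the rounding precision of published tables (2 decimal places for
  pg).
* `HitGraph` — an undirected read-similarity graph ("hitsort"): nodes
  are reads labelled with a species code and a cluster, edges are
  similarity hits with positive weight. Species are decoded from a
  fixed-length read-name prefix (default 3 characters) because
  comparative clustering tools encode the sample in the read name; the
  length is a parameter since naming schemes vary.
* `DistanceMatrix` / `ClusterSimilarityMatrix` — per-cluster species ×
  species observed/expected edge ratios and their distance transforms.
* `SplitSet` — weighted bipartitions of the taxon set with support
  frequencies; written/read as a SplitsTree-compatible NEXUS SPLITS
  block.

## Abundance and genome-size arithmetic

Per-family and per-sample summaries are computed over non-missing
entries; per-sample totals come from a designated `Total` column when the
table provides one (published tables do), else from row sums.
Group differences use the tie-corrected Kruskal–Wallis *H* with a
χ²(k−1) upper tail, delegated to `stats::kruskal.test`; the grouping is
caller-supplied because published analyses are ambiguous about whether
they grouped by major clade or by lineage. p-values are reported raw.

## Repeat amounts versus genome size

Absolute amounts are reconstructed as (% of 1C)/100 × 1Cx(Mbp). To
remove shared-ancestry correlation, both the family amount and 1Cx are
converted to phylogenetically independent contrasts (Felsenstein
pruning, written out in `independentContrasts()`): contrast
(x_i − x_j)/√(v_i+v_j), ancestral value the 1/v-weighted mean, parent
edge augmented by v_i v_j/(v_i+v_j). Contrast vectors are correlated
*through the origin* (no re-centering) — contrasts have expectation zero,
and re-centering would waste a degree of freedom; the p-value uses
t = r√((n−2)/(1−r²)) on n−2 df. The suite verifies the identity between
this correlation and the direct GLS correlation computed from the
Brownian covariance matrix (tolerance 1e-8 on trees of ≤ 8 tips), and
checks `independentContrasts()` against the reference implementation in
ape.

The contribution of family *f* to pairwise genome-size differences
orients each pair so GS_a > GS_b and averages
100 × (A_fa − A_fb)/(GS_a − GS_b) over pairs. Signed shares are kept —
families anti-correlated with genome size legitimately contribute
negative percentages. Pairs whose genome sizes differ by less than 1% of
the mean genome size (parameter `floorFrac`) are excluded: the share is a
ratio of differences and blows up as the denominator vanishes. On
compositional data (genome size = Σ amounts / (1 − unclassified
fraction)) the summed-amounts contribution equals exactly
100 × (1 − unclassified fraction), which the tests exploit.

## Similarity matrices, distances, networks

For each cluster the observed/expected interspecies edge ratio uses the
simplest null consistent with the statistic's name: *E* edges placed
uniformly over all node pairs conditioned on per-species read counts,
giving expected counts E·n_s n_t/C(N,2) off-diagonal and
E·C(n_s,2)/C(N,2) on the diagonal. Ratios with expected count zero are
recorded as missing. Two transforms to distances are provided:
Euclidean distance between species' ratio profiles (diagonal columns
included — they carry real information about intra-species cohesion) and
the elementwise inverse 1/S. The Euclidean transform yields a metric
(property-tested); the inverse transform need not satisfy the triangle
inequality and is kept because it is the other transform used in
practice. Clusters with missing species, `NA`, or zero interspecies
ratios are discarded before tree building, with per-reason counts
reported.

Neighbor-joining is implemented from the Saitou–Nei recursion with two
documented conventions: ties in the Q-criterion break to the lowest
index pair, and negative branch lengths are clamped to zero with the
deficit transferred to the sibling branch so path lengths through the
new node are preserved. Consistency (exact recovery from additive
matrices) is tested exhaustively on all 4- and 5-taxon topologies, and
topologies are cross-checked against ape's NJ.

The consensus network retains every nontrivial split occurring in more
than a threshold fraction of the per-cluster NJ trees (plus all trivial
splits); split weight is the mean branch length over the trees
containing the split. The default threshold is 0.25 — deliberately below
majority rule, because the point of a split *network* is to expose
conflicting signal; it is a surfaced parameter since the original
SplitsTree setting used in published work is unstated.

## Phylogenetic signal

Blomberg's *K* is computed from the direct matrix formulas: with V the
Brownian covariance of a rooted tree, phylogenetic mean
ā = (1ᵀV⁻¹x)/(1ᵀV⁻¹1), K = (MSE0/MSE) ÷ [(tr V − n/(1ᵀV⁻¹1))/(n−1)].
K ≈ 1 means the trait is as tree-structured as Brownian motion predicts;
K ≈ 0 means no signal. The significance test permutes trait values over
tips and scores the GLS mean squared error (smaller = more signal), with
the add-one rule p = (1 + #{MSE_perm ≤ MSE_obs})/(n_perm + 1), so p can
never be zero. *K* requires a rooted covariance; a pure star tree is
accepted as its own rooting (and gives K = 1 for any non-constant trait,
a useful algebraic control), while other unrooted trees are rejected with
instructions to root first. A cladogram mode (all branch lengths 1) is
provided because signal tests in the literature are often run on
topology-only cladograms; both modes are exposed since published methods
sections rarely say which was used. Calibration is tested: type-I error
0.05 ± 0.02 over 500 null datasets (16-tip tree, 199 permutations), and
mean K within [0.85, 1.15] over 200 Brownian simulations on a 32-tip
tree. These problem sizes keep the default suite fast while leaving the
Monte-Carlo error comfortably inside the asserted bands.

## Hs/Ho conservatism profiles

For every read in a family's graph, Hs counts same-species neighbours
and Ho other-species neighbours. Because species contribute unequal read
numbers, the ratio is per-capita normalized:
ρ = [Hs/(n_s − 1)] / [Ho/(N − n_s)]. A conserved repeat hits both pools
at the same per-capita rate (log10 ρ ≈ 0); a diversified repeat hits
mostly its own species (log10 ρ ≫ 0). Reads with Hs = Ho = 0 carry no
information and are excluded; reads with only a zero denominator are
capped/floored at the histogram limits rather than dropped, because an
extreme read is evidence, not noise. Histograms default to 40 bins over
log10 ∈ [−2, 3] (the positive tail accommodates highly diversified
spacer-like sequences); mode positions are therefore quantized to a
0.125 bin grid, which the tests allow for. The normalization is
validated by a scaling property: doubling every species' read count
leaves the expected mode position unchanged.

## Tandem-repeat graph classification

A tandemly repeated monomer sampled by reads produces a circular
structure; one ribotype yields a single loop, two ribotypes sharing the
conserved gene yield two loops joined at the shared path. The package
operationalizes the usual visual classification as the cycle rank
β = E − V + components of a simplified graph: prune light edges, keep
the largest connected component, iteratively trim degree-1 vertices, and
count (degree-2 chain contraction leaves β unchanged, so chains need not
be contracted explicitly). β = 1 ⇒ type 1; β ≥ 2 ⇒ type 2; a graph that
prunes to a tree is flagged "linear/ambiguous" rather than forced into a
type.

Two numerical choices matter here. First, classification runs on the
*k-mer (de Bruijn) graph* of the reads, not on the read-pair similarity
graph: a densely sampled circle makes the read graph a "thick" annulus
whose graph-theoretic cycle rank is huge, whereas the k-mer graph of an
error-free circular monomer is exactly one cycle and two gene-sharing
ribotypes give exactly a theta graph. The read graph still serves the
connected-component index C = |largest component|/|V| (computed on
undirected components, a documented divergence from tools that use
directed strongly connected components). Second, the pruning threshold
is `pruneWeightFrac` (default 0.1) times the *weight-mass median* of the
edge weights — the weight at which half the total edge mass lies below.
With per-base errors, erroneous k-mers create many weight-1 edges that
outnumber true edges; the plain median collapses onto them and pruning
would remove nothing, while the mass-weighted median tracks true
coverage. Defaults k = 11 and `pruneWeightFrac` = 0.1 are exposed.

The greedy dominant-cycle score walks the directed k-mer graph from the
most frequent k-mer, always taking the heaviest unvisited successor and
closing on revisit; the score is the summed occurrence count of the
cycle's k-mers over all k-mer occurrences — near 1 for one clean
monomer, near the dominant ribotype's share for mixtures, 0 when no
cycle exists.

## The synthetic generator

`simulateRepeatome()` draws, in a documented RNG order (tree → amounts →
graphs, with separate tree and data seeds so one tree can carry
replicate datasets):

* a pure-birth (Yule) species tree rescaled to unit root-to-tip depth;
* "signal" clusters whose per-species amount is exp(Brownian trait) —
  exponentiation guarantees positivity and gives the right-skewed
  abundance distributions real repeatomes show — and "noise" clusters
  with i.i.d. log-normal amounts;
* genome sizes composed additively, 1Cx(Mbp) = Σ amounts/(1 − u) with
  unclassified fraction u, so composition identities hold exactly;
* per-cluster read-similarity graphs with within-species edge
  probability p_in and between-species probability
  p_in · c · exp(−λ·d) for tree distance d. The conservatism ratio
  c ∈ (0,1] and decay λ ≥ 0 are the two axes that make a repeat family
  look conserved (c high, λ low) or diversified (c low, λ high).

Defaults are fixed once and describe a desk-scale experiment: 8 species,
8 signal + 4 noise clusters, 40 reads/species/cluster, p_in = 0.5,
c = 0.2, λ = 2, σ² = 0.3 on log-amounts, u = 0.05, root amount
150 Mbp (≈ a 1.9 Gbp monoploid genome, grass-scale). Real comparative
runs use hundreds of thousands of reads; read counts here enter only
proportion arithmetic, so scaling down changes Monte-Carlo noise, not
structure. What the generator does *not* emulate: sequence-level
retrotransposon structure, Illumina error profiles, chimeric clusters,
copy-number heterogeneity within species, and cluster annotation errors
— so passing tests demonstrate correctness of the downstream statistics
under the stated generative model, not robustness to every artefact of
real read clustering.

`simulateTandemCluster()` samples reads from random circular offsets of
one or two random monomers (default 300 bp, read length 100 bp,
conserved shared gene 120 bp — the 5S-gene-like segment), with optional
per-base substitution errors, and builds the read-pair graph by shared
k-mer counts (edge if ≥ 20 shared 11-mers).

Because interspecies edge probabilities decay exponentially with λ = 2,
distant species pairs can draw zero edges in a 40-read cluster; such
clusters are then discarded by the completeness filter. Split recovery
of the consensus network is therefore a stochastic quantity, and the
acceptance checks average it over replicate datasets rather than
scoring a single draw.

## Known limitations

* The o/e null (uniform random edges conditioned on read counts) is the
  simplest defensible null; real clustering tools may emit
  post-normalized similarity matrices, so absolute ratio values are not
  comparable across tools — only their relative structure is used.
* The inverse-similarity distance is not a metric; NJ accepts it, but
  Euclidean-transform networks are the primary product.
* β automates a judgement that is visual in the source tools; graphs
  that prune to trees are reported as ambiguous rather than typed.
* PIC requires a fully bifurcating tree with positive terminal branches;
  polytomies must be resolved by the caller (e.g. `ape::multi2di`).
* Published headline correlations from real data (e.g. an all-repeats
  R² on a specific 23-taxon tree) are not desk-reproducible without the
  original supplementary amounts and tree; the package instead proves
  the estimator's behaviour on compositional synthetic data where the
  true answer is known exactly.
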