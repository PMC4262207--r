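---
title: "Comparing species-level evolutionary isolation metrics"
author: "evoiso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing species-level evolutionary isolation metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoiso)
```

## The problem

A species sitting alone at the end of a long branch carries evolutionary
history that no close relative shares; a species inside a dense, recently
radiated clade carries very little that its relatives do not. Conservation
prioritisation schemes in the EDGE tradition turn this intuition into a
per-species score on a phylogeny, but at least eleven distinct scores have
been proposed, and they can disagree substantially. This package
implements the full set under one tree framework and provides the
apparatus to ask, for any collection of trees: which metrics are
redundant, which measure genuinely different things, and how much a small
subset can stand in for the rest.

All metrics operate on a rooted tree with branch lengths, usually
ultrametric (contemporaneous tips). Non-ultrametric trees are accepted —
the length-based metrics remain well defined, and the QE weights may then
genuinely contain zeros — but the simulation study and all calibration
below concern ultrametric trees. Branch lengths are treated as arbitrary
time units; no calibration is attempted. Edge lengths live on the child
node of each edge; a root edge in the input is ignored, because no metric
uses it. Zero-length interior edges are permitted and their nodes count as
real nodes in the node-counting metrics.

## The metrics and their conventions

PE, FP/ED, ES, SV and APD are in branch-length units; the node-count
scores (VW, MVW, NWU, NWW), the QE weights and CHR are dimensionless.
Where the literature leaves a convention open we fixed it as follows, so
that the classical identities pin the implementation down:

* **FP/ED** (one computation, two names) partitions total tree length:
  Σ FP = PD exactly, which the tests assert to 1e-9.
* **ES** divides an edge's credit by the daughter count at every node
  passed below it, so Σ ES = PD on strictly bifurcating trees.
* **SV** is the Shapley value of the *unrooted* spanning-length game (root
  suppressed), with closed form Σ_e l_e (N − a_e)/(N a_e) over edges on
  the focal side. The rooted variant of the game would make SV identical
  to FP; the unrooted one keeps them close but distinct, which is the
  behaviour reported for these metrics (mean normalised distance ≈ 0.04),
  and the closed form is checked exactly against a subset-enumeration
  oracle on all trees with up to 8 tips.
* **VW** counts interior nodes on the root-to-tip path root-inclusively
  and tip-exclusively; **MVW** sums daughter counts over the same nodes.
  With these choices MVW = VW/2 exactly on bifurcating trees, matching
  the "2 per bifurcating node" description of the May variant.
* **NWU**: a path node contributes 1 when its clade strictly outnumbers
  *every* sister clade; the score is 1/(1 + Σ), so it is always defined
  and a maximally isolated species scores 1. The published description is
  not operational as written (a bare reciprocal is undefined for a tip
  that is never on the larger side); this is our resolution, chosen to be
  bounded and isolation-increasing.
* **NWW** sums total descendant counts over interior path nodes (root
  included, tip excluded — including the tip would add a constant 1 for
  every species).
* **QE** maximises Rao's quadratic entropy Q(p) = Σ p_i p_j d_ij over the
  probability simplex. On the optimal support the stationarity condition
  D p = c·1 holds; the solver is an active set that solves the linear
  system on the current support, zeroes negative weights, and re-admits
  any dropped species violating the KKT bound (D p)_i ≤ c. Tests verify
  the KKT certificate to 1e-8 and agreement with a simplex grid search on
  3- and 4-tip trees.

### Character rarity (CHR)

CHR models neutral character evolution: characters originate at rate ν
per unit branch length and survive each subsequent edge with probability
ρ. The score of species *i* is the expected number of characters *i*
possesses, each weighted by its expected rarity — one minus the expected
fraction of the *N* extant species carrying it. Both ingredients follow
from the model: a character born on the edge above path node *k* is
retained by *i* with probability ρ^(edges from *k* to *i*), and is
expected in (Σ_{j below k} ρ^(edges k→j))/N of the assemblage.

In the perfect-retention limit ρ = 1 the score is *exactly* an affine
function of APD on an ultrametric tree: every character separating *i*
from *j* marks length on their patristic path, and
Σ_{e on i's path} l_e (N − n_e) = (N−1)/2 · APD(i) + a constant. This is
the analytic root of the well-known empirical redundancy between CHR and
APD, and the tests assert it (R² = 1 at ρ = 1). The defaults are ν = 1
(a pure scale factor, tested as such) and ρ = 0.99: retention per branch
is high on macroevolutionary timescales, and at this value the metric
exhibits the strong rank redundancy with APD (mean Spearman > 0.9 across
simulated 100-tip trees) that motivates carrying it in the comparison
set. Lower retention rates progressively decouple CHR from APD (at
ρ = 0.95 the mean Spearman drops to ≈ 0.83); conclusions that hinge on
CHR should therefore be read as conditional on its inputs, which is also
why the per-metric results report CHR separately rather than folding it
into an APD group by fiat.

## Simulated study conditions

The comparison study runs on homogeneous birth–death trees conditioned on
their extant tip count: four sets with birth rate λ = 0.5 and death rates
µ ∈ {0, 0.125, 0.25, 0.4}, 1000 replicates of 100-tip trees per set. The
simulator (`simulate_bd_tree()`) works forward in continuous time from a
crown split: events arrive at rate k(λ+µ); when the extant count first
reaches the target the process is truncated at a time drawn just before
the next would-be event (so pendant edges are never zero), extinct
lineages are pruned, and degree-2 nodes collapsed. Whole-tree extinction
triggers a fresh attempt (capped at 1000). The output is always
ultrametric to 1e-9, has exactly the requested number of tips, and is
bit-reproducible from the seed.

Conditioning on tip number is known to be sensitive to the stopping rule;
we use the simple forward-with-truncation scheme and compare only means
over many replicates, which are robust to those subtleties (an
independent check against `ape::rphylo`, which conditions differently,
gave indistinguishable summary statistics). One distributional fact worth
noting: at fixed tip count, extinction makes trees *older*, so absolute
pendant edges lengthen with µ while pendant edges relative to tree depth
shrink (≈ 0.15, 0.11, 0.07 of depth at µ = 0, 0.25, 0.4) — "shorter
pendant edges near parity" is a statement about the scale-free shape.

Threat categories for EDGE exercises are drawn independently and
uniformly from {LC, NT, VU, EN, CR} (configurable probabilities). Real
red-list data are of course not independent of the tree; the synthetic
tables exercise the ranking machinery, not the ecology.

What the generator does *not* emulate: rate variation across lineages or
time, incomplete taxon sampling, tree-reconstruction error, and any
correlation between threat and phylogeny. Results on these trees
therefore bound what the metrics do under the cleanest possible
conditions; empirical trees can only add further disagreement.

## Measuring redundancy between metrics

Per tree, all eleven scores are computed and standardised by their means
(every metric then averages 1, making scores comparable across metrics
and trees; `standardize_scores()`). Redundancy between metrics is the
Euclidean distance between their per-tip score vectors, computed — and
this is a deliberate design choice — after reducing each vector to unit
variance (`metric_distance_matrix(scale = "sd")`). Mean-standardised
scores retain enormous dispersion differences (the pendant edge has a
relative spread of ≈ 1.3 on these trees, fair proportion ≈ 0.5), and
Euclidean distances on them are dominated by those spreads rather than by
whether two metrics order species the same way; under dispersion
equalisation the distance is a pure (dis)similarity of profiles, and two
metrics related by a positive affine map — VW and MVW on bifurcating
trees — are at distance exactly 0. The per-tree matrix is normalised so
its mean off-diagonal entry is 1, making entries comparable across trees;
the mean-standardised variant remains available as `scale = "mean"`.

Each per-tree matrix is clustered by average-linkage agglomeration
(`hierarchical_cluster()`, deterministic given the canonical metric
order), and the 1000 per-set dendrograms are condensed into a 50%
majority-rule consensus (`majority_consensus()`): exactly those clades
present in more than half of the dendrograms, with support proportions
attached and verified against an independent bipartition recount. Merge
heights are discarded — only topology is counted. On the simulated sets
this recovers three stable families: the uniqueness-flavoured
{ES, ED, SV, PE}, the originality-flavoured {NWW, APD, CHR}, and a
middle-ground {QE, VW, MVW, NWU} whose support degrades as µ approaches
λ.

## "Variation captured" by a metric subset

The package provides two operationalisations of how much of the total
variation in isolation scores a subset of metrics captures
(`variation_captured()`), because they answer different questions:

* `method = "share"` (default): the fraction of the summed per-metric
  variances of the mean-standardised scores that the subset's own
  variances contribute. This treats a metric's dispersion as the
  information it brings and does not credit the unselected metrics'
  redundancy with the selected ones.
* `method = "r2"`: the variance-weighted mean R² of all eleven metrics
  regressed (OLS with intercept, pseudo-inverse for collinear subsets) on
  the subset. This credits redundancy fully — and because the set
  contains three near-identical pairs and pervasive correlations, it
  saturates almost immediately (any two well-chosen metrics already
  exceed ~75%, and is provably monotone in subset inclusion, which the
  tests assert).

The published ladder of captured percentages rises far too slowly to be a
regression-style measure on these trees — we verified that every
regression, pooled-regression and PCA-eigenvalue reading saturates above
75% at two metrics — and is consistent with the variance-share reading,
which is therefore the default in the reproduction pipeline.

"Selecting the k most different metrics" is operationalised by cutting
the pooled mean-standardised distance clustering into k groups
(`major_groups()`) and drawing one representative per group at random
(`select_dissimilar_subset(mode = "one-per-group")`), averaging over
seeded draws; a greedy forward selector maximising captured variation at
each step is also provided (`mode = "greedy"`). All draws are seeded and
recorded.

## Uniqueness versus originality

The second analysis asks what each metric actually measures, by
projecting it onto two interpretable axes: *uniqueness* — the pendant
edge, the species' own unshared history — and *originality* — its mean
patristic distance to all other species. For each tree in the µ = 0.25
set, each of the eight non-redundant metrics (FP, VW and CHR are dropped
as duplicates of ED, MVW and APD) is Spearman-correlated (average ranks
on ties, the `stats::cor` convention; essential because node-count
metrics tie heavily) with the PE scores and with the APD scores; PE and
APD anchor the two ends with self-correlation 1. The per-tree trade-off
is the OLS fit of the uniqueness correlations on the originality
correlations across the eight metrics (`fit_axis_tradeoff()`); adjusted
R² uses the n − 2 correction. The regression orientation is a genuine
free choice — the relationship is reported symmetrically in the
literature — and we regress uniqueness on originality; with the observed
scatter the two orientations give mean slopes of about −0.93 and −0.78
on these study conditions, so the choice matters and is stated here
once. The mean slope is strongly negative with both: alignment with one
axis trades off against the other almost one-for-one.

## EDGE-style lists

`build_edge_list()` standardises any isolation metric by its mean and
combines it with an ordinal threat category (LC..CR → 0..4) as
EDGE = ln(1 + isolation) + GE·ln 2, ranking species with average ranks on
ties (then by label, for determinism). `compare_top_k()` reports the
top-k overlap of two lists, the Spearman similarity of their full ranks
over the *reference's* top-k species (the convention matching
published comparisons against a reference ED list; computing over the
union instead is a one-line change on the returned ranks), and the number
of distinct isolation values in the other list — node-count metrics
assign identical scores to large swaths of species, which is visible
here as very few unique scores.

## Clade-size scaling

`clade_scaling_profile()` recomputes every metric for one target species
on the nested sequence of complete clades containing it, from its
immediate cherry to the full tree, each metric scaled by its own maximum;
`asymptote_slope()` fits the OLS slope of score against clade size over a
window. PE is constant by construction; the other metrics approach
asymptotes at a few hundred tips, except APD, whose absolute scale grows
with the tree — dividing it by total tree length (APD/PD) restores the
asymptotic behaviour, which the tests assert comparatively on a 250-tip
tree.

## Numerical choices and degenerate inputs

* QE: active-set iterations are capped at 200; negative weights below
  −1e-12 are treated as zero; an all-zero distance matrix is refused.
* Standardisation refuses metrics with non-positive means (a constant
  zero score vector carries no ranking information).
* Constant score vectors yield undefined correlations; these are recorded
  as `NA` with a warning rather than silently dropped.
* Consensus ties at exactly 50% are excluded (strict majority), so
  conflicting resolutions can only produce a star.
* All tie-breaking inside metrics is avoided by design; ranks downstream
  use average ranks.
* Trees without branch lengths are rejected by every metric; they are
  accepted only where topology suffices (consensus input).

## Problem sizes used by the tests and the reproduction script

The acceptance script (`scripts/acceptance.R`) runs the study at full
scale — 4 × 1000 trees of 100 tips (about 70 s on one core). The test
suite exercises the same pipeline at 150 trees per set, which holds the
Monte-Carlo standard error of the reported means well below the
tolerances asserted, and uses 8–100-tip trees for the exact
(oracle-backed) properties. These sizes are package choices balancing
resolution against a pleasant test cycle; all of them are seeded.

## Known limitations

* The captured-variation percentages depend on the chosen
  operationalisation (share versus R²); both are exported, and analyses
  should state which they use.
* CHR conclusions are conditional on (ν, ρ); only its high-retention
  regime is calibrated against APD.
* The simulator covers homogeneous birth–death only; no fossilised
  lineages, rate shifts, or sampling fractions.
* Unrooted trees and networks are out of scope, although SV is defined on
  the unrooted tree and would extend naturally.
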