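---
title: "Graph-based analysis of granule-cell to Purkinje-cell connectivity maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based analysis of granule-cell to Purkinje-cell connectivity maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptograph)
```

## The measurement and its model

A connectivity map records, for one Purkinje cell (PC) held in voltage
clamp, the mean amplitude of the excitatory postsynaptic current (EPSC)
evoked by photostimulating each site of a rectangular grid laid over the
granule-cell (GC) layer: 20 × 20 µm sites in 6 rows (high resolution) or
40 × 40 µm sites in 4 rows (low resolution), covering up to 1280 µm of
the mediolateral axis. Each stimulated site activates tens to hundreds of
GCs — about 76.8 for a 20-µm site under the standard density and
light-penetration assumptions, see `estimate_activated_gc_count()` — so a
site's amplitude summarises a small population of potential synapses. All
amplitudes are stored as magnitudes in pA.

Maps are patchy: clusters of responsive sites surrounded by silent
background. The package quantifies that spatial structure in five stages.

### 1. Thresholding against the recording noise

Every site's mean evoked amplitude $A$ is standardised against the
map-wide synaptic-noise distribution (mean $X$, SD $\sigma$), estimated
by pooling the per-site noise measurements of the whole recording:

$$z = \frac{A - X}{\sigma}.$$

Sites with $z \ge 3$ are *active* (connected). The noise statistics are
pooled map-wide rather than per site, matching how the noise distribution
is built from all sites of a recording; the z map is then invariant under
any positive affine rescaling of the amplitudes, which the test suite
verifies numerically. A degenerate noise SD of zero is an error, never a
silent division.

### 2. Profiles in zebrin coordinates

Each GC-layer column is collapsed to its maximal z score (connectivity
profiles) or to the maximal amplitude among its significant sites
(weight-bearing profiles, used for cumulative-strength curves and
zone-wise weights). Positions are expressed in a zebrin frame: the origin
is the centre of the P1+ band and positions are normalised to the width
of the ipsilateral P1− band (% of P1−), the unit that lets maps from
different animals be pooled. Group summaries interpolate profiles onto a
common 1-µm-equivalent grid, convolve with a unit-area triangular kernel
(half-width 9 µm at high resolution, 18 µm at low), and take the
pointwise median with a raw median absolute deviation envelope; averaged
maps bin pooled site values into 30- or 60-µm-equivalent bins, reporting
empty bins as missing rather than zero so that group means are not
dragged toward zero where no map has coverage. Any display smoothing is
excluded from numeric outputs.

### 3. Graph representation and weighted metrics

Columns become nodes; the edge weight between two columns is the Pearson
correlation of their amplitude depth-profiles, clipped below at zero
(negative correlation is read as absence of similarity, and constant
columns contribute zero weight). On this weighted undirected graph the
package computes:

* **Modularity** $Q^w = \frac{1}{l^w}\sum_{ij}\left[w_{ij} -
  \frac{k_i^w k_j^w}{l^w}\right]\delta_{m_i m_j}$ over the Louvain
  partition — how patchy the map is;
* **module degree z-score** — within-module standardised degree, high
  when patches have graded centres;
* **participation coefficient** $y_i^w = 1 - \sum_m (k_i^w(m)/k_i^w)^2$
  — how much of a node's weight crosses module boundaries;
* **assortativity** — the weighted degree–degree correlation over links,
  capturing coexistence of narrow and broad patches.

Conventions that matter and are fixed here: sums in $Q^w$ run over
ordered pairs with $l^w$ the total (double-counted) weight; the
within-module SD uses the population convention; a singleton or
homogeneous module yields $z = 0$ rather than an undefined value so that
medians stay well defined; a regular (equal-degree) graph has an
undefined assortativity and returns `NA` rather than raising. Louvain is
run with 20 seeded restarts, keeping the best modularity with ties broken
by fewer modules and then lexicographic membership, which makes module
detection deterministic given a seed; on graphs of up to 8 nodes the
result matches exhaustive search over all partitions to 1e−9 (tested).

Absolute metric values of small graphs are hard to interpret, so metrics
can be expressed as percent deviations from chance,

$$\Delta\% = \frac{\mathrm{Actual} - \mathrm{Null}}{\mathrm{Null}} \times 100,$$

where Null is the median over an ensemble (≥ 10, default) of
degree-preserving rewired copies of the graph: Maslov–Sneppen edge swaps
with weights travelling along edges, 10 swap attempts per edge. When the
null median is within 1e−12 of zero the ratio is reported as `NA`.

Node metrics are reduced to feature vectors at three resolutions: a
4-dimensional global vector (modularity + whole-map medians), a
7-dimensional bilateral vector (modularity + per-side medians and
per-side assortativity on induced subgraphs), and zone-wise vectors. The
published description of the zone-wise graph vector as eight-dimensional
does not fit three metrics × several zones, so the zone-wise reduction
here is per-zone medians of each node metric, flattened, with the
ambiguity documented rather than resolved silently. The zone-wise
*weight* vector is the mean significant synaptic weight per structural
microzone, normalised to the map's maximum zone value, giving 8 entries
under the eight-zone template.

### 4. Zones and their correspondence

Structural zones label columns by the zebrin band containing them (seven
printed bands; the eight-zone template splits the ipsilateral P1− band at
its midpoint into medial and lateral halves — the exact published split
is not fully specified, so the template is configurable and a boundary
position joins the band on its ipsilateral side). Functional zones come
from the graph modules under two definitions: contiguous (maximal runs of
a module, so a module split across space yields several zones) and
module-wise (spatial connectedness dropped). Correspondence is the
plug-in mutual information between the two labelings, normalised by the
larger entropy so 1 means identity up to relabeling; chance levels come
from shuffling structural labels per column (the literal reading of the
published shuffle; a block-preserving shuffle that keeps zone shapes is
available as an option). Natural logarithms are used throughout — the
normalised value is base-free.

### 5. Supervised analyses

`classify_conditions()` implements the published protocol exactly: a
random forest of 150 trees with maximum depth 30, evaluated over 100
stratified 80:20 train/test splits, with features standardised on the
training split only and missing entries (empty zones, undefined
assortativity) imputed by training medians with missingness indicators.
Chance is the same protocol with labels shuffled within the training
split of each trial (a single global permutation is available as an
option; the per-trial shuffle is the published description and avoids
the dataset-level bias a single fixed permutation induces). On
signal-free features the shuffled accuracy settles at the sum of squared
class priors — about 0.156 for the seven study groups — which the
acceptance suite checks.

`glm_predict()` fits the behaviour model

$$Y_i = \beta_0 + \sum_j \beta_j G_{ji} + \sum_j \gamma_j T_i G_{ji}
  + \epsilon_i,$$

Gaussian with identity link, where $T_i = \pm 1$ encodes the subgroup,
over 100 random 75:25 splits, reporting per-trial Pearson r and MSE
against a paired shuffled-target baseline. Features are standardised by
scale only: centering them would generate a group main-effect term
($\gamma^\top \mu \, T_i$) that this model, which has no $T$ column,
cannot represent, and exact recovery of noise-free planted data would be
lost. Full-data coefficients are reported on the raw feature scale, with
rank deficiency flagged explicitly.

`tsne_embed()` provides a two-dimensional exact t-SNE (perplexity 10 by
default, suited to cohorts of ~100 maps; deterministic given a seed) for
visualisation, with group centroids as coordinate-wise medians and IQR
dispersion. Embeddings are exploratory; only sanity properties
(duplicates stay closest, well-separated clusters stay separated) are
tested.

## Behavioural features

The balance index of a corridor crossing is
$\mathrm{BI} = \log_{10}(\int \mathrm{left} / \int \mathrm{right})$ —
the base is a package convention, as the source only says "log", and all
identities used (antisymmetry under side swap, invariance to common
rescaling) are base-covariant. Trials need at least five strides and
three valid trials make a session. Time courses are baseline-subtracted
("normalised to baseline" is implemented as subtraction of the
pre-surgery mean) and summarised by trapezoidal AUCs over early
(0–9 days), late (9–21) and adapted (> 21) phases, with the alternative
published late window (4–21 days) available through the `phases`
argument since both windows appear in the source material; AUCs
interpolate the curve at window boundaries so adjacent windows add
exactly. BI_day15 is the measurement nearest day 15. Wheel training
reduces to total distance and the OLS slope of distance against session;
the logistic group-trajectory fit is a display helper only.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions so every stage runs
and is testable without recordings:

* **Zebrin geometries** are drawn from the printed band-width means and
  SDs (e.g. P1+ 34.63 ± 16.18 µm), truncated at a positive floor, with
  the PC position from 52.42 ± 29.8 µm clipped to the 0–130 µm recording
  criterion.
* **Maps** are background Gaussian noise (mean 6 pA, SD 3 pA, placing
  the 3σ detection point at ~15 pA, the published equivalence) plus
  elliptical patches with jittered extents, centred on a mixture prior
  with mass near the mid-ipsilateral hotspot (~500 µm), the midline and
  the contralateral side. Patch shape and the size distribution are
  generator choices — the source shows patches but states no generative
  form — and are tunable, not fitted.
* **Active-site amplitudes** are lognormal (matching the right-skewed
  published distributions, mean ≫ median) *truncated below at the
  detection threshold*, with parameters solved numerically so the
  truncated distribution itself has the published per-condition mean and
  SD (e.g. control 72.3 ± 50 pA). Without the truncation-aware
  calibration, detection would bias pooled significant-site means above
  target.
* **Group sizes** default to the published high-resolution counts
  (14, 13, 11, 11, 25, 14, 17 — 105 maps in 7 conditions).
* **Behaviour** is generated by inverting the prediction model: the
  cohort's own bilateral graph features enter the planted-coefficient
  GLM plus Gaussian noise, so prediction tests have a known ground
  truth.

Everything is deterministic given the configuration seed, to the level
of byte-identical serialised cohorts.

What the generator does *not* emulate: temporal structure of currents
(only amplitudes are modelled), per-recording empirical noise (noise is
i.i.d. Gaussian per site), spatial correlations between geometry and
patch placement beyond the configured priors, and any real
condition-dependent *shape* differences beyond amplitude, active
fraction and patch placement. Passing tests therefore demonstrate the
correctness and calibration of the analysis machinery, not that real
maps have these properties; headline real-data values (e.g. the 0.51
bilateral-feature classification accuracy) depend on the original
recordings and are out of scope.

## Numerical choices and degenerate inputs

* Profile interpolation is linear onto a 1-µm-equivalent normalised
  grid before kernel convolution; the kernel is renormalised at the
  edges so a constant profile is preserved exactly.
* Median profiles are reported only where at least half of the maps
  overlap spatially.
* The bootstrap of group profiles resamples maps with replacement
  (percentile CI of the pointwise median); the resampling unit and CI
  rule of the original supplementary analysis are not specified in the
  available methods, so this default is a documented choice, validated
  against exhaustive enumeration on five profiles.
* Problem sizes in the test and acceptance suites (e.g. 100 random
  graphs of ≤ 12 nodes for oracle equivalence, 50-member null ensembles,
  50 GLM replicates) were chosen as the smallest sizes at which the
  checked statistics are stable.

## Worked example

```{r, eval = FALSE}
library(synaptograph)

cfg <- cohort_config(seed = 1)
cohort <- generate_cohort(cfg)          # 105 maps, 7 conditions

map <- cohort$maps[[1]]
zm  <- compute_zscore_map(map, noise_mean = cfg$noise_mean,
                          noise_sd = cfg$noise_sd)
active_site_stats(zm, map)$fraction_active

graph <- build_correlation_graph(map)
part  <- detect_modules(graph, seed = 1)
assemble_features(graph, part, scheme = "g_bilateral")

sz <- structural_zones(map$positions, map$geometry, "bands8")
fz <- functional_zones(part, "contiguous")
normalized_mi(sz, fz)$nmi

cls <- classify_conditions(cohort$features, cohort$labels, seed = 1)
cls$summary
```

## Known limitations

* Louvain optimality is only guaranteed (and tested) for small graphs;
  on 64-column maps the 20-restart best is a heuristic optimum.
* The rewiring null preserves the binary degree sequence exactly and the
  weighted degrees only approximately, as in the standard weighted
  Maslov–Sneppen scheme.
* The published "local assortativity" is implemented as the printed
  graph-level equation, with lateralised values computed on induced
  side subgraphs; a per-node variant is not provided.
* The eight-zone structural template is a configurable default, not a
  reproduction of the unpublished supplementary split.
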