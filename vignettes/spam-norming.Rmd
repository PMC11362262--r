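---
title: "Norming novel object sets with the spatial arrangement method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Norming novel object sets with the spatial arrangement method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spamkit)
```

spamkit implements the complete analysis chain used to norm a roster of
novel object stimuli: how novel people find each object, how similar the
objects are to one another, and which of them cohere into "global
categories" suitable for category-learning experiments. The chain has five
statistical stages — trial design, dissimilarity construction, metric
multidimensional scaling, dual clustering with a bootstrap stability test,
and a color-confound control — plus novelty scoring and a synthetic
participant generator that lets every stage be exercised and validated
without human data. This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic checks do and do
not establish about real data.

## Pair-covering trial designs

With $N$ objects there are $\binom{N}{2}$ unordered pairs ($435$ for the
default $N = 30$), and a spatial-arrangement study can only measure a
pair's dissimilarity if both objects appear on the canvas in the same
trial. A design is therefore a set of trials ("blocks") of $K$ objects
each such that every pair co-occurs at least once — a covering design in
the combinatorial sense.

`generate_blocks()` uses a randomized greedy: a block is seeded with a
still-uncovered pair, then grown by repeatedly adding the object that
covers the most uncovered pairs (ties broken uniformly at random), and
blocks are added until coverage is complete. `minimal_blocks()` repeats
this under independent seeds and keeps the fewest-trial design, and
`sweep_block_size()` traces the trials-versus-$K$ trade-off. At
$N = 30, K = 16$ the best of 1000 restarts achieves the counting lower
bound of $\lceil 435 / 120 \rceil \cdot$ (overlap slack) $= 6$ trials; for
tiny rosters the tests verify against an exhaustive covering-number
search. The greedy makes no attempt to balance how often each pair or
object recurs beyond its natural tendency to prefer uncovered pairs;
`verify_coverage()` reports per-pair multiplicities so a user can audit a
design before running it.

## From canvas coordinates to dissimilarities

Each participant-trial yields final object-center coordinates on a
$1000 \times 600$ px canvas (origin top-left, $y$ downward — the screen
convention; the choice of origin cancels in all distances).
`trial_pair_distances()` takes plain Euclidean pixel distances;
`participant_matrix()` averages a pair's distances over every trial where
it co-occurred, which under a covering design leaves no missing entries;
`group_matrix()` averages element-wise across participants. All stages
preserve symmetry and the zero diagonal.

Distances are kept in raw pixels by default. A `normalize` switch divides
by the canvas diagonal first; both conventions appear in practice and the
choice is a pure rescaling, so it does not affect embedding shape,
cluster structure, rank orders, or correlations — only the units of
reported stress and distances.

## Metric SMACOF and raw stress

The group matrix $D = (d_{ij})$ is embedded by metric SMACOF: find
$X \in \mathbb{R}^{N \times d}$ minimizing the raw stress

$$\sigma(X) = \sum_{i<j} \left( d_{ij} - \hat d_{ij}(X) \right)^2,$$

where $\hat d_{ij}(X)$ are configuration distances. The ratio variant is
used (distances fit directly, no intercept, no normalization), matching
dissimilarities that are meaningful at the ratio level — doubling all
input distances exactly doubles the recovered configuration. Each start
iterates the Guttman transform, which majorizes the stress and therefore
never increases it; the fit stops when the relative stress decrease drops
below `tol` (default $10^{-6}$) or after `max_iter` (default 300)
iterations. Starts are initialized uniformly in a hypercube scaled to the
mean input dissimilarity, and `n_starts` (default 8 for a final
configuration) independent starts are run with the best kept, since
SMACOF converges only to a local minimum. One conscious reading: the sum
of *squared* residuals is used — an unsquared signed sum is not a loss
function, and majorization is defined on the squared form.

## Choosing the dimensionality: scree + kneedle

`stress_profile()` refits the embedding at each candidate dimensionality
with independently initialized single starts (`replicates` of them;
exploratory analyses used up to 1000) and records the mean and SD of
stress, averaging away start-configuration variability. The elbow of this
scree is located by the discrete kneedle detector
(`kneedle_elbow()`): min-max normalize both axes, invert the $y$ axis so
the elbow of a decreasing convex curve becomes a knee, and take the grid
point maximizing the difference curve $\,(1 - y_n) - x_n$, subject to a
sensitivity threshold ($S = 1$, in units of the mean normalized grid
step). Perfectly linear curves produce an identically zero difference
curve and report "no elbow". No interpolation or smoothing is applied —
the grids here are short integer grids.

One numerical choice matters and is deliberate: the elbow is detected on
the **root** stress scale, $\sqrt{\text{mean stress}}$ (equivalently, a
Kruskal stress-1 scree, since the two differ by a constant factor per
matrix). On the raw squared scale the one-dimensional point dominates the
min-max normalization for *any* Euclidean configuration — the squared
residual at $d = 1$ is an order of magnitude above everything else, so
the normalized difference curve always peaks at $d = 2$ and later elbows
are invisible. On the root scale, planted three-dimensional structure is
recovered reliably (10/10 synthetic worlds in the acceptance checks).
`select_dimensionality(..., scale = "raw")` exposes the raw behavior for
comparison. The same root convention is used for the k-means distortion
elbow, where it corresponds to the RMS distance of objects to their
centroids, in input units.

## Global categories: k-means and Ward, and their stability

`kmeans_partition()` runs Lloyd's algorithm with k-means++ seeding, best
of `n_restarts` (default 50) by within-cluster sum of squares, and
reports the squared-error distortion (mean squared distance to assigned
centroid). `distortion_elbow()` applies kneedle to distortion over a grid
of $k$. `ward_tree()` builds the agglomerative Ward hierarchy on the
MDS-space distance matrix via `stats::hclust(method = "ward.D2")` — the
Lance–Williams update on squared distances, whose variance interpretation
is exact here because MDS distances are Euclidean — and `cut_tree()`
takes the flat partition a dendrogram cut yields. `quartile_bins()` splits
the similarity-ranked pair table into four rank quartiles (Q1 most
similar); when the count is not a multiple of four the earlier quartiles
take the extra pairs (435 splits 109/109/109/108), and exact distance
ties keep lexical $(i, j)$ order everywhere.

The stability protocol (`bootstrap_partitions()`, `stability_summary()`)
resamples *participants* with replacement — the participant's full
dissimilarity matrix is the exchangeable unit — rebuilds the group
matrix, re-embeds at a fixed dimensionality (3, per the study protocol)
with a reduced start count (4) for tractability, and re-clusters at fixed
$k = 7$. Within-method stability is the mean Adjusted Rand Index over all
$\binom{B}{2}$ replicate pairs; cross-method agreement is reported both
as the mean of replicate-matched comparisons (primary) and as the single
comparison on the original non-resampled data, since "agreement between
the two methods" is meaningful both ways. ARI is computed from the
contingency-table formula and cross-checked in the tests against an
independent pair-counting implementation and a reference library.

## The color-confound control

Because stimuli are multi-colored but norming should reflect shape, the
package checks whether arrangement-derived distances correlate with
color. Object images (PNG with alpha) are area-average downsampled to
$20 \times 20$; cells whose resampled alpha falls below 0.5 count as
background and are dropped (box resampling is used precisely so that
partial-coverage cells average rather than alias). Retained sRGB colors
are converted to CIELAB (D65, 2° observer), and a pair's color difference
is the mean CIEDE2000 ($k_L = k_C = k_H = 1$, including the blue-region
rotation term) over the full cross product of the two pixel sets. Note
the sign convention: this is a *dissimilarity*, so a color-driven
arrangement would produce a positive Pearson correlation with MDS
distance. `color_shape_correlation()` reports $r$, $df = \binom{N}{2}-2$,
and the two-tailed $t$-based $p$. One caveat documented rather than
assumed away: CIEDE2000 is not translation-invariant (its weighting
functions depend on the pair means), so even a uniform lightness shift
applied to both objects moves the score slightly; the tests assert
symmetry, pixel-order invariance, and only approximate invariance under
small common shifts.

## Novelty and naming agreement

From per-participant yes/no familiarity answers and coded free-text
concepts, `novelty_rate()` is the percentage of "no" answers per object,
and `identity_agreement()` divides the count of the most popular
single-concept name by the number of single-concept responses — a
conservative denominator that excludes hybrid (two-concept) and
no-concept responses. Concept extraction itself is not automated: the
input carries concept tokens already listed per response and a synonym
map collapses variants ("half circle" → "semicircle"); coding is
independent of the yes/no answer. `summary_stats()` reports sample mean,
SD ($n-1$), range, and flags objects more than two SDs above the mean;
the "known-object" benchmark against which agreement is compared defaults
to 85%. `spearman_rho()` (average ranks, $t$-approximate two-tailed $p$)
quantifies the expected negative relation between novelty and agreement.

## The synthetic world: what it emulates, and what it does not

`make_world()` plants the structure the analysis assumes: 30 objects in a
3-dimensional latent shape space, 7 clusters with sizes between 2 and 6,
cluster centers placed by greedy maximin in a side-100 hypercube so
categories are well separated, within-cluster spread
$\sigma_c = 4$. Familiarity is uniform on $[0.31, 0.81]$, chosen to match
the observed range of human novelty rates (roughly 19–69% "no"
answers). Colors are assigned independently of geometry, which makes the
color control's null hypothesis true by construction.

`simulate_arrangements()` models a participant-trial as a 2-dimensional
metric MDS layout of the trial objects' latent distances — classical
scaling refined by majorization, hence deterministic and exact for 2-d
latent worlds — rescaled into the canvas with a 50 px margin, plus
isotropic Gaussian placement jitter ($\sigma_p = 15$ px by default) and
clipping at the canvas edge. The flattening is intentional: participants
arrange on a flat canvas whatever the latent dimensionality, and the
covering design's cross-trial averaging is what restores
higher-dimensional structure. Two honest limitations follow. First, there
is no accepted model of how people trade off dimensions when flattening;
per-trial optimal 2-d MDS is a stand-in, and it is *better* at flattening
than people are, so the group matrix is closer to 2-embeddable than real
data — the end-to-end scree elbow consequently sits on the 2/3 boundary
even when the latent space is 3-dimensional, and the dimensionality-
recovery checks are run on the latent distances, where the elbow is
clean. Second, the generator ignores attention, fatigue, drag order and
anchoring; passing tests demonstrate that the pipeline recovers planted
structure under its own assumptions, not that human data satisfy those
assumptions.

`simulate_naming()` draws "seen before" as Bernoulli(familiarity) and
names from a convergence model: the canonical name is emitted with
probability $\kappa_o / (1 + \kappa_o)$ where
$\kappa_o = \kappa \cdot f_o / (1 - f_o)$, otherwise an idiosyncratic
(all-distinct) description; $\kappa \to \infty$ gives perfect agreement,
$\kappa = 0$ all-distinct names, and the coupling to familiarity $f_o$
produces the negative novelty–agreement correlation seen in human
norming. Hybrid and no-concept responses occur with probabilities 0.08
and 0.05. Default $\kappa = 3$.

All generator defaults live in one documented block
(`synthetic_defaults()`); every stochastic function takes a seed and
derives independent child streams (`child_seed()`), so identical
configurations reproduce bit-for-bit.

## Problem sizes used in the checks

Unit and property tests run on reduced sizes (typically 2–12 synthetic
participants, 4–50 SMACOF replicates, bootstrap $B \le 50$). The
acceptance script uses 1000 design restarts, 10 worlds × 50 replicates
for dimensionality recovery, and a full pipeline with 96 participants,
300 stress replicates per dimensionality and $B = 300$ bootstrap
replicates; these sizes were chosen so the whole script completes in a
few minutes while estimates of means and rates are stable to well within
the tolerances being checked.

## Known limitations

- Missing dissimilarities are rejected, not imputed: the metric pipeline
  assumes a covering design.
- Only Ward linkage and Lloyd k-means are provided; other linkages or
  soft clustering are out of scope, as are ordinal (non-metric) MDS and
  alternative deterministic initializations.
- The embedding-agnostic stability protocol ships only with the MDS
  embedding.
- Dendrogram and scree rendering is left to base plotting of the returned
  objects; no publication styling is included.
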