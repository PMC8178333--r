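---
title: "Methods: spatial statistics for fossil hook assemblages"
author: "crownmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial statistics for fossil hook assemblages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crownmap)
```

## The problem

Body chambers of some Late Cretaceous scaphitid ammonites preserve dozens
to over a hundred small hook-like sclerites, each assignable to one of nine
morphotypes: five major bicuspid classes `G1`–`G5` (with `G1`/`G5` and
`G2`/`G4` mirror images of each other), a very small bicuspid class `VSB`,
and rare tricuspid, unicuspid and rounded classes. Whether these hooks are
arm armature hinges on their *arrangement*: random scatter would suggest
taphonomic accumulation, whereas morphotype-wise clustering, fixed pairings
between mirror morphotypes, and coherent linear axes support an origin on a
brachial crown (paired files of hooks along arms or tentacle clubs).

`crownmap` provides the statistical machinery for that argument: per-hook
centroids from opening landmarks, nearest-neighbour morphotype composition
against an analytic random-labelling null, outlier-robust cross-morphotype
association, persistent-homology "links" within morphotypes, and the
reconstruction of candidate axes — together with a synthetic-specimen
generator so every stage is testable without access to the original
tomographic data, which is not publicly deposited in machine-readable form.

## Data model and assumptions

A hook is represented by the centroid of the four landmarks digitised on
its basal opening, taken as a proxy for its soft-tissue attachment point;
hook shape itself is *not* modelled, and morphotype labels are inputs, not
inferred. Coordinates are millimetres in an arbitrary specimen-fixed frame;
all statistics are invariant under rigid motion, and no registration across
specimens is attempted (specimens are only combined through summary
counts). Wherever an ordering tie-break is needed (nearest-neighbour ties,
filtration ties, path orientation), the smaller hook id wins; ties have
measure zero for real coordinates, so this only pins down determinism.

## Nearest-neighbour composition and its analytic null

For every hook, the unique nearest neighbour by centroid distance is found
among all other hooks. For morphotype $m_i$ with $N_{m_i}$ of the $N_{tot}$
hooks, the expected number of $m_i$ hooks whose nearest neighbour is also
$m_i$, if labels were assigned at random over the fixed positions, is

$$E_{m_i\text{-}m_i} = \frac{N_{m_i}-1}{N_{tot}-1}\,N_{m_i},$$

and after removing each hook's own morphotype from consideration (and
excluding outliers, primed counts), the expected number of $m_i$ hooks
whose nearest *other-morphotype* hook is an $m_j$ is

$$E_{m_i\text{-}m_j} = \frac{N'_{m_j}}{N'_{tot}-N'_{m_i}}\,N'_{m_i}.$$

Both are exact expectations under label exchangeability — the first because
the neighbour of a hook is equally likely to carry any of the remaining
labels, the second because the first non-$m_i$ entry of a hook's distance
ranking is uniform over the non-$m_i$ hooks. They satisfy
$\sum_{j\ne i}E_{m_i\text{-}m_j}=N'_{m_i}$ identically, which the test
suite asserts, and `permutationNull()` provides a Monte Carlo cross-check
of both. Results are reported as observed counts, expectations and their
ratio as a percentage (one decimal; `n/a` when the expectation is zero);
across specimens, aggregation is sum-of-observed over sum-of-expected, not
a mean of ratios. Morphotypes with fewer than 3 representatives are
flagged: their ratios are reported but should not be interpreted, and the
package's own association summaries ignore them.

## Outlier exclusion

Because same-morphotype clustering biases the cross-morphotype counts (a
stray hook far from its own cluster acquires arbitrary neighbours), hooks
far from the cluster formed by the rest of their morphotype are excluded
before the cross analysis using the 1.5×IQR rule. The per-hook statistic is
the **mean** centroid distance to the other hooks of the same morphotype —
chosen over the nearest-distance alternative (exposed as
`stat = "nearest"`) because it measures distance *to the cluster as a
whole* and is insensitive to a lone nearby companion; quartiles use linear
interpolation (R's default type 7, the convention of the analysis
environment this workflow targets); only the upper fence
$Q_3 + 1.5\,\mathrm{IQR}$ is applied, since only "far apart" hooks are
outliers; and the rule is skipped for morphotypes with fewer than 4 hooks,
where quartiles are meaningless.

## Persistence, links and their retention

`ripsPersistence()` is a self-contained Vietoris–Rips implementation for
dimensions 0 and 1. Dimension 0 is union-find over edges sorted by length
(elder rule, ties towards the smaller minimal hook id); its death times
coincide with single-linkage merge heights, which the tests assert against
`stats::hclust`. Dimension 1 uses the standard boundary-matrix reduction
over GF(2), with edges and triangles entering at their longest-edge scale
and simplices ordered by (scale, dimension, lexicographic ids); the
reduction is compiled (C++) and practical to a few hundred points, well
beyond the observed maximum of 171 hooks in one specimen. `maxScale`
defaults to the cloud diameter so the filtration completes; at these sizes
truncation buys nothing. `diagramDistance()` implements the bottleneck
distance by binary search over candidate costs with a bipartite matching
feasibility test, and is used in the tests to compare diagrams at 1e-9.

The "links" of a morphotype are the $n-1$ component-merging edges of its
dimension-0 filtration — equivalently its Euclidean minimum spanning tree,
with edge strength equal to the merge scale. Display and downstream stages
retain the strongest, best-integrated links: strength at or below the Tukey
upper fence of all strengths. One guard is added to the plain fence: when
strengths are nearly constant (a clean imbricated file), the IQR collapses
towards zero and sampling noise alone would split genuinely continuous
files, so the fence is floored at twice the median strength. A link longer
than twice the typical step is a break; anything shorter is kept.

## Axis reconstruction

An "axis" is a qualitative notion in this field — link diagrams are drawn
per morphotype and the axes indicated by eye — so the construction here is
this package's own formalisation, validated by parameter recovery on
synthetic data. A geometric observation drives the
design: in a paired arrangement (two imbricated files side by side, the
within-file step smaller than the file separation, which is exactly the
regime in which same-morphotype nearest-neighbour clustering holds), the
minimum spanning tree of the *union* of both files is two chains joined by
a single rung, and its diameter path can never traverse both files — any
path-based axis on the union systematically misses about half the pair's
hooks. The two files, not their union, are the linear objects.

`inferAxes()` therefore works per morphotype file: for each morphotype of
a pair, the retained-link graph's largest component is reduced to its
diameter path (the longest shortest path by edge length — deterministic
and parameter-free, computed by a double sweep, exact on trees); the two
file paths are then merged into a single ordered axis, using the longer
path as the spine and interleaving the other file's hooks at their nearest
spine position, with the secondary file's direction aligned by rank
correlation. Each axis reports its member hooks in order, arc-length
coordinates, total length, straightness (end-to-end distance over path
length — arcs score below 1; note that the interleaved ordering zigzags
between the files, so even a straight paired axis scores well below 1),
and coverage: the fraction of the pair's retained hooks on the axis.
Pairs with fewer than 4 retained hooks are skipped.

`basalPositionScore()` quantifies "small morphotypes at the axis base": the
fraction of basal-group hooks (default `G3` + `VSB`) whose nearest axis
hook lies in the first quartile of the axis ordering. The algorithm cannot
know anatomically which end is the base, so both orientations of every
axis are scored and the maximising combination is reported alongside all
orientation scores — under a uniform arrangement the unmaximised score sits
near 0.25, and readers should remember the maximisation when interpreting
values near that floor.

## The synthetic world

`syntheticConfig()` encodes the arrangement the analysis is meant to
detect; its defaults are the package's statement of a well-preserved
specimen and are deliberately not tuned per experiment:

* **two straight axes** of 50 hooks each, populated by the mirror pairs
  `G1`+`G4` and `G2`+`G5` — matching the reported pattern of up to two
  axes with at most about 60–70 hooks per axis;
* **imbrication step 1.5 mm** along each file: hooks are 2–5 mm
  structures described as imbricated, so consecutive same-file hooks
  overlap at sub-hook-size spacing;
* **lateral offset 2 mm** between the files of a pair ("side by side,
  nearly touching"), staggered by half a step — larger than the step, so
  each hook's nearest neighbour is usually its own file (the clustering
  signal), yet small enough that the pair forms one physical structure;
* **basal group of 14** small hooks (`G3`, `VSB`) in two adjacent blobs
  (1 mm SD, centres 3 mm apart) just proximal of the axis bases —
  morphotype-wise clustering applies to the small classes too, so they are
  not mixed into a single blob;
* **two hooks each** of `TRI`, `UNI`, `RND` scattered uniformly (the rare
  classes are about 2% of hooks);
* **jitter 0.3 mm SD**, isotropic — landmarking error plus mild
  taphonomic displacement, an order of magnitude below the imbrication
  step;
* **chamber ellipsoid 45 × 25 × 20 mm semi-axes** — a body-chamber-like
  volume for an adult macroconch, the support of the uniform null and of
  scrambled hooks;
* **scrambleFraction** relocates that fraction of hooks uniformly in the
  chamber: the simplest mechanism spanning clustered to chaotic
  preservation states. At 1 the clustered generator is statistically
  indistinguishable from `generateNull()`, and the clustering ratio
  degrades monotonically in between (both asserted in the tests).

The defaults give 120 hooks, inside the observed 40–168 range;
`generateSuite()` varies per-axis counts to emulate a multi-specimen
study. Arc geometry (radius 25 mm, span 120°) replaces the straight lines
on request. Landmarks are synthesised as 1 mm squares centred on each hook
position, so centroid recovery is exact by construction.

What the generator does *not* emulate: shell and chamber wall geometry
(hooks may jitter slightly outside the ellipsoid), cusp orientation
("cusps pointing outward" is untestable without cusp landmarks), size
gradients along axes beyond the basal group, inter-specimen registration,
and any biomechanics of arm retraction. A green recovery test therefore
establishes that the algorithms detect the *stated* arrangement under the
stated noise — not that real assemblages look like this world.

## Numerical choices

* Quartiles: type 7 everywhere (outlier fences, link retention).
* Ties: smaller hook id, everywhere; stable sorts in the filtration.
* Stability: moving every point by at most ε changes any pairwise
  distance, hence any Rips bar endpoint, by at most 2ε; the tests assert
  the 2ε bound via the bottleneck distance.
* Coordinates serialise with 9 decimals, making file round trips
  identities to 1e-9 mm.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; identical inputs and seeds give byte-identical
  outputs, which the pipeline tests assert.

## Known limitations

* **Null-world axis coverage.** Matched random specimens show no
  nearest-neighbour clustering (aggregate ratio ≈ 100%), but their
  "axes" are not as incoherent as one might hope: minimum spanning trees
  of ~25 uniform points in a bounded chamber are themselves fairly
  path-like, so diameter-path coverage under the null concentrates near
  55–60% rather than below 50%. The package reports this honestly; axis
  coverage alone does not separate clustered from random worlds at these
  sample sizes — the nearest-neighbour ratios do.
* Ratios are descriptive; no significance testing is attempted (the
  permutation machinery exists but the headline analysis follows the
  descriptive ratio convention).
* Persistence is limited to dimensions 0–1 and exact reduction; no
  sparse/approximate variants, so point clouds beyond a few hundred
  points become slow.
* The basal score's orientation maximisation inflates small scores (see
  above); interpret values near 0.25–0.4 as uninformative.
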