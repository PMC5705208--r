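---
title: "Methods: the random-placement null model and the no-reflow analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the random-placement null model and the no-reflow analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the models and
procedures it implements, the parameters that matter, what the synthetic
generator does and does not emulate, and the numerical and design choices
that were genuinely open.

## The question and the data model

After transient occlusion of a coronary artery, a fraction of capillaries
remains unperfused even once the artery is reopened. The hypothesis under
test is that these blockages are caused by contractile pericytes, in which
case blockage sites should sit closer to pericyte somata than random
placement along the blocked capillaries would put them.

The package starts from a geometric abstraction of a confocal image: a
`capillary_graph` holds polyline segments (µm coordinates), a partition of
segments into named capillaries, the imaged field bounds, pericyte soma
positions (arc positions denote the soma mid-point; a `visible` flag marks
somata inside the field) and blockage positions. Segment ends sharing a
coordinate are one node; all distances are geodesics along the vessel,
computed via shortest paths on the node graph (delegated to `igraph`) plus
the within-segment offsets. Segmentation of raster images into such graphs
is out of scope: the analysis begins at the geometry.

## The exact random-placement null

For a blockage placed uniformly along the imaged arc length $L$ of one
capillary, the distance to the nearest visible soma has a distribution
that can be computed exactly rather than by simulation. The key
observation is that on any subinterval of a segment that contains no soma,
the distance to each candidate soma is affine in the arc coordinate with
slope $+1$ (routes leaving through the segment start) or $-1$ (routes
through the end); the nearest-soma distance is the lower envelope of these
affine functions, i.e. $\min(c^+ + s,\; c^- - s)$ with at most one kink
per subinterval. Each linear piece of length $\ell$ maps uniform arc
measure to uniform distance measure, contributing probability mass
$\ell/L$ spread evenly over its distance range; summing the pieces yields
a piecewise-linear CDF (`image_null_cdf()`). For a single soma at distance
$A$ from one end of an unbranched capillary this reduces to the density
$2/L$ below $A$, $1/L$ between $A$ and $L-A$, and $0$ beyond.

Branching and image truncation are handled by the same construction: only
the imaged extent contributes to $L$, and all imaged visible somata on the
capillary compete. Per-image CDFs are averaged (equal weight per image by
default; a length-weighted variant exists for sensitivity analysis) and
the pooled CDF can be reduced to $n$ quantiles at probabilities
$(i - \tfrac12)/n$ (`equiprobability_sample()`), mirroring how a smooth
prediction is compared with $n$ observations. The midpoint convention
keeps the top quantile finite for approximations with unbounded support;
the $i/n$ convention is available as a switch. The idealized reference —
somata exactly every 60 µm on an infinite unbranched capillary — gives a
CDF rising linearly to 1 at 30 µm (`linear_null()`).

The exact computation is verified in the test suite against a brute-force
oracle that samples the nearest-soma distance every 0.01 µm and
integrates the level indicator per cell. Because a sampled oracle carries
an irreducible quantization error of order (step × density) at arbitrary
coordinates, the oracle geometries are drawn on a 0.02 µm lattice, which
places every kink of the distance function on a cell edge and makes the
oracle an exact integrator; agreement is then at machine precision over
200 randomized straight and branched geometries.

## Observed distances and the comparison

`observed_distances()` measures each annotated blockage to its nearest
visible soma (blockages with no reachable visible soma are excluded, and
the null model excludes the same capillaries). The median uses the
mid-rank convention. `compare_to_null()` reports a one-sample
Kolmogorov–Smirnov test against the continuous pooled null as the primary
comparison, and a two-sample KS against the equi-probability sample for
parity with comparing two equally-sized empirical distributions; neither
is privileged in serialized output, since the original analysis compared
two 42-point distributions without stating the test variant.
`pericyte_association()` bundles observed distances, the fitted null and
both comparisons into a single model-style object with `print()`,
`summary()` and `plot()` methods.

## Blockage detection in lumen profiles

A blockage appears in a lumen intensity profile as an abrupt fall of the
perfusion-marker signal over a few microns. "Abrupt" is operationalized —
the choice is the package's own — as: after background subtraction and
normalization to the upstream plateau (median of the first 25% of
samples), the signal falls from ≥ 0.8 to ≤ 0.2 within at most 5 µm; the
call position is the 0.5-crossing by linear interpolation. All four
thresholds are arguments of `detect_block()`. Crossings that share an
upstream shoulder are one candidate; if several distinct drops qualify,
the most upstream is returned with a warning. `aggregate_profiles()`
aligns profiles at their calls, resamples to a common grid and averages
with per-point s.e.m. (undefined and flagged at n = 1).

## Perfusion and diameter quantification

Per heart, 12 ROI intensities ordered clockwise from the mid-septum are
divided by that heart's maximum; hearts are averaged per condition; and
each condition's curves are rescaled by one common factor so its own
ROIs 1–3 mean equals 1 (`normalize_rois()`). ROIs 1–3 lie outside the
risk zone in every condition, which is why a per-condition factor is the
default; a shared sham-reference factor is available. The risk-zone
statistic is the per-heart mean over ROIs 7–10; contrasts (ischaemia vs
sham deficit, adenosine vs ischaemia rescue) are percent changes of
condition means, tested on per-heart values — hearts, not ROIs, are the
experimental units.

Transect counting (`transect_counts()`) draws a line through the field
centre perpendicular to the dominant capillary axis and classifies each
crossing capillary as perfused or blocked; in the synthetic data a
capillary carrying a blockage annotation counts as blocked, since the
generator does not model partial filling at the transect position.
Blocked percentages average per-image fractions (images as units,
unweighted), matching mean ± s.e.m. reporting with image counts.

Diameter analysis forms the ratio d_soma/d_upstream per pericyte (lumen
diameter at the soma and 10 µm upstream), reports condition means ±
s.e.m., percent changes of the mean soma diameter between conditions,
one-sample tests of the ratio against 1, and gated pairwise tests
corrected within the panel family.

## The statistical protocol

`auto_compare()` encodes the selection protocol: Shapiro–Wilk normality in
each group (gate p ≥ 0.05 — the protocol names the test, the threshold is
the package's choice), then an F test of variances (same gate) choosing
Student versus Welch t; any normality failure routes to Mann–Whitney
(mid-rank ties, exact p for small untied samples, normal approximation
with continuity correction otherwise). Every result carries its selection
trace for audit. The multiple-comparison rule multiplies the most
significant of N p-values by N, the next by N − 1, and so on, clamped at
1; by default no monotonicity is enforced across ranks, which follows the
rule as stated literally — a `monotone = TRUE` flag makes it identical to
step-down Holm–Bonferroni. `min_sample_size()` searches the smallest
per-group n (floor 2) whose two-sided two-sample t-test power, from the
noncentral-t distribution with noncentrality $\delta/\sigma\sqrt{n/2}$
and $2n-2$ df, reaches the target; distributional routines are delegated
to `stats`, the search and the protocol are implemented here.

## The synthetic-data generator

`generate_bed()` emulates the measured structure of a left-ventricular
capillary bed: 26 parallel capillaries spanning a 160 µm square field,
sparse orthogonal connectors (15% of adjacent pairs), inter-soma gaps
gamma-distributed with mean 60 µm and CV 0.35 (the gamma is the package's
choice of a positive, CV-parameterized family; the underlying data show
variability around the mean without naming a distribution), and soma
coverage of 92% of parallel versus 66% of connector capillaries. Observed
within-image gap means sit slightly below 60 µm because long gaps are
less likely to fit inside the field — the same truncation a real image
imposes.

`assign_condition()` blocks each capillary independently with probability
3% (sham), 40% (ischaemia) or 30% (ischaemia + adenosine). In
`"associated"` mode the blockage is offset from a randomly chosen soma by
a half-normal distance scaled so its median is 3.6 µm (exponential
available; the observed median is the only constraint the data provide,
so a one-parameter family parameterized by its median is used); in
`"random"` mode placement is uniform over the capillary — exactly the
generative counterpart of the null model, which is what makes the KS
calibration testable. Diameter pairs are drawn per condition with soma
diameter mean 5.38 µm (s.d. 1.25 µm, converted from s.e.m. × √n at
n = 20) in sham, reduced 37% under ischaemia and recovered 21% under
adenosine (s.d. scaled to preserve the coefficient of variation, a choice
the data do not constrain), and ratio means/s.d.s of 1.058/0.067,
0.822/0.170 and 0.822 × 1.21/0.170 — the adenosine ratio assumes the
upstream diameter is unchanged by adenosine, consistent with a
soma-specific action. Each blockage gets a sigmoid lumen profile (10–90%
fall width 3 µm, additive noise s.d. 0.05, background offset 0.1,
0.25 µm sampling over 40 µm).

`generate_ventricle_map()` builds 12-ROI maps: baseline 1, posterior
(ROIs 4–6) elevation ×1.2 (the data say "somewhat higher"; 20% is the
package's choice), risk-zone multipliers 1 / 0.51 / 0.51 × 1.57, and
multiplicative log-normal noise at heart and ROI level (s.d. 0.10 each,
chosen so cohort contrasts at 5/6/8 hearts have realistic spread).
`generate_study()` writes the full dataset — graph directories, profile
CSVs, cohort ROI and diameter tables — with a manifest of derived seeds
sufficient for byte-identical replay.

What the generator does **not** emulate: partial filling at a transect,
spatially correlated blockage of neighbouring capillaries, per-heart
clustering of diameters, curved or three-dimensional vessels, soma-size
effects on local diameter, or imaging noise in the geometry itself.
Passing tests therefore demonstrate that the pipeline recovers known
population parameters from data with the study's structure and sampling
variability — not that it is robust to segmentation error or biological
correlation structure absent from the generator.

## Numerical choices and degenerate inputs

* CDFs are piecewise linear with strictly increasing breakpoints; pooling
  evaluates at the union of breakpoints, which is closed for piecewise
  linear functions, so no resampling error accrues. Quantiles invert by
  linear interpolation; within a flat stretch the left-most distance is
  returned.
* Nearest-soma ties break to the lowest soma index; blocked capillaries
  with no visible soma signal errors from the null model and are excluded
  (with a warning) by the distance measurement, keeping both sides of the
  comparison on the same support.
* Zero-length capillaries, empty image sets, all-zero perfusion maps,
  non-positive diameters and out-of-range p-values all signal immediately
  rather than propagating NaN.
* All generator randomness flows through per-artifact seeds derived
  deterministically from one master seed; the caller's RNG state is
  restored afterwards.

## Problem sizes used in the checks

The packaged checks run at the study's own scales: 25 image stacks per
condition for blocked fractions, 5/6/8 hearts for the perfusion cohorts,
20/60/60 diameter pairs, 42 images for the blockage-distance median, 200
randomized geometries for the oracle comparison, 1000 replicates for KS
calibration and 100 for power. These sizes make the recovery tolerances
(three standard errors of the simulated quantity) meaningful while the
whole suite completes in well under a minute per component.

## Known limitations

* The capillary-restricted soma search constrains candidate somata to the
  named capillary but measures the geodesic on the whole graph; on highly
  interconnected geometries a path may briefly leave the capillary. For
  tree-like beds (and the generator's geometry) the two notions coincide.
* The null model treats each image's blocked capillary set as given; it
  does not model selection effects in which capillaries get imaged.
* `intersoma_distances()` measures along the vessel by default; chord
  (Euclidean) distances are available since measurements made in a single
  imaging plane may correspond to either convention.
* The rank-multiplier correction without monotonicity can order corrected
  p-values differently from raw ones (e.g. 0.5, 0.6 → 1.0, 0.6); this is
  the literal rule, and the monotone flag restores the conventional
  behaviour.
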