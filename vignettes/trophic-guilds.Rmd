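---
title: "Estimating trophic structure from stable isotopes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating trophic structure from stable isotopes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoweb)
```

## The model

`isoweb` analyses benthic food webs through paired carbon and nitrogen
stable isotope measurements. A sample's isotopic composition is expressed
in delta notation, the per-mil deviation of its heavy/light isotope ratio
from an international standard (VPDB for carbon, atmospheric N~2~ for
nitrogen):

$$\delta = \left(\frac{R_{sample}}{R_{standard}} - 1\right) \times 1000$$

Two empirical regularities make these values informative about feeding
relationships. δ^15^N increases stepwise from diet to consumer by a
roughly constant trophic enrichment factor (TEF), ~3.4 ‰ per step (with
literature values up to ~5 ‰), while δ^13^C increases only weakly (~1 ‰
per step) and mostly records the primary carbon source. The continuous
trophic position of a consumer relative to an isotopic baseline is then

$$TP = \lambda + \frac{\delta^{15}N - \delta^{15}N_{baseline}}{TEF}$$

where λ is the trophic level occupied by the baseline. For reef webs
fuelled by photosynthetic production the natural baseline is suspended
particulate organic matter (SPOM), taken at λ = 1.

The assumptions are the standard ones: a single dominant primary source,
a constant TEF across taxa and levels, and tissue isotopic equilibrium
with diet. Where they fail (e.g. sponges hosting intense microbial
nitrogen cycling), TP values are still computed but should be read as
descriptive of the δ^15^N axis rather than of diet alone.

## Parameters that matter

* **TEF** (`tef_config()`): δ^15^N enrichment per step, default 3.4 ‰;
  δ^13^C enrichment, default 1.0 ‰ (used by the simulator and web
  metrics only). `tef_scan()` exposes the 3.4–5.0 ‰ sensitivity range.
  Misspecifying the TEF biases TP by exactly
  $(t-\lambda)(TEF_{true}/TEF_{used} - 1)$, a closed form the test suite
  verifies.
* **λ** (`build_baseline(lambda=)`): baseline trophic level, default 1.
* **Baseline pooling**: group-level means are pooled *unweighted*
  (`pool_groups(weighted = FALSE)`), i.e. each SPOM pool counts once
  regardless of how many filter samples went into it. This is the
  convention that reproduces published pooled baselines from group
  summaries; replicate-weighted pooling is available behind the flag.
* **Uncertainty**: TP spread is propagated linearly, `sd(δ15N)/TEF`,
  with baseline and TEF held fixed — the convention behind published
  "TP ± s.d." columns. Adding the baseline variance in quadrature is
  available via `include_baseline_sd = TRUE`.
* **Aggregation**: the sample (n−1) standard deviation is used
  throughout; spreads are reported as absent (not zero) for singletons.

## Guild detection

Trophic guilds are found by k-means on the (δ^13^C, δ^15^N) plane.

* **Axes**: raw per-mil values by default (`scale = FALSE`). The two
  axes have comparable units and their unequal ranges are themselves
  ecological signal; a z-score option exists and the choice is recorded
  in every fit and report.
* **Algorithm**: Lloyd iterations from k-means++ seeding, best of
  `n_init = 100` restarts by WSS (squared Euclidean, ‰²), assignment
  ties to the lowest cluster index, empty clusters repaired by
  re-seeding on the farthest point, convergence when assignments
  stabilise or centroids shift < 10^-10^ ‰. On point sets small enough
  to enumerate (≤ 8 points) the restart policy attains the
  exhaustive-search optimum in every tested draw.
* **Number of clusters** (`select_k()`): three diagnostics on one grid —
  the elbow, the mean silhouette width, and the gap statistic with a
  uniform reference over the data's bounding box and the one-standard-
  error rule. Disagreement is resolved by majority, ties to the smallest
  k, and all three curves are always reported. The elbow is computed on
  the *log*-WSS curve (maximum relative-drop curvature): on the raw
  curve the first split's drop dominates whenever the one-cluster
  dispersion is large, so the heuristic would name k = 2 for any
  strongly separated data regardless of structure.
* **Labelling**: clusters are renumbered 1..k by ascending mean δ^15^N,
  so cluster 1 is always the baseline-like (POM) guild.

A degenerate geometry worth knowing about: for equal blobs on a perfectly
symmetric square, the best 2-partition removes exactly the share of
dispersion a uniform reference loses, so the gap statistic's
one-standard-error rule legitimately stops at k = 1. The validation suite
therefore plants blobs in generic position (pairwise separations ≥ 10,
no symmetry).

## What the synthetic generator emulates

`simulate_web()` draws from the same generative structure the estimator
assumes: source pools with Gaussian scatter; consumer taxa whose true
mean is `source + (t − 1)·(TEF_C, TEF_N)` plus a Gaussian taxon-level
offset; Gaussian replicate noise around each taxon mean. Everything is
reproducible from a mandatory seed.

The default scenario (`default_web_spec()`) mirrors a reef-like web: one
SPOM source at (−21.9, 4.2) ‰ with spread (0.45, 1.6) ‰ — the observed
SPOM scatter — and three consumer guilds at trophic levels 3.5, 4.2 and
5.7 with 14, 4 and 5 taxa, taxon offsets of 0.5 ‰ per axis, replicate
noise of (0.2, 0.5) ‰ matching typical analytical precision, three
replicates per taxon and twenty source samples.

What it does **not** emulate — and hence what passing recovery tests do
not establish for field data: correlated noise between the two axes,
taxon-specific or level-dependent TEFs, multiple partially-mixed carbon
sources, depth structure, and non-Gaussian outliers (opportunistic
feeders produce heavy-tailed spreads). Recovery results should be read
as "the pipeline inverts its own generative model", which is the
property the tests are designed to pin down.

The Monte-Carlo recovery harness uses four guilds at t = 1, 3.5, 4.2,
5.7 with taxon offsets of 0.5 ‰ and ten taxa per guild. Ten is chosen so
that a single boundary mis-assignment among 40 taxa still leaves the
adjusted Rand index near 0.93: the closest guild pair is separated by
about 2.4 within-guild standard deviations, making mis-assignments rare
(expected ≈ 0.13 per web) but not impossible, and the pass criterion
(ARI ≥ 0.9 in ≥ 95 % of 200 seeds) should not hinge on whether exactly
one taxon crossed a boundary.

## Numerical choices

* Display rounding is half-away-from-zero at two decimals
  (`round_half_up()`), the convention of published isotope tables, with
  a 10^-9^ guard against binary representation (4.225 must display as
  4.23). All computation is at full double precision; only reports
  round.
* Full-precision versus printed-precision baselines differ visibly in
  the last display digit: the pooled SPOM baseline is 4.225 ‰, printed
  4.23 ‰, and the highest guild's mean TP displays as 5.70 or 5.69
  accordingly. Comparisons against published tables feed the
  printed-precision baseline; the API never rounds internally.
* Degenerate inputs error early and descriptively: empty group sets,
  k exceeding the number of distinct points, all-identical points in
  the gap statistic, zero-variance vectors in the correlation, negative
  spreads anywhere.
* The WSS curve across k is made monotone by construction (each k is
  warm-started from the previous solution plus farthest points), not by
  post-hoc sorting.

## Problem sizes

The validation suite runs entirely on synthetic data plus the 29-group
packaged fixture: exhaustive k-means enumeration on 100 random sets of
4–8 points; gap-statistic decisions on 25–40-point blob layouts with 50
reference sets across 5 seeds; membership stability on the fixture
across 10 seeds with 100 restarts; 200-seed guild recovery at 40 taxa
per web; and a 10^4^-replicate web for the uncertainty-propagation
check. These sizes keep the full suite under a few minutes on one core
while leaving each decision's Monte-Carlo error well inside the asserted
tolerances.

## Known limitations

* TP is a single-baseline, single-TEF summary: no Bayesian estimation,
  no isotope mixing models, no source-attribution percentages, no
  compound-specific corrections.
* The δ^13^C–δ^15^N Pearson correlation of a published study computed on
  sample-level replicates cannot be reproduced from group-level means
  (different n and variance structure); the estimator is validated
  against a covariance oracle and its invariances instead.
* k-means presumes convex, similarly-sized guilds in isotope space;
  elongated or nested isotopic niches would call for model-based
  clustering, which is out of scope.
* Published tables round inputs to two decimals, so recomputed per-taxon
  TPs can differ from published ones by up to 0.01 — the tolerance used
  when comparing.
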