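---
title: "Partitioning beta diversity on island systems: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning beta diversity on island systems: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betanest)
```

## The problem

On recently fragmented landscapes — archetypally, hilltops turned into
land-bridge islands by reservoir inundation — all sites inherit a common
species pool, and compositional differences among them accumulate through
two distinct processes: **replacement** of species from site to site
(turnover) and **selective loss** that leaves poor sites nested inside rich
ones. A broad-sense dissimilarity index returns the same number for both,
so `betanest` is organized around decompositions that keep them separate,
plus the auxiliary statistics needed to interpret them (nestedness null
tests, species–area models, distance-matrix regressions).

## The partition

For two sites with `a` shared species and `b`, `c` exclusive species,
Sørensen dissimilarity `(b + c) / (2a + b + c)` splits into Simpson
dissimilarity `min(b, c) / (a + min(b, c))` — pure turnover, insensitive to
richness differences — and the nestedness-resultant remainder. The
remainder equals the product of the richness-difference fraction
`|b − c| / (2a + b + c)` and the Simpson similarity `a / (a + min(b, c))`,
an identity the tests verify to 1e-12: it is dissimilarity *caused by*
richness differences between nested assemblages, not a measure of
nestedness itself. The multiple-site forms replace `b` and `c` by the sums
of pairwise exclusive richness `Σ min(b_ij, b_ji)` and `Σ max(b_ij, b_ji)`
and `a` by `Σ S_i − S_T`; at n = 2 they reduce exactly to the pairwise
partition, which the tests use as an oracle. Jaccard and Carvalho variants
are provided for robustness checks; all three families are additive by
construction.

Conventions worth stating once:

* Sites are rows internally, whatever the orientation of the input file.
* Pairs (or site sets) with no species at all are an error, not a zero:
  empty inventories are excluded (`drop_empty_sites()`) before analysis,
  mirroring field practice, and `beta_ratio` at `beta_SOR = 0` is signalled
  as undefined rather than silently classified.
* `beta_ratio < 0.5` labels a system turnover-dominated, `> 0.5`
  nestedness-dominated. Because multiple-site values grow with the number
  of sites, cross-system comparisons use `resampled_multisite()`: samples
  are drawn **without replacement within a sample** (subsets of
  inventories, not a bootstrap), independently across samples, and spread
  is reported as the sample SD.

## NODF and the PP null

NODF scores, per pair of lines of one axis, the percentage of the poorer
line's presences shared with a strictly fuller line; equal fills contribute
zero (the "decreasing filling" condition, implemented with a strict
inequality). Axis scores are means over unordered pairs; the total pools
both axes. The metric depends only on marginal totals and overlaps, so it
is permutation-invariant and `max_pack()` (stable sort by decreasing
marginals) is cosmetic — a property the tests check against brute-force
pair enumeration and against an independent implementation.

The null model is proportional–proportional: cell (i, j) is an independent
Bernoulli draw with probability `(f_row_i + f_col_j) / 2`, preserving fill
in expectation while letting marginals vary. Two decisions are open in the
literature and documented here as switches:

* Null samples that lose whole lines are **retained** with their empty
  lines removed before scoring (default), mirroring the empirical
  exclusion of empty islands and avoiding the bias of re-drawing;
  `drop_degenerate_lines = FALSE` discards such samples instead.
* The Monte Carlo p is **one-tailed in the direction of the observed
  deviation**, `(extreme + 1) / (n_used + 1)`, with the direction labelled
  `nested` or `anti-nested`. A Z score `(N_obs − mean) / SD` accompanies it
  and is recomputable from the reported mean and SD.

## Distance-matrix association

Attribute differences are one-dimensional Euclidean distances, with island
area log10-transformed (areas span >3 orders of magnitude); whether to log
isolation (a fraction ≤ 1) is left as a caller choice since both
conventions are defensible. Geographic distance is the haversine
great-circle distance between site centroids in km.

Mantel statistics correlate unfolded upper triangles; the only
exchangeable unit of a distance matrix is the site label, so permutations
shuffle rows and columns simultaneously. The p-values are **two-sided**
with the +1 correction — negative correlations (e.g. turnover shrinking
with area difference) are substantively meaningful here, so a one-tailed
default would be wrong. The partial Mantel statistic is the first-order
partial correlation with the covariate (typically space), permuting the
focal matrix. At n = 4 the permutation null can be enumerated exactly
(4! relabelings), and the tests compare the sampled p against that oracle.

MRM fits OLS on the unfolded triangles with per-coefficient permutation
p-values (response labels permuted, two-sided on coefficient magnitude;
R² one-sided). Because the partition is additive and OLS is linear, MRM
coefficients for `beta_sor` equal the sums of those for `beta_sim` and
`beta_sne` on any shared predictor set — an exact identity the tests hold
to 1e-10. The pipeline reports both the simple and the space-partialled
Mantel r alongside MRM slopes, since printed figures in the literature are
often ambiguous about which is shown.

## Island models

All island variables are log10-transformed before correlation and
regression; base 10 is the convention that makes power-law species–area
coefficients readable (`log10 S = b + a log10 A`). Zero-richness islands
are **excluded** before the log rather than offset by default: with the
packaged attribute table this choice reproduces the lizard regression
coefficients to printed precision, whereas a +1 offset over all islands
does not; `zero_offset` remains available for callers who prefer an
offset. Backward stepwise selection uses `stats::step` with the standard
AIC penalty (k = 2) and never returns a model with higher AIC than the
full model. Two caveats belong with it: AIC retains an irrelevant variable
with probability ≈ 0.16 each, so "noise dropped" is a majority outcome,
not a near-certain one; and on the packaged bird data area-plus-isolation
beats area-only by ΔAIC ≈ 0.6 — an effective tie in which other selection
variants legitimately land on area only.

## What the generators emulate — and what they do not

`generate_nested()` ranks species and gives site k the top `richness_k`
species; `generate_turnover()` slides a fixed-width window along the
species list. Symmetric Bernoulli cell-flipping (`noise`) degrades either
archetype continuously; because flips change richness, a
richness-preserving variant swaps presences and absences within sites.
`generate_mixture()` assigns each species to nested or turnover dynamics
with a weight, producing intermediate `beta_ratio` values for calibration.

`generate_island_system()` emulates the joint structure of the packaged
37-island system, and its defaults are calibrated to that table once:
log10-areas normal with mean 0.46 and SD 0.80 (the table's moments),
species–area law with slope 0.09 and intercept 1.34, `sar_sigma = 0.04`
(chosen so the law explains ≈ 3/4 of log-richness variance, matching the
observed R²), habitat richness tied to log-area with link strength 0.9
(observed log–log r ≈ 0.88), isolation normal (0.73, 0.11) and independent
of area. The attribute table keeps the *unrounded* law richness so that
noiseless parameter recovery is exact; the community realizes the rounded
count. Community assembly is ranked occupancy — strictly nested — so the
turnover component is exactly zero unless `noise > 0`.

Real incidence data differ in ways these generators do not imitate:
species' incidences are not independent (competition, habitat
associations), occupancy-frequency distributions are fatter-tailed, noise
is not symmetric, and spatial autocorrelation is absent (coordinates are
uniform jitter). Passing tests therefore demonstrate the *statistical
machinery* — additivity, invariances, null calibration, parameter
recovery — not that any particular empirical system behaves like the
generator. Dominance-regime tests run the nested generator at
`noise = 0.01`: the multiple-site turnover sum accumulates over all
O(n²) site pairs, so at 30 sites even 5% cell noise swamps nestedness
dominance — a property of the statistic, documented here so users do not
mistake it for a generator defect.

## Numerical choices and problem sizes

Additivity identities are asserted at 1e-12 (pairwise/multisite) and 1e-10
(MRM coefficients); distance-matrix symmetry at 1e-8. Ties in
`max_pack()` keep original order (stable sort). Degenerate inputs fail
loudly: all-empty matrices, constant triangles (correlation undefined),
covariates perfectly correlated with a response (partial r undefined),
collinear MRM predictors, `beta_SOR = 0` ratios. Permutation p-values are
never zero by construction (+1 correction). The test suite works at sizes
where exhaustive oracles are feasible (4-site Mantel enumeration,
brute-force NODF pairs) and uses 100–200 seed replicates for
recovery-rate properties; the acceptance script uses 1000 PP
randomizations and 999 Mantel permutations on a 37-island synthetic
system, all of which run in seconds.

## Limitations

Only incidence (0/1) data are supported — no abundance-weighted
partitions or WNODF. The PP null is the only null model; fixed-fixed
(swap/curveball) algorithms are out of scope. Isolation is taken as given
(a buffer-water fraction), not computed from GIS. The packaged attribute
table supports every attribute-level reproduction, but the study's full
incidence matrices are supplementary files of their publication and are
not redistributed; analyses needing them accept user-supplied CSVs, and a
clearly-labelled synthetic stand-in (`synthetic_tisl_community()`)
matching the published per-island richness exercises the same code paths.
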