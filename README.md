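# betanest

Beta diversity — the change in species composition among sites — confounds
two antithetic phenomena when measured with a broad-sense dissimilarity
index: **spatial turnover** (species replaced from site to site) and
**nestedness-resultant dissimilarity** (species-poor sites holding subsets
of the species of richer sites). `betanest` implements the incidence-based
machinery needed to tell them apart on fragmented landscapes such as
land-bridge island systems: community ecologists can partition pairwise and
multiple-site dissimilarity, test nestedness against a null model, and
relate each component to differences in island attributes.

## What it computes

**Pairwise partition** (Sørensen family): with *a* species shared by two
sites and *b*, *c* exclusive to each,

```
beta_sor = (b + c) / (2a + b + c)
beta_sim = min(b, c) / (a + min(b, c))
beta_sne = beta_sor - beta_sim
```

`beta_sim` (Simpson dissimilarity) captures turnover free of richness
gradients; `beta_sne` is the dissimilarity caused by nested richness
differences. The decomposition is exactly additive, as are the Jaccard and
Carvalho alternatives (`alternative_partitions()`).

**Multiple-site partition**: `beta_SOR = beta_SIM + beta_SNE` over n sites,
built from the pairwise exclusive-richness sums `Σ min(b_ij, b_ji)`,
`Σ max(b_ij, b_ji)` and the shared fraction `Σ S_i − S_T`. The ratio
`beta_ratio = beta_SNE / beta_SOR` classifies a system as
turnover-dominated (< 0.5) or nestedness-dominated (> 0.5);
`resampled_multisite()` standardizes comparisons between systems with
different numbers of inventories.

**Nestedness**: the NODF metric (0–100; per site pairs, species pairs and
total) with maximal matrix packing, and a Monte Carlo test against the
proportional-proportional (PP) null model, in which each cell is a
Bernoulli draw with probability equal to the mean of its row and column
fill fractions (Z score and one-tailed +1-corrected p).

**Distance-matrix association**: Mantel and space-partialled partial
Mantel permutation tests and multiple regression on distance matrices
(MRM) relating dissimilarity matrices to differences in island area
(log10), isolation and habitat richness; MRM coefficients inherit the
partition's additivity exactly.

**Island models**: Pearson correlations among log-transformed attributes,
power-law species–area regression (`log10 S = b + a log10 A`), and
backward stepwise selection by AIC.

**Synthetic data**: seeded generators of nested gradients, turnover
(sliding-window) communities, mixtures, and whole island systems with
calibrated lognormal areas, a species–area law, and area-linked habitat
richness — so every stage is testable with known truth.

The package ships the attribute table of a 37-island land-bridge study
system (`tisl_islands()`): coordinates, area (0.57–1289.23 ha), isolation,
habitat richness, and observed breeding-bird (60 species) and lizard
(5 species) richness per island.

## Worked example

```r
library(betanest)

attrs <- tisl_islands()
m <- synthetic_tisl_community("birds", seed = 7)  # synthetic stand-in

matrix_fill(m)
#> [1] 41.03604
richness_cv(site_richness(m))
#> [1] 0.2124147

multisite_partition(m)
#> Multiple-site dissimilarity over 37 sites
#>   beta_SOR = 0.9060  beta_SIM = 0.8826  beta_SNE = 0.0234
#>   beta_ratio = 0.0259 (turnover-dominated)

species_area_regression(attrs$richness_birds, attrs)
#> Regression of log10(richness) on log10-transformed area_ha
#>          term estimate std_error        p
#> 1 (Intercept)   1.3411    0.0079 1.12e-52
#> 2     area_ha   0.0910    0.0086 1.83e-12
#> R^2 = 0.7623, AIC = -126.66
```

The fill (41.0%), richness CV (0.21) and the species–area slope/intercept
(0.09 / 1.34, R² 0.76) are fixed by the published attribute table; the
dissimilarity values above describe the synthetic stand-in, not the real
communities. The full analysis — partition, resampling, NODF null test,
richness models and all Mantel/MRM associations — runs in one call:

```r
b <- reproduce_analysis(list(
  community = m, attributes = attrs, taxon = "birds",
  resample = list(subset_size = 29, n_samples = 100),
  nodf = list(n_sim = 1000), n_perm = 9999, seed = 1,
  out_dir = "results"))
```

which writes `results_birds.json` (full precision), `report_birds.txt`
(rounded) and the three pairwise dissimilarity matrices as CSVs.

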