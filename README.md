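# saltFCE

Non-destructive salt-tolerance grading of forage germplasm (alfalfa) from
hyperspectral imagery and LiDAR point clouds.

Screening salt-tolerant varieties traditionally requires destructive
measurements — fresh weight, dry weight, water content, SPAD chlorophyll —
that are slow and kill the material. `saltFCE` instead grades samples from
**computing phenotypic traits** extracted without contact:

* **16 narrow-band vegetation indices** (chlorophyll, anthocyanin,
  carotenol, LAI, water, stress and biomass proxies such as NDVI, TVI,
  ARI, CRI, WI, SWSI, CTR) averaged over a canopy mask obtained by
  thresholding the Triangular Vegetation Index at TVI > 10.6;
* **3 structural traits** from the canopy point cloud after a statistical
  outlier filter, sub-canopy voxel downsampling and moving-least-squares
  smoothing: grid plant height (mean of per-0.5 cm-cell maxima), canopy
  leaf area (occupied cells × cell area) and convex-hull volume.

## The grading model (FCE-E)

Given the n × m trait matrix A with per-trait polarity, the entropy-weighted
fuzzy comprehensive evaluation proceeds:

1. **Standardize** each trait to [0, 1] by min–max scaling (negative-sense
   traits are reversed: x ↦ (max − x)/(max − min)).
2. **Entropy weights.** With shares p_ij = x'_ij / Σ_i x'_ij, the
   normalized Shannon entropy is E_j = −(1/log₂ n) Σ_i p_ij log₂ p_ij and
   the weight is w_j = (1 − E_j) / Σ_k (1 − E_k): traits that barely vary
   across samples carry no discriminating information and get weight ≈ 0.
3. **Trapezoidal memberships.** Each standardized value is mapped to
   memberships in four grades (*Very tolerant, Intermediate, Susceptible,
   Very susceptible*) by complementary piecewise-linear functions with
   breakpoints x₁..x₆ = 0.2, 0.3, 0.45, 0.55, 0.7, 0.8 — transition bands
   of width 0.1 around the quartile critical values 0.25 / 0.5 / 0.75.
4. **Composition.** b_k = Σ_j w_j · r_jk (weighted-average operator); b
   sums to 1.
5. **Rating.** The maximum-membership grade wins, scored 100 / 75 / 50 /
   25; the defuzzified expected score Σ_k b_k·score_k is also reported as
   a continuous tolerance score.

A PCA baseline (`pca_composite()`: first principal component of the
z-scored traits as a composite score, sign-oriented toward a reference
trait) and trait-statistics tables (`trait_stats_table()`: coefficient of
variation, entropy divergence 1 − E, signed variance contribution rate)
support the comparisons; `consistency_rate()` and `rank_agreement()`
compare two rating procedures.

Because no reference data set ships with the method, the package includes
seeded generators with known ground truth: hyperspectral scenes with a
stress-severity knob (`make_scene()`), box / hemisphere / ellipsoid canopy
clouds with closed-form height, footprint and hull volume
(`make_canopy()`), and trait cohorts with a planted tolerance ordering
(`make_cohort()`).

## Worked example

Four synthetic samples — two watered controls, two salt-stressed — run
through the whole pipeline:

```r
library(saltFCE)
dir    <- tempfile(); dir.create(dir)
ids    <- c("CK-1", "CK-2", "NaCl-1", "NaCl-2")
stress <- c(0.05, 0.15, 0.6, 0.85)
rows <- lapply(seq_along(ids), function(i) {
  sc <- make_scene(scene_spec(rows = 24, cols = 24, stress = stress[i],
                              noise_sd = 0.004, seed = 100 + i))
  write_envi(sc$cube, img <- file.path(dir, paste0(ids[i], ".img")))
  cn <- make_canopy(canopy_spec("hemisphere", 12 - 4 * stress[i],
                                point_density = 8, seed = 100 + i))
  write_ply(cn$cloud, ply <- file.path(dir, paste0(ids[i], ".ply")))
  data.frame(sample_id = ids[i], cube = img, cloud = ply)
})
res <- run_pipeline(run_config(), list(samples = do.call(rbind, rows)),
                    file.path(dir, "report"))
res$fce
#> <fce_result>
#>  sample_id            grade score expected_score
#>       CK-1    Very tolerant   100       83.05699
#>       CK-2    Very tolerant   100       78.71421
#>     NaCl-1      Susceptible    50       48.59230
#>     NaCl-2 Very susceptible    25       46.83163
res$pca
#> <pca_result> PC1 explains 90.3% of variance
#>  sample_id pc1_score rank
#>       CK-1     4.027    1
#>       CK-2     2.833    2
#>     NaCl-1    -2.066    3
#>     NaCl-2    -4.794    4
res$rank_agreement
#> [1] 1
```

The stressed samples drop through the grade scale (higher red reflectance,
collapsed NIR plateau, smaller canopies), the 100/75/50/25 scores map the
winning grades, the expected score preserves the finer ordering, and the
PCA composite ranks the samples identically (rank agreement 1). The
report directory holds `traits.csv`, `ratings.csv`, `stats.csv`,
`pca.csv` and `report.json` with the resolved configuration echoed.

A command-line front end is installed at `exec/saltfce` with subcommands
`traits-hsi`, `traits-lidar`, `evaluate`, `stats`, `pca`, `compare`,
`simulate` and `run`.

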