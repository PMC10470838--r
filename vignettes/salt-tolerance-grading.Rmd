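---
title: "Grading salt tolerance from computing phenotypic traits: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading salt tolerance from computing phenotypic traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltFCE)
```

# The problem

Screening germplasm for salt tolerance needs a per-sample verdict that
integrates many weak signals: canopy structure shrinks under osmotic
stress, pigments shift, water content drops. Each signal alone is noisy
and none is decisive, so the package grades samples by fusing a
multi-trait evaluation index system — 16 narrow-band spectral indices plus
3 LiDAR structural traits, the *computing phenotypic traits* — through an
entropy-weighted fuzzy comprehensive evaluation (FCE-E). This vignette
records the model, its assumptions, the tunable constants and the design
choices made where the method description left the design open.

# Trait extraction

## Spectral traits

Input is a radiometrically calibrated reflectance cube (0–1 scale) over
400–1000 nm. Index formulas name wavelengths (e.g. R750); a real sensor
samples a grid (reference resolution 4.6875 nm), so each requested
wavelength resolves to the nearest band center, with ties to the shorter
wavelength and a 10 nm tolerance. Vegetation is segmented by thresholding
the Triangular Vegetation Index,

TVI = 0.5·(120·(R750 − R550) − 200·(R670 − R550)),

at TVI > 10.6 — strictly: boundary pixels are background. On the 0–1
reflectance scale the 120/200 multipliers put canopy TVI in roughly
10–30, soil near 0, which is why a single global threshold works. Each
index image is reduced to its arithmetic mean over vegetation pixels.
Pixels where a denominator vanishes become NaN and are excluded from the
mean rather than aborting the scene — an isolated dead pixel should not
kill a sample. No morphological cleanup is applied to the mask, and no
shadow handling: the method description specifies plain thresholding.

Two small conventions: `BN = log(R800/R550)` uses the natural log — any
positive log base differs by a positive scalar factor, which min–max
standardization removes, so no downstream number can depend on the
choice; and `SWSI = (R803 − R681)/√(R905 + R972)` takes the square root
of the band *sum*, exactly as printed in its source.

## Structural traits

The canopy point cloud (cm units) passes through a fixed filter chain and
then three extractors:

1. **Statistical outlier removal** — each point's mean distance to its
   `knn` nearest neighbours; points beyond mean + `std_multiplier` × sd of
   that statistic are dropped. Defaults knn = 16, multiplier = 2.
2. **Sub-canopy voxel filter** — points in the lower `canopy_fraction`
   (default 0.5) of the z range are replaced by one centroid per occupied
   `voxel_size` (default 0.25 cm) voxel. "Below the canopy" has no
   standard definition; the lower half of the height range is the
   operational choice, exposed in the configuration.
3. **MLS smoothing** — each point is projected onto the total-least-squares
   plane of its neighbours within `mls_radius` (default 1 cm); a degree-1
   fit is the lowest-order member of the moving-least-squares family and
   is sufficient to pull mixed points back to the leaf surface. Points
   with fewer than 3 neighbours pass through. Point count is preserved.
4. **Rebase** so min z = 0 (pot bottom = ground; no terrain model).

Then: **height** = mean over occupied 0.5 cm grid cells of the per-cell
maximum z (occupied cells only — an empty cell has no highest point);
**canopy leaf area** = occupied-cell count × cell²; **volume** = 3-D
convex hull volume. The grid is anchored at (min x, min y); occupancy is
≥ 1 point. Degenerate (coplanar) hulls raise an error rather than
returning 0, because a silent zero would corrupt the downstream min–max
standardization. The filter defaults are not prescribed anywhere in the
method description; the values above were chosen once so that the
synthetic fixtures with analytic ground truth are recovered, and all are
user-configurable.

The hull, kNN statistic and MLS projection are compiled (Rcpp/Armadillo);
the hull is an incremental algorithm returning both the volume and the
outward facet planes, which the test suite uses for an independent
Monte-Carlo point-in-hull volume check, alongside a cross-check against
an external computational-geometry implementation.

# The FCE-E model

With n samples and m traits (matrix A, entries X_nm, per-trait polarity):

**Standardization.** Positive traits map to (x − min)/(max − min),
negative traits to (max − x)/(max − min): every trait becomes
positive-sense on [0, 1]. A constant trait cannot be scaled; it is set to
0.5 with a warning and ends up with zero weight — never a division by
zero. Values outside [0, 1] (possible when scoring new samples against
stored extrema) are clamped.

**Entropy weights.** Trait j's values become shares
p_ij = x′_ij / Σ_i x′_ij — the standard entropy-weight construction for
continuous traits, rather than a histogram of repeated values, which
almost never repeat. The Shannon entropy is normalized by log₂ n so
E_j ∈ [0, 1]; without this normalization the divergence 1 − E could go
negative for n > 2, and reported per-trait "information entropy" tables
in this literature (low-variation traits near 0) are consistent with the
*divergence* d_j = 1 − E_j of the normalized entropy, which is what the
statistics table exposes as its `h` column. Weights are
w_j = d_j / Σ d_j; if every trait has maximal entropy there is no
discriminating information and the fit aborts with an explicit error.

**Memberships.** Four complementary trapezoids on [0, 1] with breakpoints
x₁..x₆ = (0.2, 0.3, 0.45, 0.55, 0.7, 0.8): transition bands of full width
0.1 centred on the quartile critical values 0.25, 0.5, 0.75. The printed
description mixes a "fuzzy boundary 0.1" with the example band 0.2–0.3
(width 0.1) and the pair 0.45/0.55 (also width 0.1), so 0.1 is read as
the *full* band width (`fuzzy_halfwidth` = 0.05); the breakpoints remain
directly settable. The four functions are exactly complementary, so for
every x in [0, 1] the memberships sum to 1 — asserted on a dense grid in
the tests. Negative traits were already reversed during standardization,
so a single positive-sense function family serves all traits. "Adaptive
parameter adjustment" is realized structurally: because the data are
standardized to [0, 1], quartile critical points are data-independent and
need no per-data-set refitting.

**Composition and rating.** b_k = Σ_j w_j·r_jk (the
multiplication–addition, i.e. weighted-average, operator; min–max and
bounded-sum operators are out of scope by design). The grade with maximal
b_k wins and is scored 100/75/50/25. Ties are broken toward the more
tolerant grade and flagged in the output — the method description is
silent on ties, and an explicit flag beats an invisible convention. The
defuzzified expected score Σ_k b_k·score_k is reported as a continuous
tolerance score; it is non-decreasing in every standardized trait
(checked numerically), which makes the grading monotone: improving any
trait can never lower a sample's score.

# Comparison machinery

* **Coefficient of variation**: sample sd (n − 1 denominator — the
  description does not say which; n − 1 is the documented choice) over
  the mean.
* **Variance contribution rate**: the published tables are signed and sum
  to ≈ 1, which rules out squared-loading or variance-share definitions;
  the implemented definition is each trait's PC1 loading (z-scored
  traits, PC1 oriented toward a reference trait) normalized by the sum of
  loadings. This is a documented interpretation, not a certified formula.
  Constant traits are excluded from the PCA with a warning and reported
  as NA.
* **PCA composite**: PC1 of the correlation structure as composite score;
  the sign of an eigenvector is arbitrary, so it is fixed by requiring
  positive correlation with a named reference trait (default NDVI for
  computing traits; FW would be the natural choice for measured typical
  traits). Ranks are dense 1..n, rank 1 = best.
* **Consistency rate**: fraction of samples with identical grades across
  two rating sets. **Rank agreement**: Spearman correlation (average
  ranks on ties) between FCE-E expected scores and PC1 scores.

# The synthetic world

No accession data are deposited with the method, so the generators state
a world explicitly:

* **Scenes** (`make_scene`): background is a smooth soil ramp; vegetation
  is a parametric spectrum — visible floor, 550 nm green peak, logistic
  red edge to a NIR plateau, 970 nm water dip. The stress knob s ∈ [0, 1]
  raises red reflectance, lowers the NIR plateau and shallows the water
  dip, all monotonically, so masked NDVI strictly decreases in s. These
  are smooth parametric curves, *not* radiative-transfer output: they
  exercise every index formula and the TVI threshold but say nothing
  about real alfalfa optics. Gaussian pixel noise with stated sd.
* **Canopies** (`make_canopy`): box, hemisphere or half-ellipsoid
  surfaces rastered on a scanner-like regular grid with spacing
  1/√density, Gaussian jitter (default 0.02 cm), plus labelled outliers
  sampled uniformly in the 2× inflated bounding box and kept clear of the
  surface so the default statistical filter can remove exactly the
  planted set. Box faces are inset by half a laser-spot diameter
  (0.05 cm): a scanner measures patch centers, never the mathematical
  edge — without the inset, a box whose side is an exact multiple of the
  grid cell straddles one extra row of cells and the occupied-cell area
  acquires a systematic +5% quantization bias that says nothing about the
  extraction code. Ground truth: box values are exact; dome footprint
  πab and volume (2/3)πabc are closed-form; dome *grid height* truth is
  the analytic mean of per-cell surface maxima (the per-cell maximum of
  c·√(1 − (x/a)² − (y/b)²) has a closed form via coordinate-wise
  clamping), since the grid-height estimand is itself grid-dependent.
  At the default density 8 points/cm² all three traits are recovered
  within 5%. Below ≈ 6 points/cm² the raster spacing approaches the
  0.5 cm analysis cell and jitter starts emptying single-point cells
  (their maxima then fall to lower surfaces), so the 5% height claim
  degrades — a property of sparse scanning, not of the estimators.
* **Cohorts** (`make_cohort`): trait j of sample i is
  a_j + b_j·tolerance_i + N(0, σ); loading signs define polarity
  (defaults: 19 traits in the CPT layout, ARI/CRI/CTR negative,
  σ = 0.1 against unit effect sizes — moderate noise for a designed
  experiment). The latent tolerance is the recovery target: the FCE-E
  expected score reaches Spearman ≥ 0.8 against it at n = 12, m = 19.

A green test on this world establishes that the algorithms implement
their stated mathematics and recover planted structure; it does not
validate biological claims, the specific published variety ratings, or
performance on real sensor artifacts (specular highlights, occlusion,
registration error), none of which the generators emulate.

# Defaults worth knowing

| Constant | Value | Where |
|---|---|---|
| TVI segmentation threshold | 10.6 (strict >) | `run_config()`, `segment_vegetation()` |
| Band-matching tolerance | 10 nm, ties to shorter | `nearest_band()` |
| Height/area grid cell | 0.5 cm | `grid_height()`, `canopy_leaf_area()` |
| Filter chain | knn 16, sd× 2, voxel 0.25 cm, fraction 0.5, MLS 1 cm | `filter_config()` |
| Breakpoints | 0.2, 0.3, 0.45, 0.55, 0.7, 0.8 | `membership_params()` |
| Grades / scores | Very tolerant…Very susceptible / 100, 75, 50, 25 | `evaluation_set()` |
| PCA reference trait | NDVI | `run_config()` |

# Numerical choices and limitations

* Partition of unity holds to < 1e-12 on [0, 1]; composition matches a
  brute-force double loop to 1e-12.
* Weights are clamped at 0 against floating-point overshoot of the
  entropy normalization; weight vectors sum to 1 within 1e-9.
* PC1 ranks use ties.method = "first" to stay a permutation; Spearman
  agreement uses average ranks.
* The incremental hull uses an epsilon scaled to the coordinate range
  (1e-10 × max |coordinate|); exact coplanarity raises "degenerate hull".
* The kNN and MLS kernels are O(n²) brute force — appropriate for
  single-plot clouds (≤ ~10⁵ points), not for field-scale scans.
* ENVI (.hdr + binary) is the supported cube format and PLY/XYZ the
  supported cloud formats; GeoTIFF and LAS are recognised but rejected
  with instructive errors, since no reader for them exists in the
  supported dependency set.
* Grading is relative to the evaluated cohort: min–max standardization
  makes grades depend on which samples are evaluated together. Evaluating
  one variety against a different cohort can change its grade — this is
  inherent to the method, not an artifact.
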