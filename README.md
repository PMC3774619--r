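# patchstat

Spatial statistics for patchwork quilts and other tessellated artefacts.

Crazy quilts — late-19th-century patchwork assembled from irregular,
non-repeating pieces — are one of the very few classes of human artefact
*intended* to look random. Regular quilts repeat a motif block on a
translational grid. `patchstat` quantifies this contrast from traced patch
outlines: it asks whether a quilt's patch areas come from one continuous
skewed distribution or from a Gaussian mixture of repeated patch types,
and whether its patch centroids are compatible with a simple inhibitory
random point process (a Strauss process) or not. The package is aimed at
researchers in empirical aesthetics and spatial statistics who want a
reproducible pipeline for "how random is this pattern?" questions on
polygonal tessellations.

## What it implements

* **Geometry and I/O** — patches as simple polygons (shoelace area, first-
  moment centroid), pixel-to-cm calibration, cropping to the patched
  bounding box, JSON/CSV quilt formats, and a packaged summary table of
  the sixteen museum quilts (8 regular, 8 crazy) that motivated the
  method.
* **Synthetic quilts** — regular quilts as motif tilings with coherent
  Gaussian seam jitter; crazy quilts as random tessellations (recursive
  random chords, or Voronoi cells of Strauss-process seeds) under a
  minimum patch area.
* **Area distributions** — maximum-likelihood fits of gamma, Weibull,
  lognormal and normal families; AIC ranking with the ΔAIC < 2 candidate
  rule and Akaike weights; moment skewness.
* **Mixture envelopes** — category-seeded Gaussian-mixture EM, kernel
  density bandwidths (0.9·min(sd, IQR/1.34)·n^(−1/5)), and the
  39-simulation sorted-area envelope test (pointwise two-sided
  α = 2/40 = 0.05).
* **Point processes** — Strauss model `β^n γ^{s(x)}`: pair counts,
  Ripley's K and Besag's L with isotropic edge correction, maximum-
  pseudolikelihood fitting with a 0.01-cm interaction-radius profile,
  fixed-n Metropolis–Hastings simulation (C++), and 39-simulation
  L-function envelopes. Fits with γ̂ > 1 are reported as model
  rejections.
* **Group statistics** — Mann–Whitney U (asymptotic, tie-corrected, no
  continuity correction) and Cohen's d.
* **Pipeline** — `analyze_quilt()` runs everything on one quilt and
  `compare_quilt_groups()` contrasts two sets of reports; all stage seeds
  derive from one master seed, so reports are bit-reproducible.

## Worked example

```r
library(patchstat)

q <- generate_crazy_quilt(c(160, 128),
                          generator_config(seed = 42, target_n = 220))
report <- analyze_quilt(q, quilt_config(seed = 7, r_step = 0.02, r_max = 32))
print(report)
#> <quilt_report 'synthetic-crazy-recursive_split-n220-seed42'> class crazy, 220 patches
#>   area skewness 1.95; candidate families: gamma, lognormal, weibull
#>   area envelope: 143 deviations (65.00%), kde bandwidth 23.83
#>   Strauss: gamma = 0.181, r = 4.11 cm; L envelope 6/64 radii outside
print(report$ranking)
#> Family ranking by AIC (candidates: delta AIC < 2)
#>     family log_likelihood      aic delta_aic weight candidate
#>      gamma      -203.2239 410.4477      0.00  0.465      TRUE
#>  lognormal      -203.7338 411.4675      1.02  0.279      TRUE
#>    weibull      -203.8200 411.6400      1.19  0.256      TRUE
#>     normal      -297.5100 599.0201    188.57  0.000     FALSE
```

Reading the report: the patch areas are strongly right-skewed (g1 = 1.95)
and any of the three positive skewed families is an acceptable fit, while
the normal is hopeless (ΔAIC 189) — so a *single* Gaussian forced onto
these areas fails the sorted-area envelope at 65% of ranks and needs a
large smoothing bandwidth. The centroids, however, are well described by
an inhibitory Strauss process (γ̂ = 0.18 at r̂ = 4.1 cm: strong avoidance
below ~4 cm, random beyond), and the observed L function stays essentially
inside the 39-simulation envelope (6/64 radii, within pointwise noise). A
regular quilt shows the mirror image: near-zero area deviations under its
category-seeded mixture, and a rejected (γ̂ > 1) or consistently
envelope-exiting Strauss fit.

The methods vignette (`vignettes/quilt-spatial-statistics.Rmd`) documents
the models, the numerical choices behind the pseudolikelihood fit, and
the generators' scope.

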