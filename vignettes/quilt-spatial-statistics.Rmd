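---
title: "Quantifying spatial randomness in patchwork: models and methods"
author: "patchstat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial randomness in patchwork: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchstat)
```

## The scientific question

Crazy quilts are patchwork blankets assembled from irregular, non-repeating
pieces, produced with the explicit intention of looking haphazard — a rare
case of humans deliberately trying to manufacture randomness. Regular
quilts, by contrast, repeat a small motif block on a translational grid, so
any variation between nominally identical patches reflects only motor
error. `patchstat` implements a pipeline that makes this contrast testable
from traced patch outlines alone, using two complementary summaries of a
quilt:

* the **distribution of patch areas** — a repeated motif produces a
  Gaussian *mixture* (one narrow component per patch category), while an
  unplanned tessellation under a minimum-piece-size constraint produces a
  single continuous, positively skewed distribution;
* the **spatial pattern of patch centroids** — an unplanned layout should
  be compatible with a simple inhibitory point process (patches cannot
  overlap, so centroids keep a minimum distance), while a periodic layout
  should not.

Every stage is testable without the original museum tracings because the
package ships a synthetic-quilt generator that emulates the statistical
structure of both quilt classes.

## Geometry and data model

Patches are simple polygons in planar cm coordinates (origin at the
top-left corner of the quilt, y pointing down, the usual image
convention). Area and centroid are computed analytically (shoelace formula
and first moments) rather than by pixel counting; the analytic values are
the infinite-resolution limit of the pixel method, and the test suite
bounds the discrepancy against a 0.001-cm rasterisation oracle (area
within 0.5%, centroid within 0.1% of the bounding-box diagonal). Pixel
inputs are calibrated at ingest: the cm-per-pixel scale is estimated from
the height and from the width and averaged, lengths scale linearly and
areas quadratically. Analysis windows are cropped to the smallest
axis-aligned rectangle containing the patchwork, so border strips never
enter the statistics.

## The synthetic generators

The generator's defaults define the conditions under which the pipeline
is validated.

**Regular quilts** tile a motif template (packaged: four-patch,
nine-patch, pinwheel; arbitrary templates via `new_motif_template()`) and
perturb seam vertices with centred Gaussian noise (`jitter_sd`, default
0.2 cm). Jitter is applied once per *unique seam vertex*, so adjacent
patches move coherently, boundary vertices slide only along the boundary,
and corners stay fixed. This is the physically correct model of a seam
sewn slightly off target — a seam that moves takes both neighbouring
patches with it — and it preserves the tessellation identity (patch areas
sum exactly to the window area), which independent per-polygon jitter
would break. At 0.2 cm on decimetre-scale patches the per-category area
coefficient of variation is a few percent, matching the ~3% re-measurement
error reported for real quilts.

**Crazy quilts** are random tessellations satisfying the two constraints a
real quilt imposes: a rectangular outline and a minimum patch area
(`min_area`, default 4 cm² — roughly the smallest piece that can be
seamed). Because only the end product is observable, two construction
methods are provided. `recursive_split` (default) repeatedly picks a patch
with probability proportional to its area and slices it with a random
chord (uniform interior point, uniform angle), skipping slices that would
violate the minimum area; this yields straight seams and positively
skewed, unimodal areas. `voronoi_strauss` tessellates the window into the
Voronoi cells of seeds drawn from a Strauss process, which links the
generator directly to the point-process model below. The default
`target_n = 300` patches on a blanket-sized window reflects the patch
counts of the historical sample (crazy quilts averaged ~321 patches). The
skewness of `recursive_split` areas at these defaults is about 1.5–2;
historical crazy quilts average 2.3 with a spread of 1.4, so the generator
sits at the lower end of the observed range — adequate for validating
sign and ranking properties, though not a calibrated reproduction of any
particular quilt. An intermediate block- or strip-level organisation seen
in some historical quilts is deliberately not generated.

## Area distributions: unimodal families and model selection

Four two-parameter families are fitted by maximum likelihood to (scaled)
patch areas: gamma, Weibull, lognormal — natural candidates for positive,
skewed sizes — and the normal, expected to fail for crazy quilts. Normal
and lognormal MLEs are closed-form (1/n variance); gamma and Weibull are
maximised numerically over log-parameters from method-of-moments starts,
with convergence certified by a local-maximum probe (no ±0.5% parameter
perturbation may improve the likelihood). Areas are conventionally scaled
by 0.01 (0.1 for very small quilts) before fitting; AIC *differences* are
invariant to the common factor, which the tests verify.

Families are ranked by AIC with `k = 2` (no small-sample correction), all
families within ΔAIC < 2 of the best are reported as candidates, and
Akaike weights `exp(-Δ/2)` (normalised, computed after subtracting the
minimum) quantify relative support. Skewness is the plain moment
coefficient `g1 = m3 / m2^1.5` with 1/n moments — the uncorrected
"moments" convention.

## Gaussian mixtures and the sorted-area envelope test

For regular quilts the mixture is **seeded** from the known motif
categories (per-category mean, SD, relative frequency) and refined by EM;
unseeded information-criterion fitting misclassifies patches whose shapes
differ but whose areas coincide, which is why seeding is the primary path.
Two seeding subtleties matter in practice:

* categories with indistinguishable mean areas (classic blocks often
  repeat the same square in two fabrics) are merged before EM — areas
  alone cannot separate them, and twin components invite the unbounded
  Gaussian-mixture likelihood;
* the pipeline runs EM with a negligible variance floor (10⁻⁹ of the data
  range), so noise-free synthetic quilts (zero jitter) yield point-mass
  components instead of a collapse error. Outside the pipeline the floor
  is off by default and a collapsing component raises an error, which is
  the honest behaviour for interactive use.

For crazy quilts the "mixture" is the single Gaussian with the overall
mean and SD. Its failure is diagnostic: fitted to positively skewed areas
it places visible probability below zero, violating the minimum-size
constraint, and the kernel-density bandwidth (`0.9 min(sd, IQR/1.34)
n^{-1/5}`, the classic rule of thumb, equal to the SD of the smoothing
kernel) must be much larger than for regular quilts.

The goodness-of-fit test is Monte-Carlo: 39 simulations of the fitted
model, each of the observed size; all series sorted; per rank the envelope
is the min and max over simulations; observed values strictly outside
count as deviations. With 39 simulations the pointwise two-sided level is
2/40 = 0.05. Simulations resample category membership multinomially
(component chosen by weight), matching the generative reading of the
mixture; fixed per-category counts are not used.

## The Strauss process: fitting, simulation, envelopes

Patch centroids are modelled as a Strauss process: density proportional
to `beta^n gamma^{s(x)}`, where `s(x)` counts point pairs closer than the
interaction radius `r`. `gamma = 1` is Poisson, `gamma = 0` a hard core;
`gamma > 1` is not a valid density and is treated as model rejection, not
an estimate.

**Fitting** maximises Besag's pseudolikelihood. For fixed `r`, the profile
in `beta` is analytic and the profile in `log(gamma)` is a concave 1-D
maximisation on `[-20, 2]` (so rejection, `gamma > 1`, is representable);
`r` is profiled over a grid from the minimum to the maximum interpoint
distance in 0.01-cm steps (`r_step`, `r_max` configurable — analyses here
truncate at a quarter of the shorter window side, the usual rule for
distance-based spatial statistics).

Three numerical choices deserve explanation:

1. *Neighbour counts in the pseudolikelihood are strict* (`d < r`). The
   profile grid starts exactly at the minimum interpoint distance, where
   the closest pair lies at distance `r` precisely; counting it there
   would hand the first grid point one guaranteed-atypical pair and
   produce degenerate boundary fits.
2. *The interaction integral is computed by disk decomposition*, not by a
   dummy-point grid. The integral of `gamma^{t(u)}` over the window
   equals `|W| + sum_i ∫_{disk_i ∩ W} (gamma^t − 1)/t du`, because the
   region with count `t = k` is covered by exactly `k` interaction disks.
   Each disk is sampled at fixed low-discrepancy locations scaled by `r`,
   each sample's neighbour count along the whole radius grid reduces to a
   sorted list of entry radii (one quadratic root per point pair, swept in
   C++), and the sampled count areas are rescaled so their first moment
   matches the closed-form circle–rectangle overlap — making the integral
   exact at `gamma = 1` and exact to first order around it. A dummy grid
   of spacing `h` cannot resolve the integrand when `r < h`, and that
   error lands precisely on the small radii the profile must compare; the
   disk decomposition is accurate at every radius by construction.
3. *A multiplicity hurdle guards the radius profile.* Every candidate
   radius embeds the same Poisson null, so scanning hundreds of radii
   finds spurious "interactions" at sparse radii by chance (the pseudo-LR
   also counts each close pair twice). A candidate may override the null
   only if its gain exceeds `0.5 qchisq(1 − 0.05/K, df = 2)` for `K` grid
   candidates; genuine interaction exceeds this by orders of magnitude,
   and Poisson-compatible patterns fall back to the most informative
   (largest-radius) candidate, reported with `significant = FALSE`. This
   is what makes the null calibration honest: without the hurdle, fits to
   simulated Poisson patterns land outside `gamma ∈ [0.8, 1.2]` more than
   half the time at every density we tried.

With the isotropic option, observed neighbour counts are Ripley-weighted
(reciprocal of the in-window fraction of the pair circle, closed form for
rectangles) to compensate for unseen out-of-window neighbours; the window
integral is unchanged.

**Simulation** holds `n` fixed (the observed number of centroids) and runs
Metropolis–Hastings: move a uniformly chosen point to a uniform location,
accept with `min(1, gamma^{Δs})`; hard cores start from random sequential
packing. Defaults are 10³ proposals per point of burn-in and 10⁴ per
point of sampling; the returned `s(x)` trace lets users check
stabilisation, which at the pattern sizes used here occurs within a small
fraction of the default chain (envelope simulations therefore use
shortened chains, 500 + 2000 proposals per point, verified to give the
same envelopes as the full defaults).

**Goodness of fit** uses Ripley's K with isotropic edge correction,
`K̂(r) = (|W|/n²) Σ w_ij 1[d_ij ≤ r]`, transformed to Besag's
`L = sqrt(K/π)` (equal to `r` under complete spatial randomness, which
the tests verify to within 3% of the window side). The envelope is the
pointwise min/max of `L̂` over 39 simulations from the fitted model —
the same 2/40 = 0.05 pointwise logic as the area envelope. `L(r)` itself
is reported (not `L − r`). Because the band is pointwise, transient
single-radius exits occur at the nominal rate even under the true model;
a quilt is scored as departing *consistently* when more than a quarter of
the grid radii fall outside, the reading under which one historical crazy
quilt (under-dispersed across the whole radius range) was rejected while
quilts with brief mid-range excursions were not.

## Group comparisons

Two-sample contrasts (patch counts, patched areas, bandwidths, envelope
deviation percentages) use the Mann–Whitney U test — `U = min(U₁, U₂)`,
normal approximation with tie-corrected variance and no continuity
correction, the "asymptotic significance" convention of the era's
statistics packages — and Cohen's d with the pooled `n₁+n₂−2` SD.

## Problem sizes and reproducibility

The validation suites run at deliberately moderate sizes chosen to make
the full pipeline repeatable in seconds per quilt: synthetic test quilts
of ~80–120 patches on 100 × 80 cm windows with a 0.05-cm radius step, and
acceptance-level syntheses of eight quilts per class (~180–220 patches on
160 × 128 cm, 0.02-cm step), mirroring the historical sample of eight
quilts per class. Parameter-recovery and null-calibration studies use
n = 200 points on 100 × 100 windows over 20 seeds. Every stochastic stage
takes an explicit seed; `analyze_quilt()` derives all stage seeds from
one master seed, so a report is bit-reproducible from its configuration.

## What passing tests do and do not show

The generators emulate the *statistical* structure the analysis targets:
repeated motifs with coherent motor error, and constrained random
tessellations. They do not reproduce fabric, colour, embroidery,
block-level organisation of real crazy quilts, curved or imperfectly
straight seams, or tracing error. Passing the synthetic dichotomy
therefore shows that the pipeline distinguishes the two generative
structures it models — not that any particular historical quilt is
random. The published per-quilt AIC tables, deviation counts and envelope
figures derive from tracings that are not publicly deposited, so the
package reproduces their *reproducible arithmetic* (summary-table
statistics, the U test, Akaike-weight recomputation from printed ΔAIC,
envelope levels) and the qualitative contrasts, not the per-quilt values.

## Known limitations

* Rectangular windows only (all cropped quilts are rectangles).
* The pseudolikelihood's radius profile is weakly identified for
  near-Poisson patterns; the significance hurdle makes the reported
  `gamma` stable but the reported `r` is then only "the most informative
  radius", not an interaction estimate.
* No censoring correction for the minimum-area constraint in the unimodal
  fits, and no additional families (beta, Pareto, ...).
* The hard-core sampler is Metropolis within fixed n, not perfect
  simulation; for packings near the jamming density it may fail to
  initialise.
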