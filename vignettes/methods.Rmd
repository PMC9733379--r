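---
title: "Canopy height and LAI from UAV point clouds: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy height and LAI from UAV point clouds: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cottoncanopy)
```

## The problem

Cotton defoliant dosing should follow canopy volume, not land area, which
makes per-field maps of plant height and leaf area index (LAI) operationally
valuable. Dense point clouds reconstructed from overlapping UAV RGB imagery
(structure from motion) capture the canopy surface well, but two obstacles
stand between a raw georeferenced cloud and usable phenotypes:

1. the cloud is in geodetic coordinates (latitude, longitude, ellipsoidal
   height) and must be expressed in a metric local frame;
2. under a closed canopy the bare ground is invisible, so no digital terrain
   model exists to subtract from the digital surface model (DSM).

`cottoncanopy` implements a complete, testable pipeline for both, plus a
linear LAI model on canopy descriptors, and ships a synthetic field
generator so every stage can be verified against known ground truth.

## Geodetic transforms

Points are converted WGS84 → ECEF with the standard closed form on the WGS84
ellipsoid (a = 6378137 m, f = 1/298.257223563), then rotated into a local
east-north-up (ENU) Cartesian frame anchored at the componentwise minimum of
(lat, lon, h) over the cloud — the "lowest point southwest" of the field —
so local x points east, y north, z up, and all field coordinates are
non-negative. The rotation rows are the ENU unit vectors:

$$R = \begin{pmatrix} -\sin\lambda & \cos\lambda & 0 \\
 -\sin\varphi\cos\lambda & -\sin\varphi\sin\lambda & \cos\varphi \\
 \cos\varphi\cos\lambda & \cos\varphi\sin\lambda & \sin\varphi \end{pmatrix}$$

The frame is stored with every localized cloud, so all downstream products
are invertible back to WGS84 (`delocalize_cloud()`). Round trips are exact
to < 1 µm; the forward transform agrees with an independent geodesy library
(pyproj, frozen as a test fixture) to < 1 µm.

## Ground elevation without a DTM

Two complementary ground models are provided.

**Orthogonal plane fits.** Between adjacent sampling regions the lower
region (by member-point centroid) stands in for bare ground and is fitted
with the plane minimizing summed squared orthogonal distances, normalized by
the squared normal norm. The optimum is the plane through the centroid whose
normal is the smallest principal direction of the centered scatter (solved
by SVD); a brute-force search over unit normals serves as the test oracle,
never the production path. Relative heights are *vertical* offsets from the
plane surface at each point's (x, y) — exactly the printed formula — not
orthogonal distances; the normal's vertical component is forced positive so
heights are positive above ground.

**Sample inversion.** Each 5 × 5 m plot contains four 1 × 1 m quadrats in
which the tallest plant height `h_c` was measured. With `P99` the 99th
percentile of DSM values over the quadrat, the quadrat ground elevation is
reverse-solved as `h_g = P99 − h_c`, and the plot ground elevation `h_gf` is
the mean of its four quadrats. The literal published formula (averaging the
`P99` values themselves, without subtracting `h_c`) contradicts its
surrounding text; it is kept behind `ground_from_samples(mode =
"as-printed")` for reproduction but is not a ground elevation.

The pipeline then fits a terrain plane through the 128 inverted quadrat
ground points to attach a relative height `e` to every point.

## Canopy height

The DSM assigns each cell the *maximum* elevation of its member points
(half-open cells; the extreme upper boundary is closed so every point is
binned exactly once). Default cell size is 0.05 m — the source imagery's
ground sampling distance is 0.29 cm but the DSM resolution is unstated, so
this is a configurable package default. Empty cells are filled from their
Chebyshev-nearest non-empty neighbours by iterative dilation (equidistant
neighbours averaged) so regional percentiles see a complete surface; the
fill method is recorded on the grid.

Canopy height is `h = P99(region) − h_ground`, with the percentile
definition fixed to linear interpolation between order statistics
(`stats::quantile` type 7; the source does not define one) and the
percentile itself exposed (95th/99th both appear in the literature).

**A known limitation.** The 99th percentile of a 25 m² plot (~10⁴ cells)
cannot reach the single tallest point among ~130 plants: the gap between a
high percentile of the canopy surface and the regional *maximum* is an
extreme-value effect of roughly one within-plot height standard deviation
(~5–6 cm in the synthetic world). At the 1 m² sampling quadrats the same gap
is much smaller and, crucially, cancels: the ground inversion subtracts a
quadrat-level P99 and the height estimate adds one back. Accuracy checks
therefore compare estimated and true tallest heights *at the quadrats*
(n = 128), as the source study's own scatter evaluation does; plot-level
heights are still produced, with this bias documented. The residual ~2 cm
quadrat-level gap also propagates into the inverted ground elevations, which
recover the true terrain to ≈ 0.020–0.021 m mean absolute error at the
stated noise level — sitting exactly at the 0.02 m bound asserted in the
acceptance suite, so that check can be marginally red even though the
noise-free inversion is exact.

## Canopy density and descriptors

Above-ground points (`e` above a 0.05 m buffer — ground-point noise and
terrain-model error make a strict zero cutoff misclassify a large fraction
of ground returns) are binned into square cells of edge ε on a vertical
slice (horizontal coordinate × relative height, as the defining equations
state; the horizontal x–y reading is selectable). Densities are
`a = count/ε²`, so mass conservation `Σ a ε² = n` holds as an integer
identity. The occupancy ratio `g` is the fraction of cells with density at
least 0.2 of the grid mean, the mean taken over *all* cells including empty
ones (the published normalization divides by the full matrix size); an
all-zero grid returns 1 under the printed `≥` convention, flagged with a
warning. ε defaults to 1 m (the planting-row-width argument of the source)
for field-level maps.

For the per-quadrat LAI descriptor, ε = 1 m would collapse a 1 × 1 m quadrat
into a single cell and make `g ≡ 1`, so `quadrat_features()` uses ε = 0.2 m
with a fixed vertical span of 1 m (the crop's height scale). Fixing the span
keeps `g` comparable across quadrats instead of depending on each quadrat's
own tallest point. Whether the published model computed `g` per quadrat or
per plot is not stated in the source; per quadrat is the only reading that
gives the model quadrat-level predictors.

The maximum canopy diameter `d_t` is the exact 2-D diameter (convex hull +
pairwise scan over hull vertices), with a bounding-box diagonal variant
exposed; the all-pairs scan is the test oracle.

## The LAI model

LAI is an affine function of descriptors scaled by the planting row spacing
δ:

$$\mathrm{LAI} = \Big(\sum_w t_w\, g_w + j\Big)\, \delta^{-1}$$

The shipped published model is
`LAI = (1.37618 g + 0.66738 d_t − 0.02035 h_e − 0.51087)/0.76`. Note the
0.76 m divisor conflicts with the 0.60 m agronomic row spacing reported for
the same trial; the package inherits the published value and surfaces 0.60
as an explicit option rather than resolving the conflict silently. Negative
predictions are legal output of an affine model and are returned with a
warning, never clipped.

Fitting regresses `LAI·δ` on candidate descriptors with an intercept
(coefficients therefore live on the published scale) and selects descriptors
by bidirectional stepwise search. **Default penalty: BIC.** The source says
only "stepwise multilinear least squares"; AIC — a common default — admits a
pure-noise regressor with probability ≈ P(χ²₁ > 2) ≈ 0.16, which is
incompatible with requiring noise descriptors to be excluded ≥ 95% of the
time, so the package defaults to k = log(n). AIC and a p-value entry/stay
mode (0.05/0.10) remain options, and `criterion = "none"` gives plain OLS.

**Identifiability caveat.** With quadrat heights varying by ~0.1 m, the
`h_e` coefficient's contribution to LAI is |−0.02035| × 0.1 ≈ 0.002 —
roughly 50× below a realistic LAI measurement noise of 0.1. No estimator
recovers that coefficient to 15% relative error at n = 128 (the OLS standard
error is ≈ 0.07, i.e. ≈ 330% of the coefficient; ~2 × 10⁶ quadrats would be
needed), and a correctly behaving stepwise fit *drops* the term. The
acceptance suite asserts the 15% bound for all three coefficients as
specified and is honestly red on `h_e`; `g` and `d_t` recover to within a
few percent and the noise-descriptor exclusion criterion passes.

## Evaluation metrics

MAE and RMSE are standard. Two R² variants are always reported side by side
because the source's printed definition,
`R² = Σ(h_e − h̄)² / Σ(h_c − h̄)²` with `h̄` the measured mean, is a
dispersion ratio, not the conventional coefficient of determination: it is
unbounded above and exceeds 1 when estimates over-disperse. `r2_ratio()`
implements the printed form, `r2_standard()` the conventional
`1 − SS_res/SS_tot`; which one produced the published headline numbers is
unknowable from the text.

## The synthetic world

`generate_field()` builds a fully ground-truthed stand-in for the study's
(unreleased) data: a 40 × 20 m field on a gently sloped plane (default
slope 0.4%/0.2%), rows 0.60 m apart, plants every 0.30 m, 32 plots with 128
quadrats, mean plant height 0.60 m. Defaults restate the trial's stated
conditions; where the source is silent the choices are:

* **Plants as dome surfaces.** SfM reconstructs the *visible* canopy
  surface, so each plant is a paraboloid dome (centre height h, edge
  40% lower) sampled with exponentially decaying depth below the surface
  (mean 0.04 m), plus a vertical stem line. Interior leaf-level structure is
  deliberately not modelled — percentile and density statistics do not see
  it.
* **Height variation.** Plant height = 0.60 m + a between-plot effect
  (sd 0.08 m, emulating the wide height spread visible in the study's
  measured-vs-estimated scatter) + an individual effect (sd 0.05 m).
* **Sampling density.** 400 points/plant (Poisson, log-normal per-plant
  vigor, sd 0.3) and 250 ground points/m² give ≈ 2 × 10⁶ points for the
  full field, the scale named in the acceptance criteria; per-point
  elevation noise is 0.005 m (RTK grade).
* **Defoliation** removes the stated fraction of leaf points (stems
  persist), with a single thinning pass at the end of generation so kept
  point sets are nested across stages under a fixed seed — that is what
  makes "more defoliation ⇒ fewer canopy points" a deterministic,
  monotonic property. No kinetic model of defoliation over days is claimed.
* **LAI truth** is generated directly from the published coefficients
  applied to each quadrat's *true* descriptors plus N(0, 0.1) noise, which
  makes coefficient recovery a well-posed test; the optics of the LAI meter
  are intentionally outside the model.

What a green end-to-end test does *not* establish: realism of leaf-level
occlusion, SfM reconstruction artifacts (wind motion, matching failures),
radiometry, or temporal defoliation dynamics. The generator is a geometric
stand-in whose purpose is verifiable bookkeeping, not biological fidelity.

## Numerical conventions

* Half-open bins everywhere, with the extreme upper boundary closed into the
  last bin (exact point conservation).
* Region membership for percentile extraction: cell centre inside the
  closed rectangle.
* Percentiles: linear interpolation (type 7).
* Plane-fit degeneracy: < 3 points or collinearity (second singular value
  below 10⁻¹⁰ of the first) raise a degenerate-geometry error; vertical
  planes are legal fits but refuse to compute relative heights.
* Ties in `lowest_region()` go to the first argument, deterministically.
* All randomness flows through a seed carried in the configuration object;
  generators save and restore the global RNG state.

## Files and provenance

Point clouds read/write as XYZ-CSV (header names the frame) and ASCII PLY
(`comment frame` header line); local-frame exports carry their origin and
rotation in a JSON sidecar so they remain invertible. Layouts are GeoJSON
FeatureCollections of axis-aligned polygons; models serialize to JSON. Every
persisted table carries a configuration hash, and `run_pipeline()` reports
are reproducible bit-for-bit given the same inputs. A CLI
(`inst/cli/cottoncanopy`) exposes the stages as subcommands (`simulate`,
`localize`, `ground`, `height`, `density`, `lai-fit`, `lai-predict`,
`evaluate`, `run`) that compose, through files, to the same results as the
in-memory pipeline — asserted in the test suite.
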