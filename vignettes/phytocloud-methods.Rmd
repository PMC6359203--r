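---
title: "Methods: chlorophyll and leaf-angle monitoring from colored point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chlorophyll and leaf-angle monitoring from colored point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phytocloud turns colored 3D point clouds of potted plants — the output of
structure-from-motion (SfM) photogrammetry — into three per-point fields
that together describe a plant's physiological and structural state:
chlorophyll content, leaf inclination (zenith) angle and azimuthal angle.
Tracked day by day, the three fields expose the signature of developing
water stress: chlorophyll falls, leaves steepen, and blades twist. This
vignette documents the models behind each stage, the tunable parameters,
the synthetic validation data, and the numerical choices a maintainer
would want spelled out.

## 1. Metric scale and the z-up frame

An SfM reconstruction is defined only up to a similarity transform: it has
no units and an arbitrary orientation. The field practice is to place a
rigid box of known dimensions (13 cm x 12 cm x 9 cm in our default) next
to the plant and pick corresponding points on its edges.
`estimate_scale_calibration()` turns those picked pairs into a
`scale_calibration`:

* **scale** — the unweighted arithmetic mean over the measured edges of
  (known length) / (model length). With several edges the mean is the
  simplest unbiased combination under small, independent picking errors;
  we deliberately do not weight by edge length, since picking error is
  roughly constant in model units, not proportional to the edge.
* **rotation** — when one edge is known to be vertical, the unique
  rotation about the axis perpendicular to both that maps its direction
  onto +z (identity if already aligned). The calibrated frame is
  right-handed, z-up, in cm; all downstream angle math assumes this.
* **translation** — zero by default; absolute position carries no
  information here.

`apply_calibration()` refuses a cloud that is already calibrated: silently
scaling twice is the kind of mistake that produces beautifully wrong
angle maps. The inverse transform (`invert_calibration()`) restores
coordinates to better than 1e-9, which the tests assert.

There is no automatic cube detection: correspondences are user-picked
(CSV/JSON), because detection quality would depend entirely on the
reconstruction and camera setup, not on anything this package controls.

## 2. Chlorophyll from the normalized Red value

Chlorophyll absorbs red light, so leaf reflectance in the red channel
falls as chlorophyll rises. The color feature used is the **normalized
Red value**

$$ r_n = \frac{R}{R + G + B} \in (0, 1), $$

which is invariant under uniform brightness changes — the property that
makes it usable across a 3D model whose faces are lit unevenly. Stored
8-bit sRGB values are used as-is: the upstream photogrammetry software's
gamma and white-balance handling is not documented anywhere we could
anchor a correction to, and a monotone gamma would simply be absorbed
into the calibration fit at these narrow leaf color ranges.

The calibration itself is an ordinary least-squares line fitted to paired
observations (r_n at a picked point, wet-chemistry chlorophyll of a leaf
disc punched at that point):

$$ \mathrm{chl} = a\,r_n + b, $$

with chlorophyll regressed **on** color because the curve is used
predictively over whole clouds. R-squared is the squared Pearson
correlation (identical to 1 - SSE/SST in this single-predictor setting).
Wet-chemistry values come from absorbances of an 80% acetone extract via
the Porra (1989) equations, `17.76 A_{646.6} + 7.34 A_{663.6}` ug/mL,
normalized to areal content (ug/mm2) by extract volume / punch area.
Volume and punch area are required inputs; there are no defensible
defaults and silently assuming one would corrupt every downstream unit.

Accuracy is summarized by leave-one-out cross-validation
(`loocv_mae()`): each disc is predicted by a line fitted to the others.
LOOCV was chosen because calibration sets are small (tens of discs) and
the procedure is deterministic; a seeded k-fold variant (`kfold_mae()`)
exists for users who want it. The implementation is an explicit n-refit
loop over closed-form OLS; the test suite checks it against an
independent `lm()`-per-fold oracle to 1e-9 and against a hand-computed
four-point case.

`map_chlorophyll()` applies the curve to every point. Black pixels
(R+G+B = 0) have undefined chroma and are masked (`chl_valid = 0`), and
negative predictions are **kept and flagged** (`chl_out_of_range`), not
clipped: a histogram with visible negative mass is the honest symptom of
extrapolating past the calibration range, and clipping would hide it.

## 3. Leaf angles by local plane fitting

For each point, the points within an axis-aligned cube of side
L = 0.5 cm centered on it (closed boundary: |p_k - c_k| <= L/2 on every
axis) form the neighborhood; the plane fitted to them gives a surface
normal, and

* **zenith** = arccos(n_z), degrees in [0, 90] — the leaf inclination
  angle (0 = horizontal blade, 90 = vertical);
* **azimuth** = atan2(n_y, n_x), degrees in [0, 360), counterclockwise
  from +x of the calibrated frame.

Numerical and design choices:

* The plane fit is **orthogonal least squares** — the normal is the
  least-variance eigenvector of the neighborhood covariance — rather than
  a regression of z on (x, y), which becomes ill-posed exactly where the
  biology is interesting (steep, wilting leaves).
* The cube is axis-aligned in the calibrated frame. L = 0.5 cm trades
  smoothing against locality at typical close-range SfM densities
  (hundreds of points/cm2); it is exposed as `cube_side`.
* Neighborhoods with fewer than `min_points` (default 10) members, or
  with a rank-deficient covariance (collinear/coincident points,
  detected at a relative eigenvalue threshold of 1e-12), are **masked**,
  never extrapolated.
* Normals are up-signed (n_z >= 0; ties broken toward positive x then
  y), so zeniths land in [0, 90]. A plane fit cannot distinguish a
  blade's top from its bottom, so downward-inclined leaves are handled
  explicitly by per-leaf orientation flags (`apply_leaf_sign()`), which
  negate the zenith for time-series display.
* The azimuth of a near-horizontal normal is numerically meaningless;
  zeniths below `horizontal_threshold` (default 1 degree) keep their
  azimuth value but are flagged.
* The grid accelerator behind `cube_neighborhood()` is contractually
  invisible: tests require exact equality with an exhaustive O(n) scan,
  including points exactly on the closed boundary.

The azimuth reference direction (+x) is a package convention. Absolute
azimuths are therefore only comparable within a consistently calibrated
series; azimuth *changes* across days are the meaningful signal.

## 4. Monitoring aggregates

`locate_regions()` finds three anchors per leaf — the labeled point
nearest the leaf centroid, and the extreme points along the leaf's
second principal axis (the across-blade direction) for the left and
right edges — and pools the labeled points within `region_radius`
(default 0.25 cm, a "small point" at leaf scale) around each.
`build_series()` summarizes each region, day and quantity into a tidy
table; a leaf or region missing on a day is a gap, never a fabricated
zero. All azimuth summaries use the **circular mean** (vector
averaging): arithmetic means of angles near the 0/360 wrap are simply
wrong, and the tests pin the rotation-equivariance this buys.

`compare_days()` is a Kruskal-Wallis rank test across days (per-point
angle and chlorophyll distributions are bounded and typically
non-normal; a Welch ANOVA option exists). One caveat is stated rather
than hidden: per-point values within a leaf are spatially
autocorrelated, so these p-values describe separation between day
distributions; they are not independent-sample inference.

Histogram bin widths default to 5 degrees for angles and 1 unit for
chlorophyll — coarse enough to be readable at a few hundred points per
leaf, fine enough to show within-leaf spread.

## 5. The synthetic generator and what it does (not) emulate

Leaves are elliptical patches with an optional parabolic fold across the
blade, sampled uniformly at `point_density` (default 400 points/cm2, a
typical close-range SfM density at this scale), perturbed by Gaussian
noise along the surface normal (`noise_sigma`, default 0.02 cm,
sub-millimeter reconstruction roughness). Every point carries analytic
ground truth: the exact surface normal's zenith/azimuth and an affine
chlorophyll field in leaf-local coordinates. Colors are constructed by
inverting the calibration line — the red and blue channels are searched
over the 8-bit lattice with green held at a leaf-like constant so the
realized r_n hits the target as closely as quantization allows. The
residual quantization error (at most about 1/500 in r_n for defaults,
bounded by |a|/765 in chlorophyll units) is the documented noise floor
of every chlorophyll round-trip test.

The five-day stress preset drives one leaf through day-1/3/5 target
means of 12.9 / 11.7 / 7.0 (chlorophyll, treated as dimensionless preset
units since the source scale is ambiguous), 23.7 / 33.1 / 33.9 degrees
(zenith) and 88.6 / 119.3 / 156.9 degrees (azimuth), interpolating
intermediate days linearly. The within-leaf chlorophyll gradient
defaults (0.5 and 0.25 units/cm along the two leaf axes) are chosen for
test power — large enough that a broken gradient would be caught — not
from measured biology. With the preset's gentle fold (curvature
0.05 /cm) the recovered mean zenith sits a few tenths of a degree above
the plane value, because folding only adds to each point's inclination;
this is a property of the geometry, not an estimator bias.

What the generator does **not** emulate: self-occlusion, SfM matching
artifacts and holes, specular highlights, non-affine chlorophyll
patterns, and cross-day registration error (each day is generated with
consistent labels; the package requires consistent labels as an input
contract and does not register reconstructions). Passing tests therefore
demonstrate correctness of the estimators on clean geometry and honest
noise, not robustness to every pathology of real reconstructions.

## 6. Validation tolerances and problem sizes

All tolerances were frozen from pre-build Monte-Carlo pilots of the
generator settings, then left alone:

* Noiseless planar patches at 100 random orientations: zenith and
  azimuth recovered to 1e-6 degrees (observed: ~1e-12).
* Noisy patches (400 points/cm2, sigma = 0.02 cm, L = 0.5 cm): a
  500-rep pilot of the per-leaf median zenith error gave mean 0.61,
  99th percentile 0.95, maximum 1.29 degrees; the suite asserts 2
  degrees, comfortably inside the 5-degree ceiling that defines useful
  recovery at this noise level.
* Calibration fits at n = 30 and population R2 = 0.81: a 1000-rep pilot
  of the fitted R2 gave the 0.5%/99.5% band [0.650, 0.923]; the suite
  asserts [0.63, 0.94].
* LOOCV vs brute force, and grid neighborhoods vs exhaustive scan:
  equality (1e-9 / exact).

Test problem sizes — leaves of 1.6 x 0.8 to 4 x 2 cm, 150-400
points/cm2, 100-rep orientation sweeps — were chosen so the full suite
exercises every estimator at realistic densities while remaining a
desk-scale computation; `scripts/acceptance.R` re-runs the same
measurements from scratch at a fixed seed.

## 7. Known limitations

* Leaf labels are inputs (or synthetic); there is no segmentation.
* No cross-day registration: "the same leaf" across days is whatever the
  labels say.
* The calibration is a single line per experiment; lighting changes
  between days shift r_n and masquerade as chlorophyll change.
* PLY support covers point clouds (scalar vertex properties, ascii and
  binary little-endian); meshes are out of scope. Positions are written
  as `double` by default because 32-bit floats cannot round-trip
  centimeter coordinates at the 1e-6 cm fidelity the tests demand;
  `position_type = "float"` is available for interoperability.
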