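---
title: "Multi-scale morphometry of tri-leaflet heart valves with valvemorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale morphometry of tri-leaflet heart valves with valvemorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valvemorph)
```

## The measurement problem

Murine heart valves are too small for conventional clinical imaging, so
organ-level geometry has to be reconstructed from high-resolution modalities:
a labeled micro-CT segmentation for the whole valve (voxels of a few
micrometres) and electron-microscopy fiber data for the extracellular matrix
at a single location. `valvemorph` implements the full analysis layer between
a labeled segmentation and the reported numbers:

1. **Landmarks** -- the three commissure points `P1` (anterior/left), `P2`
   (anterior/right), `P3` (left/right); per-leaflet free-edge and
   basal-attachment node chains; the annulus (ANL) plane through the three
   basal midpoints `P5`, and the sino-tubular junction (STJ) plane through
   the commissures.
2. **Geometric quantities of interest (gQOIs)** -- per-leaflet free-edge and
   basal-attachment lengths $L_{FE}$, $L_{BA}$; valve height $H$ (mean
   commissure distance to the ANL plane); leaflet thickness $w$ (distance
   transform at nine random belly sites); valve perimeter $L_\Gamma$ (length
   of the closed contour obtained by projecting all basal attachments onto
   the ANL plane); tilt angle $\beta$ between the ANL and STJ planes.
   Dimensional quantities are normalized by $L_\Gamma$.
3. **Leaflet shape** -- a tensor-product B-spline surface (a NURBS surface
   with unit weights)
   $\mathbf{S}(\xi,\eta)=\sum_i\sum_j R^{p,q}_{i,j}(\xi,\eta)\,\mathbf{P}_{i,j}$
   fitted to the segmented leaflet mid-surface; central circumferential
   (`c2`) and radial (`r2`) cross-sections normalized into representative
   shape coordinates $\bar c \in [-1,1]$, $\bar r \in [0,1]$, $\bar h$
   (0 on the ANL plane).
4. **Fiber statistics** -- rigid mapping of collagen-fiber sets from the
   microscope frame into the valve frame, orientation histograms
   ($\theta$, $\varphi$ under the axial convention), the mean axis from the
   orientation second-moment tensor, and the alignment angle with the local
   circumferential direction $\partial\mathbf{S}/\partial\xi$.
5. **Per-pressure statistics** -- mean ± s.e.m per transvalvular pressure
   (TVP, 10/20/30 mmHg; study sizes n = 3, 5, 3), ordinary least squares of
   each gQOI against TVP with a two-sided t-test on the slope, a degenerate
   constant model for thickness and tilt, left/right pooling, and the
   derived quantities (anterior size ratios, relative perimeter change).

Because the raw scans behind the reference study are not public, the package
ships a synthetic valve generator with closed-form ground truth; every
pipeline stage is validated against it.

## The valve phantom

`generate_valve_phantom()` builds a labeled voxel volume (wall, anterior,
left, right) from closed-form surfaces:

* The arterial wall is a shell around the valve axis whose radius
  interpolates from `wall_radius_at_ANL` (annulus level, z = 0) to
  `wall_radius_at_STJ` at the rim. The rim is tilted about a horizontal axis
  through the anterior leaflet midpoint: the rim height is
  $h_0 + R\tan\beta\,(1-\cos(\psi-\psi_A))$, which keeps the anterior
  commissure pair level (so the anterior leaflet stays symmetric) and makes
  the commissure plane meet the annulus at exactly the tilt angle.
* Each leaflet mid-surface is a ruled patch between its basal attachment arc
  on the wall and a free-edge curve, plus a quadratic belly sag:
  $\mathbf{S}(\xi,\eta)=(1-\eta)\mathbf{B}(\xi)+\eta\mathbf{F}(\xi)
  -4\,s\,\eta(1-\eta)\sin(\pi\xi)\,\hat z$.
  The basal height profile is a flat-bottomed dip
  ($z_B = z_a(1-2\xi)_+^3 + z_b(2\xi-1)_+^3$): the attachment tracks the
  annulus level over the central span and rises to the commissures over
  cubic shoulders. This reproduces the reported low-pressure morphology in
  which the central radial cross-sections lie almost entirely below the
  annulus plane.
* Azimuthal sector widths are proportional to `leaflet_scale`
  (anterior 0.8, left = right = 1), giving the anterior leaflet roughly 80%
  of the left/right size.
* Leaflets are voxelized with center-inside-object semantics: a voxel gets
  the leaflet label only if its center lies within half a thickness of the
  mid-surface, matching what a segmentation of the continuum object would
  produce. Leaflets overwrite the wall where they cross the shell (the
  attachment), and never overwrite each other (first-come at coaptation,
  as in a manual segmentation).

Ground truth (`phantom_ground_truth()`) is computed by densely sampling the
closed-form curves (4001 points per curve) and applying the same landmark
definitions -- never the voxel pipeline.

The murine preset (`murine_pv_preset()`) represents a 1-year-old murine
pulmonary valve fixed at 10, 20 or 30 mmHg: perimeter ~4.8 mm at 10 mmHg
growing ~12% to 20 mmHg and then leveling off, thickness 19 um, tilt 10
degrees, normalized height 0.14, normalized basal lengths ~0.42/0.50.
Free-edge dimensional lengths are approximate: the reference only reports
perimeter-normalized values, so the preset backs plausible free-edge curves
out of the normalized scale and the coaptation geometry (free-edge midpoint
at half the rim radius, slightly below the annulus at 10 mmHg, with the
belly sag decreasing at higher pressures). What the phantom does *not*
emulate: scanner noise and partial-volume effects (volumes are already
"segmented"), biological shape variability beyond a radius jitter in the
demo study, and any mechanical response of the tissue -- so passing tests
demonstrate correctness of the measurement pipeline, not robustness to
segmentation error in real scans.

## Deterministic landmark rules

The reference workflow relied on interactive correction of mis-detected
edge nodes; `valvemorph` replaces this with deterministic rules:

* **Valve axis**: the wall is an approximate tube of revolution; the axis
  direction comes from the isolated eigenvalue of the wall voxel covariance
  and is refined through centroids of fully-annular axial slabs (these lie
  exactly on the axis even with a tilted rim). Orientation (arterial side)
  is fixed by the commissure contact sets projecting beyond the leaflet
  bulk.
* **Commissures**: for each leaflet pair, the contact set is voxels of
  either leaflet that are 26-adjacent to the other leaflet and to the wall.
  Because the two leaflet labels merge into one label right at the tip, the
  contact set stops short of the true commissure; the detector therefore
  takes the farthest-from-annulus *wall-attached* voxel of either leaflet
  near the contact region, and projects out the residual half-thickness
  overshoot along the local mid-surface normal. Ties break lexicographically.
* **Edges**: "attached" is a 1-voxel dilation against the wall label; the
  basal chain is the azimuthally binned centroid of wall-adjacent leaflet
  voxels. The free edge is, per azimuthal bin, the radially innermost margin
  of the mid-surface ridge (the ridge carries no half-thickness ambiguity,
  and the free margin is the leaflet's closest approach to the valve axis).
  Bins within 1.5 thicknesses of a commissure are discarded (coapting
  leaflets contaminate the adjacency bands there), both chains are anchored
  at the exact commissure points, lightly smoothed, and decimated to ~10 um
  node spacing by window averaging. Edge splines are interpolating
  (`smoothing = 0`) by default; the decimation already averages out voxel
  jitter.
* **Mid-surface**: the ridge of the exact 3-D Euclidean distance transform
  of the leaflet label. A voxel is a ridge voxel if the axis pair of its
  26-neighborhood with the smallest distance sum (the thickness direction)
  is a genuine local-max descent; testing all pairs would accept in-plane
  plateau voxels, and the descent requirement (half a voxel over the pair)
  rejects the interior layers of thick slabs.
* **Thickness**: at three seeded random belly sites per leaflet (belly =
  mid-surface with $\eta \in [0.35, 0.65]$ and the central circumferential
  half $\xi \in [0.25, 0.75]$ -- bounds chosen here, since "belly region" has
  no standard quantitative definition), local thickness is
  $2\,\mathrm{EDT} + 0.35\,h$. The 0.35-voxel correction was calibrated on
  analytic slabs at representative tilts: for a generically tilted slab the
  ridge EDT underestimates the half thickness by ~0.17 voxels. The site
  seed is recorded in the output metadata.

## Shape fitting choices

* Weights are fixed at 1 (B-spline specialization): the fit optimizes
  control point positions only, which keeps it a linear least-squares
  problem per coordinate.
* Defaults p = q = 3 with an 8 x 8 control net resolve the belly sag
  without overfitting; all configurable.
* The ridge penalty on second differences of the control net is scaled so
  `lambda` is the penalty's share of the normal-matrix trace
  (default 1e-3). A fixed absolute penalty weight would change meaning with
  the data scale; the trace-relative form keeps it a small spectral
  perturbation that regularizes the sparsely sampled corners of the net.
* `fit_leaflet_surface()` additionally (a) discards mid-surface points
  closer than 0.8 thicknesses to the basal chain, where the leaflet merges
  into the wall and the ridge is unreliable, (b) anchors the fit with the
  measured basal (eta = 0) and free-edge (eta = 1) chains as weighted data,
  and (c) performs one robust trim-and-refit pass at 2x the median residual
  to reject stray ridge voxels.
* The chart: $\xi$ is the normalized azimuth between the leaflet's two
  commissures (increasing from the first to the second commissure, in the
  order P1->P2, P2->P3, P3->P1); $\eta$ is the fractional distance between
  the interpolated basal and free-edge chains.
* "Vertical" for the best-fitted cross-section plane means parallel to the
  ANL normal (the valve axis). The circumferential section `c2` is the
  iso-curve through the belly point $S(\xi^*, 0.5)$, where $\xi^*$ is chosen
  so the radial section `r2` ends nearest the free-edge midpoint `P4`.
  Circumferential sections are normalized by half their horizontal extent
  (span exactly $[-1, 1]$), radial sections by the full extent (span
  $[0, 1]$, 0 at the basal end); heights are divided by the same scale, one
  scale per curve.

## Statistics layer

OLS is fitted over all individual points (each valve contributes two values
to pooled left & right rows, not their average), with the usual variance
estimator and a two-sided t-test with n - 2 degrees of freedom. Fitting on
per-pressure means with weights n gives the identical slope (an algebraic
identity that is also tested) but a different standard error, which is why
`fit_linear_vs_tvp()` accepts explicit weights for mean-level fits. The
constant model reports the grand mean ± s.e.m with no p-value. Printed
precision follows the reference table (2 decimals for normalized values and
p-values, integers for micrometres and degrees, slopes x100 except the
perimeter row); machine-readable output keeps full precision.

## Numerical and degenerate-input behavior

* Arc lengths use adaptive quadrature of the spline speed (`rel.tol 1e-9`);
  the perimeter contour uses a periodic spline.
* Planes through near-collinear points, degenerate (near-vertical-line)
  cross-sections, zero fiber vectors, leaflets thinner than 3 voxels, and
  missing labels raise informative errors rather than silently degrading.
* All generators and samplers take explicit integer seeds and restore the
  caller's RNG state; identical configurations produce byte-identical
  artifacts.

## Problem sizes used in the test-suite

Unit tests run on a quarter-scale phantom (radii ~230-260 um, 24 um
leaflets, 6 um voxels) that exercises every code path in seconds. The
acceptance checks use the murine preset: recovery at the acquisition
resolution (2.8 um), shape analysis at 4 um, and a convergence series at
{8, 4, 2} um with leaflets thickened to 25 um so the coarsest grid still
resolves them (the preset's own 19 um leaflets would violate the
three-voxel resolvability requirement at 8 um; the length-type quantities
under test do not depend on thickness).

## Known limitations

* Recovery errors of the edge-length estimators reach a sub-voxel bias
  floor of ~0.5-1.5% (systematic chain offsets of fractions of a leaflet
  thickness near the rim and commissures) already at 8 um voxels on the
  murine geometry. Consequently the *absolute* error does not decrease
  strictly monotonically with voxel size for every quantity -- only the
  perimeter, whose estimator is essentially unbiased, shows clean monotone
  convergence. All quantities stay well within 5% of ground truth at every
  tested resolution.
* The analysis consumes labeled voxel volumes; surface meshes are produced
  as outputs (PLY) but not accepted as measurement inputs.
* Fiber statistics describe a local sample; nothing in the package
  extrapolates them across the leaflet.

## A short worked example

```{r example, eval = FALSE}
library(valvemorph)

# synthetic study: two valves per pressure, coarse voxels
demo <- run_demo(seed = 7, voxel_size = 7)
format_gqoi_table(demo$table)
demo$report

# published reference values and the derived quantities
tab <- published_gqoi_table()
round(anterior_ratio(tab, "free_edge", 10), 2)  # 0.81
perimeter_change(tab, 10, 20)                   # 12.05 (%)
```
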