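---
title: "Methods: the lake twin, bloom indices and field interpolation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the lake twin, bloom indices and field interpolation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinlake)
```

This vignette is the package's own account of its models and the choices
behind them: what each component assumes, which parameters matter and why
their defaults are what they are, what the synthetic generators do and do
not emulate, and where the numerics required a decision.

## The lake twin

The twin is the geometric substrate everything else is draped on. Its
assumptions are deliberately austere:

* **The water surface is planar.** The level L (metres above the DEM datum)
  is a single number per instant, taken as the arithmetic mean over gauging
  stations of each station's latest reading within a staleness window
  (default 6 h; a silent station drops out rather than contributing stale
  data). Wind set-up, seiches and waves are outside scope; on large lakes a
  planar level is an approximation and the twin inherits that error.
* **The wetted surface is a connected level set.** Cells with elevation
  `z ≤ L` are candidate water; the surface is the 8-connected component
  containing a user seed point. Flood-filling from a seed, rather than
  taking every low cell, excludes disconnected depressions elsewhere in the
  watershed deterministically. Ties (`z == L`) count as water, consistent
  with the mesh clip rule keeping vertices with `z ≤ L`. Island holes stay
  non-water; they are interior boundary rings.
* **The shoreline is the 0.5 iso-contour of the binary mask.** On the cone
  test basin the recovered radius converges to the analytic `L / slope` as
  the cell size shrinks (checked at 10 m and 5 m cells with relative error
  below `cellsize/radius + 1%`).

The bed mesh is a Delaunay triangulation of the bathymetry planform with
sounding elevation carried on the vertices, so it reproduces every sounding
exactly and is exact for affine beds. The triangulation is an incremental
Bowyer–Watson construction; grid-sampled soundings make cocircular quadruples
the common case, so insertion coordinates carry a deterministic symbolic
perturbation (relative magnitude 1e-9) that breaks ties without touching the
stored vertex coordinates. Degenerate inputs (fewer than three points,
collinear points, duplicated planform positions) are rejected with errors.

Merging surface and bed applies two rules, in order: *clip* (if any vertex
sits above L, keep only `z ≤ L` and re-triangulate; an entirely emergent
mesh is an error) and *mend* (wetted cell centres outside the mesh footprint
are added as DEM terrain vertices at DEM resolution — the simplest
densification consistent with the terrain data). The footprint test uses the
convex hull of the mesh vertices, which is exactly the region a Delaunay
mesh tiles. Which branches fired is recorded in the twin's provenance, and
the no-op case returns the input mesh object unchanged.

## Floating algae index

FAI is a linear-baseline subtraction: the NIR reflectance minus the chord
from red to SWIR. Two identities make it testable without any real scene:
adding a constant to all three bands leaves it unchanged, and it vanishes
exactly when NIR lies on the chord. Both are asserted to 1e-12. The bloom
threshold default is 0.0, appropriate for the spectrally flat synthetic
scenes where any positive uplift is signal; for real sensors the threshold
is atmosphere- and sensor-dependent, so it is a plain config scalar with an
optional per-scene Otsu mode. Sensors without SWIR (e.g. geostationary
ocean-colour imagers) fall back to a two-band normalised difference behind
the same interface; summaries carry the index name so the two are never
silently mixed. Chlorophyll-a inversion from reflectance is deliberately not
implemented: it is a per-lake calibration, not something this package can
supply responsibly.

## Camera segmentation and coverage

Segmentation is a contract, not a model: anything mapping a frame to a
same-size logical mask, deterministically under fixed parameters, plugs in.
Two reference implementations ship:

* the **green-excess baseline** (`G − (R+B)/2 > 20` on the 8-bit scale),
  used wherever determinism matters — surface cyanobacterial scum is
  strongly green-dominant against blue-grey water;
* a **trainable pixel-colour logistic classifier**, fit by full-batch
  gradient descent with backtracking line search. Backtracking makes the
  recorded binary cross-entropy non-increasing by construction, which turns
  "training converged" into a hard property rather than a hope; the seed
  affects only the train/validation split and pixel subsampling. This is a
  linear classifier on colour features and is documented as such; it is one
  valid instance of the contract, not a spatial-context model, and it
  reports its validation F-score so users can judge it on their data.

The coverage ratio is an exact pixel fraction in [0, 1]. Stream monitoring
samples one frame per period (default 1 s) inside a daily observation
window (default 08:00–18:00, daylight camera operation) and refuses
unordered streams. Accuracy is scored by precision, recall and F; the
degenerate case with no positives anywhere is defined as F = 0 with a
warning, and the true-negative count is tracked only to assert that the four
counts sum to the pixel count.

## Kriging and the 3-D field

Nearshore coverage interpolation is ordinary kriging: weights solve the
semivariance system bordered by the unbiasedness constraint, so they sum to
one, constant samples reproduce a constant field, and prediction is exact at
samples when the nugget is zero (tolerance 1e-6 in tests). The variogram
defaults to a spherical model fit by weighted least squares
(weights `N_j / γ(h_j)²`) to the binned empirical variogram; for sparse or
ring-like sample geometries where the usual one-third-of-diagonal cutoff
leaves too few pairs, the cutoff widens to the maximum lag rather than
failing. Duplicate sample locations are averaged (the system is singular
otherwise) with a warning; with fewer than three distinct samples the
method falls back to inverse-distance weighting, warning, because no
variogram is estimable. Interpolated ratios are clamped to [0, 1] and the
clamp count is reported — kriging overshoot is information, not an error.
The nearshore band is water within 500 m of the shoreline by default
(configurable; deployment guidance of one camera per ~5 km of shoreline
says nothing about band width, so this is a package choice), delimited by a
two-pass chamfer distance transform (local steps 1 and √2, error under 8%
of Euclidean — well inside the band-width uncertainty).

For the 3-D field the default is a **separable** scheme: each station's
vertical profile is interpolated linearly to the target depth (constant
beyond its sampled span), then the per-station values are spread
horizontally by inverse-distance weighting (power 2). Profiling stations
sample depth densely but planform sparsely; a plain 3-D inverse-distance
interpolation in anisotropy-scaled coordinates (offered as `method =
"idw3d"`, default anisotropy 100:1) blends across depths wherever the
horizontal distance to stations exceeds the scaled depth spacing — with
eight stations in a few-hundred-metre lake that is almost everywhere, and
measured layer-mean errors reached tens of percent on a linear-in-depth
test field. The separable default preserves the measured vertical structure
at any horizontal distance and reproduces linear-in-depth layer means
exactly. Depth is positive down from the instantaneous surface; cells below
the local bed (level minus DEM elevation) are masked, and sections mask
columns beyond the local bed depth likewise.

## Fusion and the risk rule

The overlay stack is a data structure, not a rendering: layers order
canonically in-situ → satellite → video from back to top regardless of call
order, at most one layer per role per timestamp. The situation summary is a
pure function of the stack (summarising twice is bitwise identical). The
subsurface risk flag operationalises a prose rule: flag a cell when surface
coverage is low (default < 0.05) while chlorophyll-a anywhere below exceeds
a user threshold — the configuration in which a bloom can surface with
little warning. Both thresholds are configurable and the flag count is
monotone non-increasing in the chlorophyll threshold.

## Synthetic fixtures: what they do and do not show

Every input has a seeded generator returning its ground truth: analytic
cone/paraboloid basins (closed-form shoreline radii), spectrally flat scenes
with elliptical NIR uplift (FAI equals the uplift inside, zero outside),
camera frames whose bloom mask is the top `round(f·H·W)` pixels of a smooth
random field (scheduled coverage exact to one pixel; bloom/water colours
separable by construction), linear-in-depth station profiles, and sinusoidal
gauge series whose per-station offsets sum to zero so the cross-station mean
is exact. The default bundle mirrors a realistic deployment scale — 42
shoreline cameras, 8 profiling stations, 3 level gauges — on a 151×151-cell,
5 m basin.

Passing on these fixtures demonstrates the *computational* properties:
level-set monotonicity, mend/clip correctness, index identities, exact
coverage accounting, kriging laws, slicing laws, end-to-end determinism. It
does not demonstrate performance on real imagery: real scenes have clouds,
sun glint and mixed pixels; real camera frames have glare, ripples, debris
and re-aimed cameras; real profiles have sensor drift. Segmentation F-scores
near 1 on the fixtures reflect the constructed colour separability, not
expected field accuracy.

## Problem sizes and numerics

Tests run the shoreline check at 501×501 cells (5 m), kriging recovery from
42 sites onto a 101×101 grid, and the full pipeline on the default bundle;
all sizes are package choices balancing resolution against an ordinary
laptop's patience. Numerical decisions collected in one place: ties at
`z == L` are water; circumcircle membership uses a relative 1e-12 slack;
mesh degeneracy is rejected at relative area 1e-14; kriging exactness is
asserted at 1e-6 with zero nugget; IDW short-circuits exactly at samples
(squared distance below 1e-12); coverage clamping is [0, 1] with counting;
the F-score degenerate case is 0 with a warning; grid cells are half-open
`[x, x + cellsize)` with y increasing north and row 1 at the northern edge.

## Known limitations

No hydrodynamics, waves or non-planar levels; no CRS reprojection (inputs
must be co-registered); no atmospheric correction, cloud masking or scene
download; no live stream ingestion; no temporal gap-filling of station
series; the trainable segmenter has no spatial context; 3-D kriging is not
attempted (eight stations cannot support a stable 3-D variogram).
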