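---
title: "Methods: DIC-based crack detection and opening measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DIC-based crack detection and opening measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crackdic)
```

## The measurement problem

An incomplete crack in a tooth crown is typically a few micrometres wide
— invisible at the ~20 µm/pixel scale of a telecentric imaging setup.
Under a compressive load below normal mastication forces, however, the
two crack faces displace relative to each other by a fraction of a
pixel. crackdic measures that relative motion from a pair of images of a
speckle-painted surface: one before loading (reference) and one under
load (deformed). The chain is

1. **subset matching** — displacement field by normalized
   cross-correlation (NCC),
2. **strain estimation** — windowed plane fits of the displacement,
3. **crack extraction** — thresholding and thinning of the maximum
   principal strain,
4. **crack kinematics** — rigid-body fits of the two crack faces,
   giving opening and slip along the crack.

Everything operates in image coordinates: zero-based pixels, x = column
increasing rightward, y = row increasing downward. Displacements are in
pixels internally; micrometres only appear in reports, via the pixel
scale (default 20 µm/px).

## Subset matching

Each subset (default 39 × 39 px) of the reference is matched inside a
search region (default 69 × 69 px, i.e. ±15 px of displacement) of the
deformed image by maximizing

$$C = \frac{\sum T\,I}{\sqrt{\sum T^2 \sum I^2}},$$

the plain (non-mean-centred) NCC, which is 1 for a perfect match and
invariant to a positive intensity scaling of either patch. The integer
stage is an exhaustive search over the window — at the default
configuration that is 31 × 31 candidate offsets, cheap enough that no
sampling shortcut is needed for correctness. Ties are broken toward the
smallest displacement magnitude, then first-found in row-major order, so
output is deterministic. Constant subsets, windows that leave the image,
and matches below the correlation floor (default 0.5) are flagged
invalid and excluded downstream.

Subpixel refinement maximizes the same C against bilinearly interpolated
grey levels of the deformed image on a shrinking 5 × 5 fractional grid
(spacings 0.25, 0.05, 0.01, 0.005 px by default; `granularity`
controls the finest level).

**Interpolation bias and the prefilter.** Speckle images are not
band-limited, and matching a sharp template against an interpolated
image biases fractional displacements toward integer positions ("peak
locking") — about −0.07 px at quarter-pixel shifts in our synthetic
experiments, which is fatal when the physical signal is a 0.1–0.5 px
crack opening. The standard countermeasure, applied here, is a mild
Gaussian low-pass of *both* images before matching
(`prefilter_sigma`, default 1.5 px). The filter is part of the matcher,
not of the data: it is applied identically to both images at analysis
time, integer-shift recovery remains exact, and the invalid border
margin grows by the filter radius (3σ). The residual bias is below
0.01 px per face. Setting `prefilter_sigma = 0` reproduces the raw
matcher.

## Strain from displacement

The displacement field is first median-filtered (default 3 × 3 lattice
points) to remove isolated mismatches, then at every lattice point a
first-order polynomial is fitted by least squares over a window of
lattice points (default 5 × 5):

$$u \approx a_0 + a_1 x + a_2 y, \qquad v \approx b_0 + b_1 x + b_2 y,$$

in local pixel coordinates, so that $\varepsilon_x = a_1$,
$\varepsilon_y = b_2$, $\gamma_{xy} = a_2 + b_1$ directly. The fit is
exact on affine fields for any window size, and the symmetric shear
measure cancels rigid rotations. Principal strains follow the 2-D closed
form; $\varepsilon_1 \ge \varepsilon_2$ and trace invariance
$\varepsilon_1 + \varepsilon_2 = \varepsilon_x + \varepsilon_y$ hold by
construction. Windows are truncated at the field border (the fit is
still performed while it has rank), keeping the strain grid aligned with
the displacement grid; rank-deficient windows flag the point invalid.

The 5 × 5 default window balances noise suppression against smearing of
the crack signature at the default 4 px lattice step: the strain ridge of
a discontinuity is spread over roughly the subset size plus the fit
window extent. Strains are reported in image coordinates (y downward);
no axis flip is applied.

## Crack extraction

A single threshold on $\varepsilon_1$ either misses weak crack segments
or admits noise. The mask is therefore grown hysteretically: pixels at
or above a high threshold seed it, and 8-connected neighbours at or
above a low threshold are added iteratively until convergence. The mask
is then closed morphologically (disc radius 1), components below
`min_component` (20) px are dropped, and the result is thinned to one
pixel width (Zhang–Suen thinning — implemented in-package, as no
installed dependency provides topology-preserving thinning). Side
branches shorter than `prune` (5) skeleton pixels are removed; each
remaining component is ordered along its longest geodesic (8-connected
pixel graph, Euclidean edge weights) and the longest path is the main
crack, ties broken by higher mean $\varepsilon_1$.

**Thresholds.** Defaults are quantiles of the meaningfully positive
$\varepsilon_1$ values (high 0.99, low 0.90), which transfer across load
levels better than absolute strains; a relative floor ($10^{-6}$ of the
peak) keeps numerical dust on analytically exact fields out of the
population. The quantile defaults presuppose that the crack occupies a
small fraction of the field of view, as in a full-crown image. In a
cropped scene where the smeared crack band covers a fraction *f* of the
grid, the low quantile must stay below 1 − *f*: the 256 px test scenes
here use `low_quantile = 0.75` (band fraction ≈ 0.2), and absolute
thresholds at fractions of the peak strain are equally sensible. A
too-low low-threshold shows up as bifurcating skeletons; adaptive
threshold selection is an open end.

For a second modality in which the crack is directly visible (e.g. a
tomographic slice), `skeletonize_reference_image()` applies
contrast-limited adaptive histogram equalization, median filtering,
Laplacian sharpening and Otsu thresholding of the dark phase before the
same cleaning/thinning, and `skeleton_agreement()` quantifies the match
between the two skeletons as symmetric mean/Hausdorff point-to-path
distances.

## Crack kinematics

At each skeleton point the local tangent is the principal direction of a
total-least-squares line fit to `w` consecutive skeleton points
(default w = 7, the window size at which the opening-vs-window curve has
converged; see below). Valid displacement lattice points near the point
are split by the sign of their across-crack offset into faces A and B.
Points within an exclusion band of the crack line are discarded: a
subset whose support straddles the crack mixes the motion of both faces,
so the band defaults to half the subset size (19.5 px at the default
configuration). The face sample extends `w` lattice points beyond the
band on each side — the band and the sampling depth are separate
concepts, and conflating them (a w-point window *inside* the band) would
leave no usable points at the default step.

Each face is fitted with a small-angle rigid motion
$u = t_x - \theta (y - y_r)$, $v = t_y + \theta (x - x_r)$ by least
squares (reference point = face centroid; at least three non-collinear
points required). The relative displacement at the skeleton point is the
difference of the two fitted motions evaluated there; the rotation term
is applied in the same linearization as the fit, so a globally rigid
field gives an exactly zero relative displacement. The opening is the
component normal to the tangent,
$\delta_n = \sin(\alpha_r)\,\lVert\delta\rVert \ge 0$ with
$\alpha_r \in [0, \pi/2]$ the unsigned inclination angle, and the slip
is the tangential remainder, so
$\lVert\delta\rVert^2 = \delta_n^2 + \delta_t^2$ identically.

**The window-sweep curve.** `cod_window_sweep()` reports the maximal
opening versus `w`. When near-crack points participate (small exclusion
band), small windows are dominated by contaminated samples and
underestimate the opening; the curve rises with `w` and plateaus once
clean points dominate. With the conservative default band every window
already sits on the plateau and the curve is flat to within the matcher
granularity. The default w = 7 is on the plateau in both regimes.

**Limitation: homogeneous strain.** A rigid-body face model cannot
represent background strain. On a crack-free but homogeneously strained
field the apparent opening is of order (strain × gauge length), with the
gauge length the face-centroid separation (~100 px at defaults); for
enamel-scale strains of $10^{-4}$–$10^{-3}$ that is 0.01–0.1 px. Openings
near that floor are not distinguishable from background strain; the
package's tests assert the exact-zero behaviour for rigid fields and
this bound for strained ones.

## The synthetic generator

`generate_speckle()` renders anti-aliased dark discs at uniform random
centres on a bright background with a mild blur, emulating an airbrushed
ink speckle. The defaults (4 px dots, 400 dots per 100 × 100 px ≈ 40%
ink coverage) sit in the mid-range of published speckle-pattern
guidance for DIC; much sparser patterns leave subsets without texture
and make plain-NCC matches ambiguous. The physical dots of the
motivating setup (3–5 µm at 20 µm/px) are sub-pixel, so the on-image dot
size is a free parameter rather than a physical one.

`warp_image()` produces the deformed image by inverse mapping with the
displacement evaluated at the target pixel
($D(x) = R(x - u(x))$, bilinear sampling, exact at integer offsets) —
exact for translations and adequate for the small piecewise-rigid crack
motions used here. Crack fields are piecewise rigid: each face
translates by half the prescribed opening/slip jump and rotates about a
documented reference point (path midpoint by default), which is exactly
the kinematic model the COD stage inverts. Additive i.i.d. Gaussian
intensity noise (seeded, clipped to [0, 1]) stands in for camera noise.

What the generator does **not** emulate: optics (defocus, vignetting,
lens distortion), out-of-plane motion and 3-D surface topography,
spatially correlated sensor noise, illumination drift, and paint
decohesion at the crack lips. Passing tests therefore demonstrate
correctness of the algorithms under the stated image model, not
end-to-end accuracy on real tooth images.

## Numerical choices and reproducibility

* Matcher tie-breaks, the quantile floor, and the refinement schedule
  are as described above; all randomness is seeded, and identical
  inputs, configuration and seed give bit-identical outputs (asserted
  in the tests).
* The plain NCC of the matching stage is kept deliberately, including
  its known sensitivity to low-texture subsets on bright backgrounds; a
  zero-mean variant would be more robust but is a different statistic.
* Degenerate inputs: empty masks warn and propagate empty skeletons; an
  all-flagged COD profile warns; configuration errors (even subset,
  subset ≥ search, bad thresholds) fail fast with messages.
* Test and acceptance problem sizes: 256 × 256 px scenes for
  matcher-level checks and 96–128 px scenes for smoke tests, chosen so
  the full suite completes in minutes on one CPU while every stage
  still operates well inside its valid-margin regime; openings span
  0.1–0.5 px (2–10 µm at 20 µm/px), the clinically reported micro-crack
  magnitude, plus 1–5 px for the large-opening regime.

## Known limitations

* Zeroth-order (rigid) subsets: under a uniform strain gradient the
  matched displacement is the subset-average one, so strains are
  accurate only for |gradient| ≪ subset⁻¹ · px; first-order subset shape
  functions are out of scope.
* Single 2-D modality; no stereo/3-D DIC, no crack growth tracking over
  load series, no multi-crack network topology.
* The COD floor set by background strain (see above) and by the matcher
  noise (~0.01 px) corresponds to ~0.2 µm at 20 µm/px; openings below
  that are not resolvable.
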