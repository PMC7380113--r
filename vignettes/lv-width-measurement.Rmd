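---
title: "Measuring fetal lateral-ventricle width from on-screen calipers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring fetal lateral-ventricle width from on-screen calipers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvmeasure)
```

## The measurement problem

The width of the fetal lateral ventricle (LV), read off the transventricular
plane of a second-trimester head ultrasound, is the standard screen for
ventriculomegaly (clinical cut-off 10 mm). Exported ultrasound frames carry
no reliable physical calibration metadata; what they do carry is the
on-screen ruler — a burned-in column of bright tick marks. Converting any
pixel measurement to millimeters therefore needs two things:

1. **PPC (pixels per centimeter)** — recovered from the ruler ticks;
2. **the LV diameter in pixels** — the widest chord of the segmented LV.

`lvmeasure` implements both, downstream of *any* segmenter that supplies an
LV mask and a caliper bounding box (the package ships a deliberately naive
brightness-based detector so its synthetic phantoms run end to end; a
trained network would plug into the same sidecar contract).

## PPC from the caliper ruler

Two ruler conventions occur on clinical machines: the **10-caliper**
(identical ticks 10 mm apart) and the **5-caliper** (ticks 5 mm apart,
alternating big–small–big). If `s` is the inter-tick spacing in pixels,

\[ \mathrm{PPC} = s \;\; (\text{10-caliper}), \qquad
   \mathrm{PPC} = 2s \;\; (\text{5-caliper}). \]

The tick extraction chain in `estimate_ppc()` is:

1. **Background filtering** (`preprocess_caliper()`): Laplacian edge
   magnitude → binarise strictly above 127 → 3×3 morphological opening.
   The Laplacian has zero response inside large smooth bright structures,
   so only small, sharp objects survive; the opening removes sub-kernel
   specks.
2. **Contours** (`find_contours()`): one contour per 8-connected component,
   represented by its boundary pixels and referenced by the top-left corner
   of its bounding box.
3. **Three prior-knowledge filters**: discard contours with more than 30
   boundary points (`filter_large()`); vote the image line crossed by the
   most contours — the ruler axis (`ruler_axis_vote()`); take the *mode* of
   adjacent reference-point distances along that axis
   (`adjacent_spacing_mode()`) and keep the longest chain of contours whose
   gaps match it within ±2 px (`select_scale_ticks()`).
4. **Type classification** (`classify_caliper()`): each tick's size score is
   the long side of its minimum-area rectangle; a strict big/small
   alternation with ratio ≥ 1.5 is a 5-caliper, a coefficient of variation
   < 0.2 a 10-caliper, anything else an explicit "ambiguous caliper" error
   rather than a guess.

### Parameter defaults and why

| key | default | role |
|---|---|---|
| `binarize_threshold` | 127 | fixed prior of the method (8-bit midpoint) |
| `max_contour_points` | 30 | fixed prior: ticks are small |
| `spacing_tolerance_px` | 2 | gap jitter tolerated in the tick chain |
| `ruler_axis` | vertical | on-screen rulers run down a column |
| `laplacian_kernel`, `open_kernel` | 3 | smallest odd stencils; larger values trade speck robustness against tick survival |
| `five_ratio_min` | 1.5 | big/small tick lengths differ by ~2× in practice; 1.5 rejects size jitter on uniform rulers |
| `ten_cv_max` | 0.2 | uniform rulers vary by rasterisation only |

The first two values are the method's own constants; the rest are documented
package choices, all collected in `ppc_config()`. The ruler-axis wording is
genuinely ambiguous between "a line of constant x" and "of constant y"; the
vertical reading matches every machine layout we emulate, and
`ruler_axis = "horizontal"` covers the transpose. Distances between adjacent
ticks are measured along the ruler axis between reference corners, which is
identical to the Euclidean distance for aligned ticks. Two tie-breaks are
deliberate: the spacing mode breaks ties toward the *smaller* distance so a
doubled gap caused by a missed tick can never beat the true spacing, and the
axis vote breaks ties toward the smaller coordinate for determinism.

## LV diameter by the minimum-enclosing-rectangle method

`measure_lv()` mimics how a sonographer places calipers across the widest
part of the ventricle:

1. fit the minimum-area rotated rectangle (MER) of the mask's convex hull
   (exact edge-sweep over hull edges);
2. rotate the mask so the rectangle's **longer** edge is horizontal;
3. scan every column for the vertical chord between topmost and bottommost
   foreground pixels; the longest chord is the diameter
   (`max_vertical_chord()`);
4. map its endpoints back through the inverse rotation and convert:
   `width_mm = 10 · pixel_length / PPC` (`to_physical()`).

Two geometry choices deserve a note. First, the conventional MER tilt
`theta_deg` (the edge inclination closest to the x-axis) is reported, but
the rotation step uses the inclination of the *longer* edge: rotating by the
conventional tilt makes the *short* edge horizontal whenever that edge
happens to lie closer to the x-axis (an ellipse at 80° is the classic case),
and the vertical chord would then return the major axis instead of the
width. Rotating the long edge flat guarantees the chord is the minor extent
for any orientation, which is what the rotation-invariance tests pin down.
Second, the rotation resamples bilinearly and cuts at 0.5 rather than using
nearest-neighbour lookup: the output is still a strict binary mask, but the
rotated boundary is reproduced about half a pixel more faithfully, and
chord lengths lose none of that half pixel to boundary chipping.

Chord endpoints are extreme *pixel centres*, not sub-pixel contour
intersections; a single-row mask therefore has chord length 0, and an
n-row column has length n − 1. At clinical calibrations (PPC ≥ 30 px/cm)
the resulting ±1 px is below the 0.1 mm display precision to which
`width_mm` is rounded in the result JSON (the R object keeps full
precision). Masks with several components keep the largest with a warning;
empty masks are a validation error.

## What the synthetic phantoms emulate — and what they do not

`compose_scene()` renders, with full ground truth and seeded determinism:

* a dark background (mean intensity 20) with multiplicative uniform speckle
  of amplitude `noise_level` — background only, structures stay crisp;
* a caliper ruler: 2-px-high bright bars, big/small lengths 9/4 px,
  reference corners exactly `spacing_px` apart (the tick chain after the
  Laplacian shifts every reference corner by (−1, −1) uniformly, so spacings
  are preserved exactly);
* a bright filled ellipse whose minor axis is `width_mm` at the scene's PPC,
  rotated by a known angle — the LV stand-in; the mask is the exact
  rasterisation;
* optionally, small distractor blobs emulating LV-like structures.

The phantoms give the pipeline *exactly recoverable* inputs: at noise 0 the
tick chain survives the morphology unchanged, so spacing and type recovery
is exact over the whole tested grid, and speckle at the tested amplitudes
never crosses the binarisation threshold. Passing these suites shows the
*arithmetic and geometry* of the method are right. It does **not** show
robustness to what real ultrasound adds — blurred LV boundaries, adjacent
echogenic structures overlapping the ruler, anti-aliased or coloured ticks,
burned-in annotation text — nor anything about segmentation quality, which
is upstream of this package's contract. Generator intensities are free
parameters (machine-dependent in reality); the pipeline never keys on their
specific values, only on contrast surviving the 127 threshold.

## Numerical choices and degenerate inputs

* MER of collinear or single-pixel masks degenerates to a 1-px-high
  rectangle along the principal direction; reported rectangle sides are
  pixel extents (projection range + 1) so an axis-aligned w×h block reports
  exactly (w, h).
* The rotation canvas is enlarged to hold the rotated corners, so nothing
  clips; the coordinate transform is exactly invertible
  (`transform_points()`, round-trip < 0.5 px).
* `score_average`, `confusion_metrics` and `width_error_stats` compute from
  raw counts/errors and round only for display. Zero-denominator metrics
  are `NA`, never silently 0. The detection report exposes *both* the
  textbook row-wise sensitivity/specificity and the column-wise variants
  (`sensitivity_paper` = precision, `specificity_paper` = negative
  predictive value) that some clinical summaries print under those names —
  reproducing published tables without propagating the naming silently.
* A failed measurement is scored as a 0 mm prediction in
  `width_error_stats()` (its absolute error is then the full ground-truth
  width), which inflates MAE and SD honestly rather than dropping failures.
  SD is the population standard deviation of absolute errors; the sample
  form is also reported since the convention is not universal.
* The MAE percentage is defined as `100 · MAE / mean(gt)` — one consistent
  convention among several; it is labelled as such.

## Known limitations

* **Round shapes.** The MER's short side equals the true minimal width for
  elongated, roughly symmetric shapes (ellipse-like LVs, major/minor ≳ 1.5).
  For nearly circular regions, or strongly asymmetric polygons, the MER
  orientation is unstable or the minimal width lies off the MER axis, and
  the chord can exceed the rotating-calipers minimal width by several
  pixels. This is a property of the method, not of the implementation; the
  oracle-equivalence suite therefore draws from the elongated ellipse
  family the generator produces.
* **Coarse masks.** Below ~40 px of minor axis, rasterisation can snap the
  MER to the image axes for mildly elongated shapes and cost ~2 px of
  chord; clinical LVs at typical calibrations are comfortably larger.
* **Ruler pathologies.** Curved/radial rulers, fewer than 3 visible ticks,
  and burned-in calibration text are out of scope; ambiguous tick-size
  patterns raise a classification error instead of guessing.

## Problem sizes used by the test and acceptance suites

The suites run noiseless recovery over both ruler types × spacings
20–80 px × 3–12 ticks, 100 noisy rulers at speckle amplitude 0.3, the width
round-trip over widths {5, 8, 10, 12, 15} mm × PPC {30, 59, 60, 80} ×
orientations 0–170°, 50 random elongated phantoms against the
rotating-calipers oracle, and a 30-scene end-to-end cohort — sizes chosen so
the whole suite completes in about a minute on a single core while covering
every branch of the method.
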