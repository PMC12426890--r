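---
title: "Seed counting by image processing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed counting by image processing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedcount)
```

## The problem and the model

Seeds photographed on a uniform surface are, to a first approximation,
compact dark (or light) blobs on a homogeneous background. Under that
assumption counting reduces to segmentation: convert to intensity, smooth
away sensor noise, split pixels into foreground and background at a single
threshold, and count the connected foreground regions. Each region is then
measured — bounding box, length and width in millimetres through a linear
pixel-to-mm calibration, aspect ratio — so the same pass yields simple
morphometrics alongside the count.

The method's assumptions are worth stating explicitly, because they are
also its failure modes:

* **Bimodal intensity.** Seeds must differ from the background in
  luminance. A single global threshold cannot separate seeds whose
  intensity straddles the background's.
* **Spatial separation.** Two seeds that touch form one connected
  component and are counted once. No de-clumping (e.g. watershed) is
  attempted; oversized regions are instead *flagged* as suspected
  clusters (area above `oversize_factor` × the median region area,
  default 3).
* **Uniform illumination.** The threshold is global. Strong illumination
  gradients combined with a very sparse foreground can defeat Otsu's
  criterion: splitting the broad background class can rival separating
  the small seed class in between-class variance. This is observable in
  this package — with a 20 % left-to-right gradient and < 1 % foreground
  the threshold collapses into the background mode — and is why the
  generator's default gradient is 0 and why a fixed `threshold` override
  exists in `count_config()`.

## Pipeline parameters

| parameter | default | units | why |
|---|---|---|---|
| `kernel_px`, `sigma` | 5, 1.0 | px | standard denoising scale for high-resolution photographs; `kernel_px = 1` disables smoothing |
| `threshold` | `NULL` (Otsu) | 8-bit level | parameter-free and reproducible under controlled lighting; fixed level available |
| `polarity` | `auto` | — | seeds may be darker than white paper or lighter than a black table; `auto` takes whichever phase is the minority (< 50 % of pixels) |
| `connectivity` | 8 | — | matches contour-based counting of diagonal-adjacent pixels; 4 available |
| `min_area_px` | 10 | px at 3024 × 4032 | rejects sensor specks without touching the smallest real seeds; rescaled by relative image area so behaviour is resolution-independent |
| `mm_per_px` | 1 | mm/px | 1 reports pixel units; set from a reference object via `calibration_from_reference()` |
| `tau` (post-processing) | 0.25 | — | conventional deployment confidence threshold; strict inequality (a detection exactly at τ is dropped) |
| NMS IoU | 0.45 | — | conventional suppression threshold; class-wise, with a class-agnostic mode for single-species images |

Grayscale uses the BT.601 weights (0.299, 0.587, 0.114) — the de facto
imaging-library standard, chosen for bit-reproducibility — rounded half-up
to 8-bit. Blur borders are reflect-padded to avoid the dark halo that
edge-zero padding would smear into near-edge seeds. Detection confidence
is objectness × max class probability (the single-stage detector
convention; `confidence = "objectness"` is available).

## Counting rule

The count is the number of connected components surviving the area filter.
Contours are still computed — external border only, holes ignored, chain-
simplified to straight-segment endpoints — but serve reporting and
measurement; on external-only contours, counting contours and counting
components are the same thing, and components make the simpler contract.
Regions are ordered by bounding-box `y_min` (ties: `x_min`, then label) so
seed identifiers read top-to-bottom. Regions touching the image border are
counted but flagged, since silently dropping them would bias counts low.

## Evaluation conventions

Matching is PASCAL-style: predictions in descending confidence, each taking
the unmatched same-class ground-truth box of highest IoU when that IoU
≥ 0.5, one-to-one. AP uses all-point interpolation (the precision
envelope `max_{r' ≥ r} p(r')` integrated over recall) — deterministic and
the modern convention; the 11-point variant is available behind a flag.
mAP can be computed per species-class or class-agnostic (all seeds one
class); both modes are supported because either convention is defensible
for single-species images, and neither is asserted as canonical.

Zero-denominator cases are defined, not errors: precision with no
predictions is 0, recall with no ground truth is 0, F1 with P + R = 0 is
0, AP with no ground truth is 0 if any prediction exists and vacuously 1
otherwise; all are logged via `message()`. Replicate summaries use the
n − 1 sample standard deviation over √n — the convention behind
"mean ± SE" rows in replicated counting trials (e.g. six replicates of a
10-seed sample with one 11 give 10.17 ± 0.17).

## The synthetic generator

`simulate_seed_image()` emulates the desk imaging setup the counter is
designed for: seeds as rotated filled ellipses with jittered size
(major axis 18–30 px), elongation (aspect 1.2–2.2, spanning round to
elongated seed shapes), and dark-brown fill, composited on calibrated
white-A4, orange-table, or black-table backgrounds, then additive Gaussian
noise and a multiplicative left-to-right illumination gradient (both
default 0 so the baseline suite is exact). The default canvas is
1008 × 1344 — the native 3024 × 4032 portrait capture at one third scale —
which keeps tests fast while preserving aspect ratio and the
area-rescaled speck filter's behaviour.

Placement is rejection sampling with a 10,000-attempt cap and an explicit
capacity error naming the limiting parameter. When touching is disallowed
the default minimum centre separation is `max(major_axis) + 12` px — the
largest seed plus two 5-px blur kernels — which guarantees that smoothed
seeds remain disjoint components, hence that the true count is exactly
recoverable. Ground truth (tight boxes, union mask, count) is recorded
before degradation. Identical configurations are bit-identical;
`run_count_experiment()` derives per-image seeds as
`master_seed + 1000·(quantity_index − 1) + (replicate − 1)` so every image
is individually reproducible.

What the generator does **not** emulate: shadows, specular highlights,
seed texture and hila, camera distortion, chromatic backgrounds with
texture, or the acrylic light-box. Passing tests on synthetic scenes
therefore demonstrates the pipeline's correctness — segmentation,
counting, measurement, metric arithmetic — not its robustness to
real-world lighting, which the assumptions above bound.

## Degradation behaviour

Two one-sided failure modes are deliberately reproducible:

* **Clusters undercount.** With `allow_touching = TRUE`, overlapping
  seeds merge; the count can only fall below the truth (never above,
  absent noise).
* **Specks overcount.** Injected single-pixel salt noise, with smoothing
  off and the area filter disabled, adds one region per speck; the count
  can only rise above the truth. The default area filter removes them
  exactly.

Both behaviours are asserted in the test suite as inequalities against
generator ground truth.

## Numerical choices and degenerate inputs

* Rounding is half-up at every 8-bit quantization point (base R's
  `round()` is half-to-even, so `floor(x + 0.5)` is used).
* Otsu ties break to the smallest level; a constant image is a
  degenerate histogram and errors at the primitive level, while the
  end-to-end counter treats a constant (post-blur) image as "no
  foreground, count 0" — the correct reading of an empty background shot.
* NMS confidence ties break to the larger box, then input order, making
  suppression deterministic.
* Contours are traced with Moore border following (Jacob's stopping
  criterion), orientation normalized to a non-negative shoelace sum in
  image coordinates; a single-pixel region yields a one-vertex contour.
* Component labeling is run-based (horizontal runs merged across rows by
  union-find), so cost scales with the number of runs; it is validated
  against a flood-fill oracle under both connectivities.

## Problem sizes in the test suite

The suite exercises: counting at N ∈ {0, 1, 10, 70, 100, 200} across all
three backgrounds at the 1008 × 1344 canvas; the replicated experiment at
6 replicates × {10, 100}; oracle equivalence on 200 random 12 × 12 masks
(both connectivities), 100 random ranked AP instances, and exhaustive
256-level Otsu scans — sizes chosen so each suite completes in seconds
while covering the regimes the method is meant for.

## Known limitations

Touching seeds are counted as one; global thresholding fails under strong
uneven illumination with sparse foreground; very low-contrast seeds (e.g.
pale seeds on white paper) may fall below any global threshold's
separability; `min_area_px` trades speck rejection against the smallest
real seeds at low resolutions. The detector post-processing chain is an
interchange-format implementation: it evaluates and post-processes
detector outputs but includes no trained detector.
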