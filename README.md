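# seedcount

Desk-scale seed counting by classical image processing, with the
post-processing chain of single-stage object detectors and the standard
detection-evaluation metrics, for R.

Counting crop and weed seeds is routine in germination assays, yield
estimation, seed production, and weed-seedbank studies, and is tedious and
error-prone by hand — especially for micro-sized seeds counted by the
hundreds. When seeds are photographed spread out on a uniform surface
(white A4 paper, an orange or black table top), a classical
image-processing pipeline counts them reliably without any training data.
`seedcount` implements that pipeline end to end, plus everything needed to
*evaluate* automated counters, and a deterministic synthetic image
generator so the whole stack is testable with exact ground truth.

## What it computes

**Image-processing (IP) counter** — for an RGB image `I`:

1. grayscale conversion (ITU-R BT.601: `Y = 0.299 R + 0.587 G + 0.114 B`);
2. Gaussian smoothing (separable kernel, default 5 px, σ = 1, reflect
   borders);
3. binary thresholding — Otsu's between-class-variance maximizer by
   default, automatic foreground polarity (seeds are the minority phase);
4. connected-component segmentation (8-connectivity by default) with
   external contour tracing and chain simplification;
5. speck rejection by area, top-to-bottom sorting, and per-seed
   morphometrics — bounding box, length `L` and width `W` in millimetres
   via an mm-per-pixel calibration, aspect ratio `L/W`;
6. the seed count = the number of surviving regions.

Touching seeds merge into one component and are counted once (flagged as
suspected clusters); no watershed splitting is attempted.

**Detector post-processing** — from a raw detection grid (normalized
`cx, cy, w, h`, objectness, class probabilities): box decoding to pixel
coordinates, confidence = objectness × max class probability, strict
confidence thresholding (default τ = 0.25), greedy class-wise non-maximum
suppression (default IoU 0.45), and the final count.

**Evaluation metrics** — IoU; PASCAL-style greedy one-to-one matching at
IoU ≥ 0.5; `Precision = TP/(TP+FP)`; `Recall = TP/(TP+FN)`;
`F1 = 2PR/(P+R)`; per-class average precision by all-point interpolation of
the precision–recall staircase; `mAP = (1/N) Σᵢ APᵢ`; and replicate count
summaries `mean ± SE` with `SE = s/√n` (sample standard deviation, n − 1).

**Synthetic generator** — seeds as rotated filled ellipses with size,
shape, and colour jitter on calibrated white/orange/black backgrounds,
optional sensor noise and illumination gradient, exact ground truth (boxes,
mask, count), bit-reproducible from an RNG seed.

## Worked example

```r
library(seedcount)

sim <- simulate_seed_image(sim_config(n_seeds = 30, rng_seed = 11))
res <- count_seeds(sim$image, count_config(mm_per_px = 0.07))
print(res)
#> Seed count: 30
#>   threshold level: 165 | foreground polarity: dark | regions filtered out: 0
summary(res)
#> Seed count: 30
#>   length (mm): mean 1.52  range [1.19, 1.96]
#>   width  (mm): mean 1.16  range [0.63, 1.61]
#>   aspect L/W : mean 1.35
#>   area  (px) : median 268
head(as.data.frame(res), 3)
#>   seed_id x_min y_min x_max y_max length_mm width_mm aspect_ratio area_px ...
#> 1       1   277     9   297    26      1.40     1.19     1.176471     263
#> 2       2   627    24   650    46      1.61     1.54     1.045455     324
#> 3       3   397    26   414    50      1.68     1.19     1.411765     320
```

All 30 seeds are found; Otsu picked level 165 and the dark phase as
foreground (dark seeds on white paper), and each seed's box, millimetre
dimensions, and aspect ratio are reported in top-to-bottom order. The
replicated accuracy experiment mirrors a counting trial — six replicate
images per quantity, mean ± standard error:

```r
run_count_experiment(quantities = c(10, 70, 100), replicates = 6,
                     master_seed = 1)
#> Counting-accuracy experiment (master seed 1 )
#>   truth  10 seeds: 10.00 ± 0.00 over 6 replicates
#>   truth  70 seeds: 70.00 ± 0.00 over 6 replicates
#>   truth 100 seeds: 100.00 ± 0.00 over 6 replicates
```

On clean, non-touching scenes the IP counter is exact at every quantity.

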