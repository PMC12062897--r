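---
title: "Methods: shape-filtered segmentation and per-worm fluorescence quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape-filtered segmentation and per-worm fluorescence quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormquant)
```

## The measurement problem

Transcriptional reporters in *C. elegans* are routinely read out as the
mean fluorescence of individual animals. The classical workflow traces
each worm by hand on the brightfield channel, transfers the trace to the
fluorescence channel, and subtracts a hand-selected background region —
accurate but slow enough to cap sample sizes. wormquant automates the
per-worm segmentation and measurement for images in which the worms have
been physically pushed apart so that no two animals touch. Touching-worm
separation is deliberately out of scope: worm transparency under backlit
brightfield produces light and dark patches within one animal, and
separating clumps reliably requires trained models that defeat the point
of a zero-training pipeline.

The pipeline per image pair is fixed:

1. brightfield preprocessing — percentile contrast stretch, illumination
   correction, slight Gaussian blur;
2. Otsu thresholding into a binary image, hole filling and speck removal
   (the cleaned result is the *step-2 mask*);
3. connected-component labeling and a **worminess** filter;
4. a minimum-area filter;
5. mask transfer to the raw fluorescence channel: per-worm mean and SD,
   per-image background subtraction, a numbered colour overlay for manual
   quality control, and CSV tables.

## The worminess score

For a candidate object with boundary length $P$ and pixel area $A$,

$$\mathrm{worminess} = \frac{P}{4\sqrt{A}}.$$

The score is scale invariant: rescaling a shape changes $P$ and
$\sqrt{A}$ by the same factor. A circle attains the continuous minimum
$\sqrt{\pi}/2 \approx 0.8862$ (0.89 at two decimals); a square scores
exactly 1; elongated shapes score higher, monotonically in aspect ratio
(a $w:1$ rectangle scores $(2w+2)/(4\sqrt{w})$). Adult worms — long,
thin, gently curved tubes — fall in a narrow band, and the default
acceptance band is $[1.5, 2.1]$, inclusive at both ends. Round debris
(eggs, dust, bubbles) scores near the circle floor and is rejected;
very ragged or merged objects score above the band and are rejected
too. Both bounds are configurable for morphologically unusual mutants.

```{r}
worminess(2 * pi * 50, pi * 50^2)   # ideal circle, any radius
worminess(4, 1)                     # unit square
```

## Perimeter estimation

Worminess is only as good as the boundary-length estimate, and naive
estimators are badly biased on rasterized shapes: counting boundary-pixel
steps inflates diagonal boundaries by tens of percent, which would shift
whole-image score distributions out of any fixed band. The Crofton
4-direction formula is unbiased on average over orientations but
underestimates axis-aligned straight edges by about 6%, enough to push a
wide, axis-aligned worm below 1.5.

The default estimator therefore extracts the 0.5-level marching-squares
contour of each object (sub-pixel vertices on pixel-edge midpoints),
smooths the closed vertex chain with a circular moving average of window
5 to suppress the staircase overestimate on shallow diagonals, and sums
the polygon length. Measured against continuous truth this estimator is
accurate to about 2% across orientations: a 50 px square scores 0.98 of
its true perimeter, rasterized disks of radius 10–100 px score worminess
0.886–0.891 against the continuous 0.8862, and straight tubes of widths
10–15 px stay within 1% of the capsule closed form at every tested
orientation. The Crofton estimator remains available
(`perimeter_estimator = "crofton"`) and as a numerical cross-check; the
estimator used is recorded on the shape table.

## Preprocessing choices

* **Contrast** — linear percentile stretch, defaults 1st/99th
  percentile, onto a [0,1] working scale. Robust to hot pixels, and the
  only normalization the rest of the pipeline assumes.
* **Illumination** — the brightfield of a transmitted-light scope shades
  multiplicatively, so the image is divided by a smooth background
  estimate: a very wide Gaussian ($\sigma$ = 1/8 of the shorter side by
  default) of the image itself, then renormalized so the median is
  unchanged. A subtractive mode exists for additive shading. Because the
  background varies over much larger scales than a worm, the estimate is
  computed on a block-mean-decimated grid and interpolated back, which
  changes nothing measurable and keeps large images fast.
* **Blur** — Gaussian, $\sigma = 2$ px by default ("slight"): its job is
  to merge the light/dark mottling inside each worm so one global
  threshold can capture whole animals. All convolutions use reflective
  padding; circular or zero padding would create dark border rims that
  threshold into spurious objects.
* The fluorescence channel is **never preprocessed**: statistics are
  taken on raw intensities in native units.

## Thresholding and cleanup

Otsu's criterion (maximum between-class variance over a 256-bin
histogram) picks the threshold; ties break to the lowest bin so runs are
deterministic. Default polarity is dark-foreground — after correction
the blurred worms read darker than the backlit background — with a flag
for inverted optics. Background holes of at most `max_hole_area`
(default 100 px²) are filled, then foreground specks below
`min_speck_area` (default 20 px²) are dropped; the operation is
idempotent. Components use 8-connectivity by default so one-pixel
diagonal necks of thin worms do not fragment. Border-touching objects
are kept but flagged (`touches_border`), with an opt-in exclusion.

## Background and measurement

The per-image fluorescence background is the mean over all pixels
**outside the step-2 mask** — the complement of every thresholded
candidate object, *including* debris that the worminess and size filters
later remove. This is the detail most worth testing: a background taken
over the complement of only the *kept* objects would re-admit debris
pixels, and non-fluorescent debris (dark particles on a glowing plate)
would drag the estimate down. The regression test plants such debris and
verifies the step-2 background moves by under 0.1% while the wrong
definition moves by over 1%.

Per worm, the mean and population SD (divide by $n$; the convention for
descriptive per-object statistics, and either convention satisfies the
method description) of the raw fluorescence under the mask are recorded,
along with area, perimeter, worminess, and
`mean_fl_bgsub = mean_fl - background_fl`. Negative values are reported
as-is — clamping would bias condition means near background. Worm
numbers are assigned in label order and are guaranteed to match the
numbers stamped on the QC overlay; a JSON sidecar per overlay stores
number, centroid and colour so tooling never parses rendered text.

## The synthetic plate generator

Every stage is validated offline against generated ground truth. A
default plate emulates a 16-bit field at ≥35× magnification:

* 20 worms per image, tubes ~120 px long and ~12 px wide (aspect ~10,
  ±10% per-worm jitter), bent along a low-order sinusoid with amplitude
  up to 0.2 of length;
* brightfield: background level 40000 with a 0.8–1.2× horizontal
  multiplicative ramp, worms at 0.45× local background, additive
  Gaussian noise (SD 800); an optional "mottled" mode adds within-worm
  light/dark texture to exercise the blur step;
* fluorescence: flat planted background 500, planted per-worm means
  (condition mean ±5% per-worm jitter), additive noise SD 50 (≈1% of the
  usable dynamic range);
* 2 round debris (radius ~15 px) that are dark in brightfield and
  non-fluorescent (intensity 0) by default — precisely the objects the
  step-2 background rule must exclude — and 3 sub-threshold 2×2 specks;
* placement enforces a minimum pairwise gap, default 8 px (~0.7 worm
  widths). Worms separated by less than roughly the blur scale would
  merge into one thresholded object exactly as genuinely touching worms
  do, so the default emulates animals that have actually been pushed
  apart; the floor of 3 px ("non-touching") remains the hard constraint.

All randomness flows from one integer seed, split into independent
sub-streams for placement, noise fields, debris and specks — so adding
debris to a plate changes neither the worm layout nor the noise, which
is what makes the background regression test exact. The generator does
**not** emulate real worm texture, eggs or larvae, optical PSF,
vignetting beyond a smooth ramp, or touching animals; passing tests
therefore demonstrate the pipeline's logic and calibration, not its
performance on adversarial real-world plates.

Validation sizes used by the test suite: 1000×1000 px plates, 4
conditions with planted means 1200/2400/4000/6000 over background 500,
20 worms per condition, 20 seeds. On these, detection recall and
precision are 1.0 at IoU ≥ 0.6, recovered per-condition means preserve
the planted order in every seed, and min–max-scaled recovered vs planted
per-worm means correlate above 0.99.

## Numerical and degenerate-input decisions

* Constant images: contrast stretch returns the input (rescaled to
  [0,1]) with a warning; thresholding returns an empty mask with a
  warning; an image that thresholds entirely to foreground is an error
  (no background pixels to average).
* The illumination divisor is guarded by a small epsilon.
* Rasterization uses closed inclusion (a pixel belongs to a disk if its
  centre is within the radius), which widens a nominal-width tube by
  about one pixel; shape expectations in the tests account for it.
* Two runs with identical inputs and configuration produce byte-identical
  CSVs and pixel-identical overlays; batch processing is per-image
  isolated, and a failing image is logged and skipped without aborting
  the batch.

## Known limitations

Touching or overlapping worms are a single object and will typically be
rejected by the band (merged pairs score high) — they are lost, not
split. Otsu thresholding assumes the worm class is a non-negligible
fraction of the image (the intended inputs carry 15+ animals per field);
on very sparse fields (worm coverage well under 1%) the criterion can
split the background instead, producing noise objects that the filters
then discard — use `threshold_method = "fixed"` for such images. The default band assumes adult, roughly 10:1 worms; L1–L3 larvae
or dumpy mutants need adjusted bounds and minimum area. The worminess
floor for *measured* objects is asserted at 0.85 rather than the
continuous 0.8862 to leave room for estimator bias on small rasterized
shapes; objects only a few pixels across can score below it, but such
objects are removed as specks long before scoring.
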