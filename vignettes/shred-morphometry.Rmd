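---
title: "Measuring curved plant fragments: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring curved plant fragments: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shredmorph)
```

shredmorph measures the two-dimensional size — length and width in mm — of
small, elongated, often curved plant-material fragments (tobacco shreds of
the four industrial classes: tobacco silk Y, cut stem G, expanded silk P,
reconstituted sheet Z) photographed on a light ground. It also provides the
surrounding machinery such a measurement system needs: background-shadow
elimination, detection-network building blocks with the complete-IoU
objective, detection metrics (precision, recall, AP, mAP over IoU
thresholds), and a synthetic scene generator with exact ground truth used to
validate all of it. This vignette explains the models and the design
decisions; the README shows the worked example.

## The size-calculation model (LWC)

A fragment is modelled as a constant-width tube along a smooth centerline.
Given a detection box, the algorithm proceeds:

1. **Crop and isolate.** The box region is cropped with a 2 px margin and
   binarised. The primary rule thresholds against the background level
   estimated from the crop border (median minus `max(8, 4*mad)`), because
   blended crops frequently contain fragments of two different shades and a
   global Otsu split then lands *between the fragments* instead of between
   fragments and ground; Otsu is retained as a fallback when the border
   estimate degenerates. Connected components are labelled and the component
   whose centroid is nearest the box centre is kept (ties go to the larger
   area). Interior holes — texture noise crossing the threshold — are
   filled, because a single interior hole halves a strip's inscribed-circle
   diameter. When the caller already has a scene-level segmentation (the
   shadow-elimination mask), it can be passed in and replaces the crop-level
   binarisation; the pipeline does this by default, which removes a second,
   redundant and less-informed thresholding step.
2. **Rotate to horizontal.** The minimum-area bounding rectangle (rotating
   calipers over the convex hull of pixel corners) gives the long-side angle;
   the mask is rotated so that side is horizontal and cropped to the
   rectangle (long side `x1`, short side `y1`).
3. **Strip slicing.** The rectangle is cut into `n` vertical strips of width
   `x1 / n`. `n` defaults to 50 — enough that each strip of a typical
   10–25 mm fragment at 10 px/mm is 2–5 px wide, so the centroid sequence
   resolves bends without chasing pixel noise. Strips narrower than 2 px are
   rejected; callers with very short objects reduce `n`.
4. **Length.** The foreground centroid of each strip is computed; a cubic
   smoothing spline `y(x)` is fitted through the centroids and its arc length
   integrated by dense chordal sampling (1000 points). Two refinements
   matter:
   - centroids within half a tube width of the horizontal extremes are
     excluded from the fit — there the cross-section is cut by the fragment
     tip and the centroid no longer tracks the medial axis;
   - each end of the fitted curve is extended along its tangent, walking
     inside the mask in 0.25 px steps (capped at three half-widths), so the
     tip-to-tip centerline is measured. A straight bar is then measured
     exactly; a semicircular arc, whose near-vertical limbs a plain `y(x)`
     fit under-integrates, is recovered to within ~1–2 %.
   With fewer than 4 usable centroids the fit falls back to the centroid
   polyline plus horizontal end residuals.
5. **Width.** Per strip, the largest circle centred in the strip and
   contained in the object has radius equal to the maximum of the interior
   Euclidean distance transform (computed once on the background-padded
   mask); the diameter convention `2 d - 1` is exact for odd pixel widths and
   at most 1 px low for even ones. The object's width is the mean diameter
   over non-empty strips — the mean, not a robust alternative, because the
   profile is the object's width profile and flat ends are already the only
   systematic casualty.
6. **Calibration.** `pixels_per_mm = block_px / block_mm` from a rendered
   reference block of known physical size (default 3 mm x 9 mm, long side
   used). The generator records the block's rendered pixel length;
   `measure_block_px()` recovers it from the image by colour within ~1 px.

Signed relative errors are `100 * (measured - actual) / actual`; per-class
and total aggregates compare summed measured lengths against summed actual
lengths, and length-weighted mean widths, the convention that matches manual
multi-part measurements.

### Accuracy envelope

On synthetic panels (see the test suite and `scripts/acceptance.R`) the
aggregate signed error over 20 fragments is within about ±4 % for length and
±7 % for width under shadowed-scene conditions; individual thin, low-contrast
fragments adjoining shadow boundaries can err by several tens of percent in
width (and occasionally length), because an inner shadow band is optically
indistinguishable from the lighter fragment classes. The same qualitative
pattern — accurate totals, occasional large per-sample width errors on pale
fragments — is what manual-versus-automatic comparisons of this kind of
system report.

## Background-shadow elimination

Scenes show dark fragments on a light ground with two nuisance fields: a
smooth illumination gradient and a soft penumbra cast beside each fragment.
The pipeline is:

1. grayscale + square dilation (running max; kernel 41 px by default) — the
   kernel must *exceed the widest fragment* so the dilation swallows
   fragments and yields a background estimate that keeps the smooth shading;
   a small kernel (e.g. 3 px) merely erodes fragment edges and leaves no
   background to difference against, so the composed pipeline deviates
   deliberately from the smallest-element choice that is natural for the
   step in isolation;
2. 3 x 3 median filter (replicate edges) to clean the estimate;
3. absolute difference original-vs-estimate — shading present in both
   cancels, fragments stand out;
4. min–max normalisation to 0–255 (a constant difference maps to all-zero);
5. adaptive local-mean threshold: foreground where the difference exceeds
   its local box mean by `offset`. The window (default 33 px) is sized to
   the *content* — about one fragment width at the 10 px/mm working scale —
   not to the frame: a much larger window lets a dark fragment's local mean
   suppress a faint neighbour. The offset (default 12) sits about three
   standard deviations above the normalised background noise; the offset 5
   one might pick on raw gray levels is below that floor after
   normalisation.

Two mask refinements follow. Interior holes are filled and components under
25 px discarded. Then a hysteresis step grows each confident component into
connected pixels above 0.75 x its own median difference: a tightly coiled
fragment whose limbs sit closer together than the window spacing otherwise
pulls its own local mean up and loses its interior. Growth is capped at 4x
the component size so a component cannot bleed across the scene.

The output image keeps original pixels under the mask and homogenises the
rest to the median background colour. Known limitation: the inner part of a
penumbra band is genuinely darker than the palest fragment class, so a few
pixels of shadow adjacent to a fragment can survive in the mask; this is the
dominant source of the residual positive width bias.

## Detection-network components

The components mirror a compact single-stage detector and are implemented as
plain-R tensors (`[C, H, W]` arrays, im2col convolutions), which is entirely
adequate for construction checks, forward passes and desk-scale training
exercises:

- **Re-I block**: 1 x 1 reduction to half the output channels, two stacked
  3 x 3 convolutions tapped individually, a 1 x 1 input projection, ELAN-style
  concatenation of the four, 1 x 1 fusion, plus a residual skip (identity, or
  1 x 1-projected when channel counts differ). This is the minimal structure
  that combines multi-branch widening with residual feature reuse; the
  channel arithmetic inside such blocks is not standardised, so the halving
  convention was chosen and documented rather than inferred.
- **Backbone**: four stages with stride-2 entries, default block counts
  1:2:2:1 (the compressed variant of the classic 3:4:6:3 residual layout —
  at equal channels the compression cuts parameters by about half) and
  channels 64/128/256/512. Pyramid taps: stage 1 reaches P3 (stride 8)
  through a 1 x 1 CBS and a downsampling max-pool, stage 2 through a CBS;
  stage 3 supplies P4 (stride 16); stage 4 feeds the SPPFCSPC block, whose
  output is P5 (stride 32).
- **SPPFCSPC**: cross-stage-partial pooling block in which three chained
  5 x 5 same-size max-pools replace parallel 5/9/13 pools. Two serial 5s
  equal one 9 and three equal one 13 exactly (max-filter algebra), so the
  receptive field is unchanged while each pool stays small.
- **Decoupled head**: shared 1 x 1 reduction, then disjoint classification
  and localisation branches, the latter emitting 4 box coordinates plus an
  objectness output; `n_anchors * (4 + 1 + n_classes)` raw channels per
  location. The "dense" localisation branch is realised as 1 x 1
  convolution — the per-location equivalent of a fully connected layer that
  also works at any spatial size.
- **CIoU loss**: `1 - IoU + rho^2/c^2 + a v` with the aspect-ratio term
  `v = (4/pi^2)(atan(wg/hg) - atan(w/h))^2` and weight `a = v/((1-IoU)+v)`.

Convolutions carry bias and SiLU activation; batch normalisation is omitted
(at desk scale it adds parameters and statefulness without changing what the
checks exercise), so printed parameter counts are indicative, not
reproductions of any particular implementation's totals.

`smoke_train()` freezes the randomly initialised backbone and branch
features and optimises the head's final 1 x 1 convolutions by SGD on the full
objective (mean CIoU over assigned anchors + BCE objectness everywhere + BCE
classification at positives). Box-coordinate gradients come from central
finite differences on the four raw outputs of each positive — cheap, exact
to O(eps^2), and independent of the loss's algebraic form; objectness and
classification gradients are analytic. Twenty epochs over 8 tiny (64 x 64)
scenes reduce the total loss to roughly a quarter of its initial value in a
couple of seconds, deterministically for a fixed seed. This exercises the
objective end to end; it is not, and does not claim to be, model training.

## Detection metrics

Matching is greedy in descending confidence (ties broken by input order,
documented for reproducibility): a prediction is a true positive when its
best-IoU unmatched same-class truth reaches the threshold; each truth
absorbs at most one prediction. AP uses all-point interpolation — the exact
discrete analogue of the area under the continuous precision–recall curve —
rather than 11-point sampling. mAP averages per-class APs over the four
classes (classes without ground truth are excluded as undefined);
mAP@.5:.95 averages over thresholds 0.50–0.95 in steps of 0.05, exactly ten.

## The synthetic scene generator

What it emulates: four colour/texture-separable fragment classes (pale woody
stem G and light expanded silk P are deliberately low-contrast against the
ground, as the real materials are); curved ribbon geometry with exact
centerline length and constant width; optional pairwise overlap with
per-object (multi-label) boxes; a calibration block; a smooth illumination
gradient and per-fragment cast penumbrae. Study-condition defaults: lengths
uniform on 8–25 mm, widths 1–2.8 mm (capped at a third of the length),
curvature ±0.06 mm⁻¹ with total turning capped at ~150°, 10 px/mm, canvas
1280 x 1280 px, shadow strength 0.6 — values representative of published
per-sample shred measurements and inspection-line imagery.

Geometry: the tube is swept along a piecewise-circular-arc centerline
(midpoint-rule integration at 0.25 px steps) and rendered by stamping
perpendicular cross-sections at sub-pixel spacing. Ends are flat (butt)
rather than rounded: with butt ends the tip-to-tip extent equals the stated
length exactly and the recorded ground truth is unambiguous, at the price of
a slightly less organic silhouette. Rasterisation widens every boundary by
about half a pixel per side; that inherent +1 px on width and length is the
floor below which no pixel-level measurement can go.

What it does not emulate: photorealistic texture, specularity, moisture
variation, true occlusion appearance (an overlapped fragment is simply
painted over), camera optics and sensor noise. Passing tests on these scenes
therefore validates the geometry and the algorithmic contracts, not
photographic robustness.

Manifests: records split per label at a train:test ratio (default 7:3) with
the test count floored and the remainder to train, so divisible compositions
split exactly (4 x 1000 gives 2800/1200; 4 x 1700 gives 4760/2040); the
shuffle is deterministic in the seed. One published composition
(`shred_image_composition()`: 4 x 1000 pure + 6 x 200 pairwise + 100
four-way = 5300) is bundled as the reference acquisition design; the
companion text also quotes a 6800-sample figure for the blended set, which
matches the 4 x 1700 split totals — the generator takes counts as inputs and
takes no position on which figure describes acquisition versus augmentation.

## Numerical choices and degenerate inputs

- All randomness flows through one seed per entry point; the caller's RNG
  state is restored afterwards.
- `normalize_0_255` maps a constant image to all-zero (declared convention).
- Empty crops, degenerate (single-pixel) masks, fewer than 2 non-empty
  strips, sub-2 px strips, non-positive calibration inputs, out-of-frame
  ribbons and over-full canvases raise explicit errors;
  `measure_scene()` records per-object failures and continues.
- Two contours at exactly equal centroid distance: the larger area wins
  (declared tie-break).
- A square minimum-area rectangle accepts either orientation.
- Smoke training validates input count (>= 4 scenes) and aborts on
  non-finite loss.

## Known limitations

- Width (and occasionally length) of pale fragments adjacent to shadow
  boundaries can be overestimated by tens of percent per object; aggregates
  remain within the bands above.
- Overlapped fragments are measured on their visible mask; no attempt is
  made to infer the occluded part.
- The quality index sometimes derived from these sizes (the fraction of
  unbroken shreds) is not computed: no standard formula exists for it, and
  publishing a measurement is more useful than inventing a threshold.
- Problem sizes in the tests and the acceptance script (640–1280 px scenes,
  20-ribbon panels, 8-scene smoke training) are the package's validation
  scale, chosen so the whole suite runs in about a minute on one CPU.
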