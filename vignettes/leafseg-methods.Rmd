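---
title: "leafseg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{leafseg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`leafseg` is a self-contained R implementation of leaf *instance*
segmentation for top-down rosette imagery: every pixel of a plant image is
assigned either to the background or to one specific leaf. The package
covers the full experimental loop — evaluation metrics, data formats and
converters, a synthetic scene generator, an augmentation stack, three
single-stage segmentation networks trained by a pure-R reverse-mode
autodiff engine, and a command-line interface. This vignette records the
modelling choices and their rationale.

## The evaluation metrics

Instance label maps are integer matrices: `0` is background, positive ids
are leaves (ids need not be contiguous). Five measures are computed per
image and averaged without weighting:

* **Dice** of two binary masks, `2|A∩B| / (|A|+|B|)`. Two empty masks
  score 1 (they agree that nothing is there); one empty and one non-empty
  mask score 0.
* **Best Dice** `BD(a, b)`: for each instance of `a`, the best Dice
  against any instance of `b`, averaged over the instances of `a`. It is
  directional; a map with no instances scores 0 so that batch evaluation
  never aborts on an empty prediction.
* **Symmetric Best Dice** `SBD = min(BD(ar, gt), BD(gt, ar))` — the
  primary segmentation score. Taking the minimum punishes whichever of
  over- and under-segmentation is worse; the canonical example (one blob
  covering two equal leaves) scores exactly 2/3.
* **FGBGDice**: Dice of the binarized foregrounds, ignoring the instance
  partition.
* **DiffFG / AbsDiffFG**: signed and absolute difference in leaf counts
  (`#predicted − #truth`).

`evaluate_dataset()` reports per-image rows plus an `ALL` row of
unweighted arithmetic means, on a percent scale with two printed decimals
(the convention of published result tables); `scale = "fraction"` gives
raw values. The implementation computes all pairwise instance
intersections with one `tabulate()` pass rather than a double loop, and
the test suite checks it against a brute-force oracle on hundreds of
random maps.

## Data formats

Three interchangeable ground-truth representations are supported:

* **Indexed PNG** label maps (`write_label_png()` encodes the id in the
  RGB channels losslessly, or as a hue wheel for visualization).
* **HDF5** datasets of 2-D integer labels. No R HDF5 package is assumed;
  `read_label_h5()` shells out to the system `python3`/`h5py` to dump the
  file. The bridge validates dataset shape/type and reports missing keys.
* **Polygon text files**: one instance per line, `class_id` followed by
  alternating normalized `x y` vertex coordinates at six decimals. Reader
  and writer invert each other to 1e-6.

`mask_to_polygons()` converts a label map to polygons by Moore-neighbour
boundary tracing (with Jacob's stopping criterion and a visited-state
guard for degenerate thin shapes), followed by Ramer–Douglas–Peucker
simplification at 1 px and exact-collinear pruning. The collinear
tolerance is deliberately strict (1e-6): a looser tolerance shrinks disks
toward inscribed polygons and erodes the round-trip quality. Rasterization
(`polygons_to_mask()`) uses even-odd pixel-center tests plus boundary
samples, with later records overwriting earlier ones (painter's rule) and
a minimum instance area of 3 px. Mask → polygons → mask round trips keep
per-instance Dice above 0.95 for convex instances of radius ≥ 10 px; the
fidelity is resolution-bound — structures only 2–3 px wide lose a large
fraction of their area to the pixel-center representation, whatever the
tracing parameters.

`split_file_list()` implements the deterministic 3:1 split: filenames are
sorted (radix order) and every fourth one goes to validation.

## The networks

All three variants share a C2f backbone (stem stride-2 conv, alternating
downsampling convs and C2f blocks, SPPF on the last stage), taps at
strides 8/16/32 (P3–P5), a decoupled anchor-free head per level (box
distribution with 16 bins per side, class logits, mask coefficients) and a
prototype-mask branch at stride 4. Compound scaling follows the usual
depth/width multipliers (`n` = 1/3, 0.25 … `x` = 1, 1.25).

* **standard**: a path-aggregation neck — top-down upsample/concat/C2f,
  then bottom-up downsample/concat/C2f.
* **bifpn**: the neck's merge points become *weighted fusion nodes*:
  inputs are harmonized to a common width with 1×1 convs and combined as
  `Σ max(wᵢ,0)·xᵢ / (Σ max(wᵢ,0) + ε)` with learnable per-input weights
  (ε = 1e-4), followed by a 3×3 conv. The middle output node fuses three
  operands, adding the same-level skip connection. Closed forms (equal
  weights → arithmetic mean; a zero weight removes its input) are verified
  to machine precision in the tests.
* **ghost**: the P4 downsampling convolution of the backbone is replaced
  by a Ghost block: `ceil(cout/s)` intrinsic maps from a dense 3×3
  primary convolution, the remaining maps from a cheap depthwise 5×5 on
  the intrinsic maps, concatenated. Trainable convolution weights follow
  the closed form `k²·cin·cout/s + (s−1)·(cout/s)·k_cheap²`, strictly
  below the dense count whenever `k_cheap² < k²·cin`; at nano scale the
  full ghost model is smaller than the standard one.

### Training

The loss couples task-aligned assignment (metric `score^0.5 · IoU^6` over
anchors inside each ground-truth box, top-10 candidates, conflicts to the
higher metric) with four terms: complete-IoU box loss, distribution-focal
loss (two-bin cross-entropy on the fractional target distance), BCE class
loss against the soft aligned scores, and a prototype-mask BCE cropped to
the box and normalized by its area. Gains are 7.5/1.5/0.5/1.0
(box/dfl/cls/mask), normalized by the summed target scores.

Optimization is SGD with momentum 0.937, weight decay 5e-4 on convolution
weights, linear warmup then linear decay. Everything — convolutions via
im2col + BLAS, batch normalization with running statistics, SiLU, pooling,
softmax — runs on a small reverse-mode tape written in base R; every
operator's gradient is checked against central differences in the test
suite.

`leafseg_train()` returns a classed `leafseg_model` with `print`,
`summary`, `predict` and `plot` methods. `coef()`/`residuals()` are not
provided: a network with millions of weights has no coefficient summary or
residual structure in the classical modelling sense.

### Inference

`predict_instances()` decodes the box distributions (softmax expectation ×
stride around anchor centers), filters at confidence 0.25, applies greedy
class-agnostic NMS at IoU 0.7, assembles each detection's mask from the
prototypes, crops it to the box, binarizes at 0.5 and paints instances in
ascending score order so the most confident detection owns contested
pixels. Prediction is deterministic.

## Synthetic rosettes

`generate_rosette()` builds labelled scenes without any external data:
`k ~ U[5, 30]` teardrop leaves (sine-tapered ellipses) placed at
golden-angle increments (137.5°, the rosette phyllotaxis) with angular
jitter, drawn over a textured soil background in a green HSV band, with
optional Gaussian defocus. Painter's order is randomized so occlusion is
independent of placement order; fully occluded leaves are removed and ids
compacted. The default leaf width range (`0.035–0.09` of the image side)
was chosen so that complete occlusion is rare and the mean instance count
stays within 10% of the `k`-range midpoint — wider leaves silently delete
ground truth. Limits worth knowing: leaves are convex-ish single
components without serration, petioles or specular highlights, and the
soil texture is low-frequency noise; the generator is meant for
end-to-end pipeline validation at desk scale, not for transfer to real
imagery.

## Augmentation

`augment_sample()` applies, in order: optional 4-image mosaic (double
canvas, random center, then resized back), random affine (rotation up to
±180°, translation ±10%, scale ±50% by default) applied inversely to the
image and forward to the polygons with Sutherland–Hodgman clipping and a
3 px minimum area, HSV jitter (h ±0.015, gain ±0.7/±0.4), and horizontal/
vertical flips at p = 0.5. Random erasing is implemented but off by
default: it paints over pixels without editing the polygon labels, which
at desk scale makes image/label pairs inconsistent for mask training.
Every output satisfies the annotation invariants (≥3 vertices, normalized
coordinates, no new instances), and a fixed seed replays bit-identically.

## Desk-scale problem sizes

The package's own reference experiment — used by the test suite and
`scripts/acceptance.R` — is deliberately small so it runs in minutes on
one CPU: nano-scale networks at 64 px input (84 anchors), 8 prototypes,
64 training and 16 validation scenes, batch 8, 40 epochs.

Problem sizing matters more than schedule length at this scale. Shrinking
the full-scale generator defaults to 64 px produces leaves 2–6 px wide —
narrower than one stride-8 anchor cell and about one pixel of the
stride-4 prototype grid — and no schedule segments objects that sit below
the model's sensor resolution (a 48-epoch rehearsal plateaued at
FGBGDice ≈ 20%). The desk-scale scenes therefore use fewer, larger
leaves (2–5 per plant, lengths 0.25–0.45 and widths 0.08–0.16 of the
side), so each instance spans several anchors; the same rehearsal shape
then reaches SBD ≈ 55% and FGBGDice ≈ 74% on held-out scenes. The
reference run trains without augmentation (it slows bootstrapping on
short schedules; the augmentation stack has its own invariant tests).
Full-scale work would use 512 px inputs and the defaults of
`train_config()` and `rosette_config()`.

```{r}
library(leafseg)
gen <- rosette_config(size = 64, k_range = c(2, 5),
                      leaf_len = c(0.25, 0.45) * 64,
                      leaf_width = c(0.08, 0.16) * 64,
                      blur_sigma = c(0, 0.4), seed = 100)
generate_dataset(gen, 64, "train")
fit <- leafseg_train("train",
  model = model_config(scale = "n", img_size = 64, n_protos = 8),
  config = train_config(epochs = 40, batch_size = 8, lr0 = 0.01, lrf = 0.1,
                        warmup_epochs = 1, augment = NULL, seed = 7))
summary(fit)
pred <- predict(fit, "train/plant_0001_rgb.png")
```
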