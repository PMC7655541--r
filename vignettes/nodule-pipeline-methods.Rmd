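---
title: "Methods: nodule segmentation, measurement and blocked-design inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nodule segmentation, measurement and blocked-design inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Legume root nodules — the small spherical organs housing nitrogen-fixing
rhizobia — are numerous, small, bright against washed roots, and frequently
overlap, which makes manual counting and sizing from field photographs slow
and unreliable. `noduleseg` implements a complete measurement pipeline for
RGB photographs of excavated root systems:

1. **offline**: annotate a modest set of images as binary masks
   (nodule = foreground, everything else including roots = background) and
   train a pixel-wise segmentation network;
2. **online**: scale-and-pad new photographs to the network input size,
   predict per-pixel nodule probabilities, refine them with a dense
   conditional random field (CRF), clean the binary mask morphologically,
   optionally apply polygon corrections from a human (or scripted) editor,
   and count/size the surviving connected components in physical units;
3. **downstream**: analyse the per-plant phenotypes with the randomized-
   complete-block-with-subsampling ANOVA, Tukey mean comparisons and
   per-treatment trait correlations.

Because the field images behind the original study are not publicly
deposited, the package ships a synthetic scene generator with exact
per-instance ground truth; every stage is validated against it.

## Segmentation network

The network is a conventional U-Net-style encoder–decoder: `depth` levels
of two 3×3 convolution + ReLU blocks with 2×2 max-pooling, a bottleneck,
a mirrored decoder using nearest-neighbour upsampling with skip
concatenation, and a 1×1 convolution with a sigmoid producing one
foreground probability per pixel. Input sides must be divisible by
`2^depth`; the scale-and-pad stage additionally keeps them multiples
of 32, the usual U-Net convention.

Choices the original description leaves open, and what this package does:

* **Loss** — soft-Dice plus binary cross-entropy (`loss = "dice_bce"`).
  Nodules cover a small fraction of the frame; plain BCE lets a network
  collapse to "all background", while the Dice term directly rewards
  overlap of the small foreground. This combination is the standard remedy
  for heavy class imbalance in biomedical segmentation.
* **Optimizer** — Adam, learning rate `1e-3`, batch size 1, weights
  He-initialized from the configuration seed. Training is deterministic
  for a fixed seed on a single thread.
* **Desk configuration** — `input_size = 128`, `depth = 3`,
  `base_channels = 16`, 30 epochs (one epoch = one pass over the training
  pairs). This trains in minutes on one CPU; the full-scale 1024-pixel
  network of a GPU workflow is the same code with a different
  configuration, not a separate code path.
* **Transfer learning** — `seg_update()` continues Adam from the current
  parameters on the union of the retained original pairs and the new
  (corrected) pairs. Replaying the old pairs guards against catastrophic
  forgetting; the correction-loop harness defaults to 10 update epochs,
  fewer than from-scratch training, since it resumes from converged
  weights. Arithmetic is single precision, the usual choice for CNN
  training.

## Dense-CRF refinement

The refinement stage couples every pixel's label to similar-looking and
nearby pixels: unary potentials are `-log p` from the network, and two
Gaussian pairwise kernels act on (colour, position) — the appearance
kernel — and on position alone — the smoothness kernel — under a Potts
penalty, solved by mean-field iteration (default 5 iterations). In the
limit of vanishing pairwise weights the output equals the input
probabilities; this is tested.

The reference mean-field method is formulated as *fully connected* and made
tractable by high-dimensional filtering. This package instead truncates
each Gaussian at 2.5 standard deviations, which retains >98% of the kernel
mass and keeps inference `O(N · R²)` with plain loops. Consequently the
published appearance position scale (~80 px, tuned for megapixel
photographs) would be both intractable and out of proportion at the
128-pixel desk scale; the defaults here are `appearance_position_sd = 5`,
`appearance_color_sd = 0.05` (the reference's 13/255 rescaled to the
`[0, 1]` intensity range), `smoothness_position_sd = 3`, with the
reference's kernel weights 10 and 3. For full-resolution photographs the
scales should be enlarged in proportion to nodule size in pixels.

Binarization applies a 0.5 threshold after refinement (the description
does not state its binarization point; 0.5 is the natural choice for a
calibrated sigmoid output).

## Mask cleanup, counting and sizing

The online order is fixed: CRF → threshold → morphological closing (disk,
default radius 1) → interior hole filling → error-correction hook →
connected components → size filter. Closing-then-fill is extensive: input
foreground is never removed. Components use 8-connectivity by default
(nodules are blobs; diagonal contact should merge) with 4-connectivity
available. The minimum component size is expressed in mm² (default
0.2 mm²) and converted through the mm-per-pixel calibration so the noise
rule does not depend on image resolution; the bound is inclusive.

A merged blob of overlapping nodules counts as **one** nodule: the
connected component is the counting unit. This is a deliberate, inherited
limitation — the synthetic generator records the true instance count even
when masks merge, so the failure mode is measurable rather than hidden.
No watershed or other instance splitting is attempted.

Areas are `pixel_count × mm_per_pixel²` measured on the reconstructed
full-size mask, not the network grid, and reported in mm² and cm²
(`cm² = mm²/100`). The mm-per-pixel scale comes from a physical reference
object: `calibrate_scale(reference_pixel_length, reference_mm_length)`.

## Geometry: scale-and-pad and its inverse

`preprocess()` applies one isotropic scale factor
`target_size / max(h, w)` (floor rounding on the shorter side) and centres
the content with constant padding — the mean image intensity for RGB
(neutral for the convolution statistics), background for masks. The
`transform_record` makes the mapping exactly invertible at the bookkeeping
level: original dimensions, scale, content placement.

Resampling kernels: bilinear for RGB and probability maps; for binary
masks, area averaging when shrinking and bilinear when enlarging, each
re-thresholded at 0.5 so the result stays binary. Area averaging is the
correct anti-aliasing filter for a downscaled indicator image and
measurably beats nearest-neighbour on round-trip IoU. Information loss is
still unavoidable: at the 6000→1024 reduction (scale factor ≈ 5.9) a
nodule must be roughly ≥ 10 px radius *on the network grid* (≈ 59 px in
the original frame) to round-trip at IoU ≥ 0.95; smaller objects simply
are not resolvable at the coarse grid, whatever the kernel. The tests
state their round-trip guarantees in network-grid units for this reason.

## Annotation data layer

The semi-automatic workflow needs masks to travel to a polygon editor and
back. `mask_to_contours()` traces one outer contour per connected
component along the pixel cracks (vertices on the half-integer corner
grid), so rasterizing the polygon recovers the component up to boundary
pixels; at saddle corners the tracer prefers the right turn, which keeps
diagonally-touching pixels in a single loop. `contours_to_mask()` uses
even-odd scanline filling over pixel centres; overlapping polygons union.
`apply_corrections()` is
`(predicted ∪ add) \ remove`, removal winning on conflict, and is
idempotent. Files use a LabelMe-compatible JSON dialect (`imagePath`,
`shapes[{label, points, shape_type: "polygon"}]`, x/y = 0-based col/row)
with a single class label `"nodule"`; polygon provenance (manual /
predicted / corrected) rides in each shape's `flags`.

The GUI itself is out of scope. The correction loop is exercised by a
scripted *oracle corrector* that replaces the predicted polygons of the k
worst-F1 images with ground-truth polygons — the desk-scale analogue of a
human fixing the worst predictions before retraining.

## Evaluation

Pixel metrics follow the usual definitions: `P = TP/(TP+FP)`,
`R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`, with TP counted on true-foreground
pixels predicted foreground. Zero-denominator conventions, documented and
tested: no predicted foreground → precision 1; no true foreground →
recall 1; `P + R = 0` → F1 0; prediction and truth both empty → all three
metrics 1. Across images the reported default is the **macro** average
(per-image F1 averaged, matching per-network evaluation of image sets);
a micro (pooled-counts) variant is provided.

`learning_curve()` trains fresh networks at increasing training-set sizes
and evaluates a fixed held-out set over several seeds;
`correction_loop()` alternates predict → oracle-correct → update and
records held-out F1 per round. Monotonicity of the learning curve is
asserted in expectation over seeds, with a tolerance, never strictly per
seed.

## Synthetic scenes: what they emulate, and what a green test means

The generator renders: a dark brown background with low-frequency
blotches and additive Gaussian noise (default sd 0.04); thin branching
root strands (width 2–7 px) as random downward walks — part of the
*background* in the mask; and bright, slightly shaded elliptical nodules
(rotated, axis ratio 0.65–1) attached to root strands, with a configurable
fraction placed overlapping an existing nodule (default 0.3, reflecting
how frequently real nodules touch; the counting-recovery harness sets it
to 0 because merged components are a known failure mode, not a bug).
Default canvas 512×512 at 0.1 mm/px, with a 128×128 desk preset used by
all harnesses. All geometry is parameterized; nodule size and density
defaults were chosen once for testability — the source study does not
report its images' size or density distributions.

What the generator does **not** emulate: soil texture and debris,
specular highlights, uneven illumination, motion blur, nodules occluded
behind roots, or colour variation between cultivars. A green test
therefore establishes that the pipeline's machinery is correct and that
the network can learn this family of scenes; it does not certify field
accuracy on real photographs.

The phenotype generator draws from the blocked-design model
`y_ijk = μ + β_j + α_i + δ_ij + ε_ijk` on the log scale and exponentiates,
emulating traits analysed after log transformation. Defaults (3 blocks ×
3 treatments × 30 subsamples = 270 rows; block sd 0.42, treatment effects
−0.25/0/+0.25, plot sd 0.115, subsample sd 0.46) were derived once from
the published ANOVA mean squares for nodule size via the expected-mean-
square identities, so the simulated world reproduces the reported
block-variance-dominant structure (blocks ≫ treatments ≫ experimental
error > sampling error).

## Blocked-design inference

`fit_rcbd_subsampling()` implements the balanced classical ANOVA from
explicit sums of squares rather than delegating to a model-fitting
routine, because the error-stratum logic is the scientifically load-
bearing choice: with subsampling, the treatment F statistic must use the
plot-level (experimental) mean square as its denominator — testing against
the subsample-level sampling error would treat the 30 plants per plot as
independent replicates and wildly overstate significance. Blocks are
tested against the same stratum. `aov()` with an `Error(plot)` term
serves as an independent oracle in the tests, never as the
implementation.

Tukey comparisons use the studentized range on treatment means with the
experimental-error mean square and degrees of freedom (equivalent to
`TukeyHSD` on the plot means, which the tests verify). Correlations are
per-treatment Pearson coefficients over subsample-level observations with
`*`/`**`/`***` stars at 0.05/0.01/0.001; a constant trait within a group
reports a missing coefficient. Diagnostics return normal Q–Q data and
fitted-versus-residual pairs at both the plot and subsample level, plus a
Shapiro–Wilk p-value on the plot-level residuals; with few plots (e.g.
3×3 = 9, 4 error df) those residuals are noticeably correlated and the
p-value is approximate — the uniformity property is tested on a larger
(6×6) design where the approximation is good.

Non-positive standard deviations are rejected by the simulator (zero is
allowed: the degenerate strata collapse exactly as expected); the log
transform refuses non-positive trait values, naming the offending rows;
unbalanced tables are rejected rather than silently reweighted. An
optional heteroscedastic variance-weighting mode (variance proportional
to a power of the fitted values) is deliberately not implemented beyond
the balanced classical case — the balanced analysis is the package's
scope, and REML mixed-model machinery is available elsewhere.

## Numerical and interface choices

* Configuration and the run manifest use JSON (no YAML parser is
  available in the target R environment); scene sidecars and annotations
  are JSON; tables are CSV; images and masks are 8-bit PNG (a minimal
  codec is built in, as no R imaging package is assumed).
* Probability clamping at `1e-6` before logs (CRF unaries, BCE).
* The Dice smoothing constant is 1 (a full-image term; stabilizes empty
  masks).
* Component labels are stable under size filtering (survivors keep their
  labels; they are not renumbered).
* All randomness flows from explicit integer seeds: scene seeds derive
  from a master seed as `(seed · 10007 + i) mod (2³¹ − 1)`; training
  shuffles derive from the model seed and epoch.

## Known limitations

* Merged nodules count as one component (inherited, by design).
* The CRF is a truncated-window approximation of the fully connected
  model; very long-range colour coupling is absent.
* Desk-scale training (128 px, minutes on CPU) demonstrates the learning
  behaviour; it does not reproduce GPU-scale absolute accuracy on
  6000×4000 field photographs, and the study's own F1 figures cannot be
  reproduced without its images.
* Sub-network-grid objects cannot survive the scale-and-pad round trip;
  at high reductions the minimum measurable nodule size is set by the
  network grid, not the camera.
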