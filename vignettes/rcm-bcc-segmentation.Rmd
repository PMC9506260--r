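---
title: "Patch-classifier heatmaps for BCC segmentation in reflectance confocal microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-classifier heatmaps for BCC segmentation in reflectance confocal microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcmseg)
```

## The problem and the modelling approach

In vivo reflectance confocal microscopy (RCM) produces horizontal grayscale
optical sections of skin at cellular resolution. Basal cell carcinoma (BCC)
presents in these sections as compact bright tumor islands — elevated local
reflectance, often demarcated from the surrounding stroma by a dark fissure.
The clinical question this package addresses is region-level: *which pixels
of a slice belong to a BCC lesion*, so that wound margins can be assessed
intraoperatively.

The pipeline follows a classic patch-to-dense design:

1. **Patch classification.** Slices are tiled into 256×256 patches. A patch
   is labelled *malignant* when strictly more than 50% of its area is
   annotated as cancer, else *healthy*. A small depthwise-separable
   convolutional network (a MobileNet-style backbone with total stride 32,
   global average pooling, and a 2-way softmax head) is trained on these
   patches with Adam under two-class cross-entropy, with rotation (±30°),
   zoom (80–120%) and horizontal-flip augmentation applied on the fly to
   training patches only — labels are never altered.
2. **Dense expansion.** The trained classifier is *convolutionalized*: the
   global average pool becomes a shape-preserving average pooling over the
   final feature grid (kernel 7 by default, stride 1, "same" padding), and
   the fully connected head becomes a 1×1 convolution with two filters
   whose weights are exactly the transplanted head weights. Applied to a
   whole mirror-padded slice (1000×1000 → 1024×1024, 12 px of symmetric
   reflection per side), the network emits a 32×32×2 probability grid that
   is upsampled ×32 into a per-pixel heatmap.
3. **Postprocessing.** Gaussian smoothing of the probability channels,
   thresholding at 0.5 (a probability of exactly 0.5 maps to foreground),
   then erosion and dilation with a 3×3 square element — an opening that
   removes isolated pixels while restoring the extent of surviving regions.
4. **Evaluation.** Pixel-level confusion counts pooled over a grouped
   k-fold cross-validation give sensitivity TP/(TP+FN) and specificity
   TN/(TN+FP). On top of the pixel metrics sit two detection criteria: a
   *stack* (one scan site's ordered slices) counts as detected when at
   least 40% of the lesion pixels are recovered in at least three of its
   slices, and a *case* (patient) when at least one of its stacks is
   detected.

Because no clinical RCM scans are distributed with this package, a
synthetic generator stands in for the imaging step and defines the study
conditions for every test and experiment here.

## The synthetic RCM generator

`generate_slice()` renders, onto a smoothly varying stromal base intensity,
one to three elliptical bright tumor islands, each ringed by a dark
fissure, and then multiplies the whole field by Gamma-distributed speckle
with mean 1 — the standard multiplicative noise model for coherent imaging.
Output is 8-bit grayscale after clipping. The ground-truth mask covers the
island *interiors only*: the fissure is background, mirroring annotation
practice that outlines compact tumor-cell clusters rather than surrounding
stroma. An optional annotation layer assigns each island one of the five
confocal BCC criteria codes, but every downstream stage consumes the
binary mask — the classification problem is binary BCC versus non-BCC
area.

Defaults were chosen once to mirror the study conditions the pipeline is
meant for: 1000×1000 slices; 1–3 islands with full axes 300–500 px, which
puts the per-slice lesion fraction near the ~28% of evaluated pixels that
the pooled clinical confusion matrix implies; island contrast 0.8 (islands
are 1.8× brighter than local stroma before speckle); a 12 px fissure at
0.35× stroma; speckle shape 4 (relative SD 0.5); and a dataset layout of
14 cases × 2–3 stacks × 10 slices, the scale of the clinical corpus. Every
slice's random stream derives from the master seed and the slice identity,
so datasets are pure functions of their parameters and any slice is
regenerable in isolation.

What the generator deliberately does **not** emulate: confocal optics
(point-spread function, depth sectioning), cellular texture inside the
islands (nuclear polarization, peripheral palisades are annotation
criteria, not rendered structures), imaging artifacts, or inter-patient
variability beyond seed-driven geometry. Passing tests on this material
therefore demonstrates that the *pipeline machinery* — labelling,
training, expansion, postprocessing, pooling — recovers planted signal
under realistic noise; it does not certify clinical accuracy on real RCM
data, and the published clinical operating point (sensitivity 0.46,
specificity 0.85) is not a reproduction target at desk scale.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `patch_size` | 256 | px | the classifier's training unit |
| `malignant_fraction_threshold` | 0.5 (strict) | fraction | a patch is malignant only when *more than* half its area is |
| `stride` (tiling) | 106 | px | lays an 8×8 grid on a 1000×1000 slice, ≈64 patches/slice — consistent with ≈24.4k patches from 385 slices |
| `learning_rate`, `epochs` | 1e-5, 20 | — | the full-scale training recipe |
| `avgpool_kernel` | 7 | cells | the published expansion uses a 7×7 pool; 8 reproduces the patch classifier's 8×8 global pool exactly |
| `mirror_pad_total` | 24 | px | 1000+24 = 1024 = 32×32: the padded side must be divisible by the backbone stride |
| `gaussian_sigma` | 2.0 | px | smooths ×32 upsampling block artifacts without erasing lesion-scale structure |
| `threshold` | 0.5 | probability | ties map to foreground ("less than 0.5 to 0 and the rest to 1") |
| structuring element | 3×3 box, 1+1 iterations | — | the minimal opening that removes isolated pixels |
| `k` (folds) | 14 | — | grouped by case: leave-one-case-out at the clinical scale |

## Design choices made where the design was open

**Backbone.** `mobilenet_spec(0.5)` reproduces the MobileNet-v1 block
layout (stride-2 stem + 13 separable blocks, strides 1,2,1,2,1,2,1×5,2,1)
at width multiplier 0.5, where the final stage has 512 channels — matching
the 32×32×512 feature volume the expansion starts from. Batch
normalisation is omitted (plain bias + ReLU with He initialisation): the
published description pins only the depthwise-separable architecture and
the 512-channel/stride-32 facts, and BN's train/eval-mode state buys
nothing at the widths used here. The classifier head is zero-initialised
so an untrained model predicts exactly (0.5, 0.5) regardless of backbone
scale.

**Exactness of the dense expansion.** Convolutionalizing a classifier is
*exactly* equivalent to sliding-window evaluation only when no
convolution's receptive field crosses a window boundary. With overlapping
"same"-padded 3×3 kernels, a patch evaluated in isolation zero-pads its
borders while the dense pass sees true image context, so boundary features
— and, after pooling, the output probabilities — differ by more than
rounding. The backbone therefore supports per-stage kernel sizes: with
`kernel = "aligned"` every stage uses kernel = stride, receptive fields
tile the input, and the dense grid equals the sliding-window prediction to
machine precision at every interior cell (the package's central
correctness test, run with pool kernel 8). The default remains the 3×3
MobileNet layout; the aligned variant is the verification regime and the
desk-scale workhorse.

**Pooling kernel 7 vs 8.** The published expansion pools 7×7; the patch
classifier's global pool is 8×8, and only kernel 8 makes the dense
predictor agree with it exactly. Both are supported; the default follows
the published 7, the equivalence test uses 8. Average pooling excludes
padded cells from its denominator ("same"-style), so edge cells average
over their valid neighbourhood only.

**Padding split.** The 24 padded pixels are split 12 per side (the split
is not pinned by the description; 12+1000+12 = 1024 and 1024/32 = 32
matches the stated 32×32 grid). Reflection is *symmetric* — the edge pixel
participates, so with 12 px of padding, padded row *i* equals original row
13−*i* — stated explicitly so tests can be bit-exact. Heatmaps, masks and
metrics live on the padded 1024-canvas by default, with truth masks padded
by the same mirror geometry; cropping back to 1000×1000 is a flag.

**Upsampling.** Bilinear by default (matching the smooth published
heatmaps), nearest-neighbour available for exactness tests. Both operators
have rows summing to 1, so per-pixel probability conservation survives
upsampling.

**Specificity formula.** The published formula block prints
TP/(TP+FP) for specificity, which contradicts both its own prose
("proportion of healthy pixels … correctly predicted") and the published
confusion matrix, whose 0.85 equals TN/(TN+FP). The standard TN/(TN+FP) is
implemented; it reproduces the published row-normalised matrix exactly.

**Stack criterion reading.** "Found 40% of the lesions correctly" is
operationalised as per-slice lesion-pixel recall ≥ 0.40 (inclusive), since
no instance-wise lesion matching is defined; slices without lesion pixels
have undefined recall and are excluded rather than counted either way.
Undefined pixel metrics (empty classes) surface as flagged `NA`, never as
silent 0 or 1.

**Grouping unit.** Cross-validation folds partition whole cases
(patients): the only leakage-safe reading of per-set splitting. Pooling is
by summed confusion counts — a single pooled confusion matrix, as in the
published evaluation — not by averaging per-fold metrics.

**Augmentation.** Applied on the fly each epoch (not pre-expanded on
disk), with bilinear resampling and symmetric-reflection fill so no flat
borders foreign to RCM texture enter the training stream.

## Numerical conventions

- "Same" padding uses the TensorFlow convention: output `ceiling(n/s)`,
  any odd padding going to the bottom/right.
- Gaussian smoothing truncates the kernel at 3σ, normalises it to unit
  sum, and uses symmetric reflection at the borders (mass-conserving);
  after channel-wise smoothing the probability pair is renormalised per
  pixel.
- Thresholding is inclusive at the threshold; erosion before dilation, in
  that order, so the pair is a morphological opening (idempotent,
  anti-extensive with σ = 0, and monotone in the threshold).
- Lesion placement rejects overlaps (bounding-circle test) and keeps each
  island plus its fissure fully inside the slice; parameters whose largest
  lesion cannot fit are rejected outright.
- All gradients of the network engine are exact and are verified against
  central finite differences in the test suite.

## Scale of the shipped experiments

The test suite and the acceptance script run a deliberately scaled-down
version of the full design, chosen as the smallest experiment in which the
planted signal is comfortably recoverable: 6 synthetic cases × 1 stack ×
4 slices at full 1000×1000 resolution, a tiny-width aligned backbone
(4-8-8-16-16 channels, ~1.3k parameters), 5×5 patch tiling per slice
(stride 186), grouped 6-fold (leave-one-case-out) cross-validation, and
5 epochs of Adam at learning rate 1e-2 with batch size 8. The larger
learning rate relative to the full-scale recipe reflects the ~100× smaller
model and dataset; the 1e-5/20-epoch defaults remain in `train_config()`
for full-scale use. Under these conditions the pooled pixel specificity is
typically ≥ 0.98 and sensitivity ≥ 0.65, and most or all stacks and cases
are detected — comfortably above the clinical analogues, as expected for
high-contrast synthetic lesions.

## Known limitations

- The network engine is plain R; it is sized for tiny-width desk
  experiments, and full MobileNet-scale training (millions of parameters,
  tens of thousands of patches) is out of its intended range.
- The generator's lesions are smooth ellipses; classifiers trained on them
  learn brightness/contrast cues, not the morphological criteria an expert
  uses. Sensitivity on real RCM data cannot be inferred from these
  experiments.
- With the default 3×3 kernels the dense heatmap is the standard
  *approximate* convolutionalization — only the aligned-kernel variant is
  exactly equivalent to patchwise evaluation.
- Stacks are generated as independent slices; no depth correlation between
  consecutive slices is modelled, which makes the stack-level criterion
  statistically easier than on real stacks.

## A minimal run

```{r example, eval = FALSE}
params <- rcm_params(n_cases = 6, stacks_per_case = 1, slices_per_stack = 4)
dataset <- generate_dataset(params)

cv <- run_cv(
  dataset,
  spec      = tiny_backbone_spec(c(4, 8, 8, 16, 16), kernel = "aligned"),
  rule      = patch_rule(stride = 186),
  train_cfg = train_config(learning_rate = 1e-2, epochs = 5, batch_size = 8),
  cv_cfg    = cv_config(k = 6)
)
glance(cv)    # pooled sensitivity/specificity, stack and case rates
tidy(cv)      # per-fold confusion counts and metrics
autoplot(cv)  # per-fold bars with pooled reference lines
```
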