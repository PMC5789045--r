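---
title: "Transparent Kellgren-Lawrence grading with a Siamese convolutional ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transparent Kellgren-Lawrence grading with a Siamese convolutional ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Radiographic knee osteoarthritis is graded on the Kellgren-Lawrence (KL)
scale, five ordinal levels from KL-0 (no changes) to KL-4 (end-stage
disease), by reading three features off a plain radiograph: narrowing of the
joint space between femur and tibia, marginal osteophytes, and subchondral
sclerosis. Reader agreement is famously modest, which motivates a
computer-aided grader whose decisions are *transparent*: besides a grade it
should say where in the joint it looked.

`kneekl` implements such a grader around a structural prior: the relevant
findings occur at the two joint compartments, and the *learned* low-level
features (edges, textures) needed on the lateral side are the same as on the
medial side once the medial patch is mirrored. Concretely:

1. A localised knee-joint region (16-bit, known pixel spacing, 140 mm
   nominal size) is intensity-normalised to 8 bits by clipping at its 5th
   and 99th intensity percentiles and mapping the clip bounds to 0/255,
   centre-cropped to 130 x 130 mm, and resampled to a 300 x 300 grid.
   Left knees are mirrored into right-knee orientation first.
2. Two square `S = 128` px patches are cut: the lateral patch at the left
   edge and the medial patch at the right edge, both with their top edge at
   `K = 100` px; the medial patch is horizontally flipped.
3. One shared convolutional branch — five 3 x 3 *valid* convolutions
   (stride 2 in the first layer, each layer strictly shrinking the map,
   2 x 2 max-pools after layers 2 and 3), each followed by batch
   normalisation and ReLU — maps either patch to 10 x 10 activation maps,
   which global average pooling reduces to a descriptor. The two
   descriptors are concatenated, passed through dropout (rate 0.2) and one
   linear layer to five unnormalised grade scores. Sharing the branch
   halves the branch parameter count relative to an unshared twin
   (`parameter_count()` makes the comparison exact).
4. Three such networks are trained from seeds 21, 42 and 84; at inference
   their pre-softmax scores are *summed* and softmaxed into one probability
   distribution over KL-0..4. The binary radiographic-OA score is the tail
   mass `P(KL >= 2)`.
5. Attention: for a target grade `c`, each branch's class-discriminating
   map is `ReLU(sum_k w_k A_k)` where `A_k` are the pre-GAP maps and `w_k`
   is the gradient of the class score with respect to the pooled feature
   `k`. Because the maps feed a global average pooling and a linear head,
   that gradient equals the spatial average of the per-pixel gradients (up
   to the constant `1/(XY)`, which cancels in the final min-max
   normalisation) — the package's tests verify this equivalence against a
   finite-difference oracle. Ensemble maps are the entrywise sums of member
   maps, which is exactly the map of the summed class score by linearity of
   the gradient. Maps are bilinearly upsampled to patch size, the medial
   map un-flipped, both pasted at their patch origins (max-blended if they
   overlap) and min-max normalised to [0, 1].

The deliberately shallow branch is the point of the design: the last
activation maps stay at 10 x 10 for a 128 px patch, versus 7 x 7 for a
224 px input in a ResNet-34, so the attention maps resolve joint margins
rather than whole-image context.

## Interpreting the fusion rule

The ensemble rule is implemented as the softmax of the *sum of the members'
pre-softmax scores* (`fuse_logits()`). Summing per-member softmax outputs
would also normalise but is a different statistic; the implementation
follows the reading under which the summed quantities are the raw network
outputs, and the tests pin the chosen semantics (shift invariance per
member, uniform output for constant scores).

## Patch geometry: two readings

For a 300 px grid with `S = 128`, `K = 100`, placing the lateral patch at
`x = 0` and the medial patch at `x = S - K = 28` would leave the rightmost
(medial) third of the joint completely unobserved, contradicting the stated
purpose of grading both compartments. The package therefore defaults to the
right-aligned medial origin `x = resized_px - S = 172`, with `K` acting as
the shared vertical offset; the literal `S - K` placement remains
constructible via `patch_geometry(variant = "literal")` so both readings
can be compared.

## Training recipe

Training (`train_one()`, `train_bundle()`, or the `kl_grader()` front end)
follows the classical recipe: class balancing by oversampling with
bootstrap replacement (each grade equally likely per draw), on-the-fly
augmentation, Adam (learning rate 1e-2, L2 weight decay 1e-4, batch 64 at
full scale) on cross-entropy, validation every `eval_every` iterations, and
per-seed snapshot selection by validation quadratic kappa (ties to the
earliest iteration). Everything — weight initialisation, sampling,
augmentation, dropout — is driven by the member seed, so runs are exactly
reproducible in a single-threaded session.

Augmentation draws rotation (±10°), brightness (±30 8-bit units), contrast
(x 0.8-1.2), translation jitter (±15 px) and gamma (0.8-1.25), applies them
in a randomly permuted order, and then takes the 130 mm crop. These
magnitudes are package choices: the literature on this pipeline leaves the
exact ranges to training scripts, and the chosen values cover the
plate-positioning and exposure variation seen across acquisition sites
without destroying grade information. Numerical choices worth knowing:

* the two geometric operations are composed into a single affine map (in
  their drawn relative order) and applied in one bilinear resampling pass;
  out-of-bounds samples clamp to the nearest edge pixel;
* contrast pivots at the 8-bit midpoint 127.5 rather than the image mean,
  so all three intensity operations are pointwise and commute with
  resampling exactly (gamma only approximately);
* inside the training loop the crop, the grid resize and the geometric
  transform are folded into one affine map and only the two patch grids
  are resampled. For an identity draw this equals the step-by-step
  pipeline to machine precision; under rotation it avoids a second
  interpolation pass (slightly *sharper* than sequential resampling);
* patches are standardised to zero mean/unit variance per image (both
  patches jointly) at tensor conversion. A consequence: brightness and
  contrast augmentations act only through their interaction with clipping
  and gamma.

Batch normalisation computes its training statistics over the stacked
lateral + medial batch (the branch genuinely sees one batch of 2B patches),
and stores running statistics for deterministic evaluation-mode inference.

The engine itself — the (H, W, batch, channel) tensor layout, valid 3 x 3
convolution as nine shifted-slice GEMM accumulations, batch-norm and
pooling kernels, backpropagation, Adam — lives in the package (`src/` holds
the compiled hot loops). Numerical gradients of the full loss agree with
the backward pass to ~1e-10 in the tests.

## Test-time exposure correction

Over- and underexposed images are gamma-corrected at inference. The trigger
is a package choice: if the mean intensity leaves the band [60, 180], the
first gamma from {0.5, 0.67, 1.5, 2.0} that brings the mean into the band
is applied (closest-to-band as fallback). The band is wide enough that
normally exposed images pass untouched.

## The phantom generator

Because the real cohorts behind this method are access-restricted, the
package ships a synthetic generator (`make_phantom()`, `make_dataset()`)
that renders the *geometry* of the grading problem: two cortical bone bands
on a soft-tissue background separated by a joint space whose width
decreases with grade (defaults 6, 5, 4, 2.5, 1 mm, drawn with 0.35 mm
jitter), Gaussian osteophyte blobs at the four joint margins growing with
grade, subchondral bands brightening with grade, plus random joint-line
tilt (±1.5°), vertical shift (±5 px), pixel noise and a global offset.
Each phantom carries a ground-truth joint-margin mask (run-length encodable
for sidecar storage) used by the attention-localisation tests.

What the phantoms *are not*: anatomy. They have no trabecular texture, no
patella, no soft-tissue gradients, no implants, no projection effects. A
model that aces phantoms has demonstrated that the pipeline wiring,
optimisation and attention arithmetic work end to end — not that it grades
human radiographs; the noise parameters are set so that adjacent grades
overlap (the task is not trivially separable) while a desk-scale run stays
learnable.

## Desk-scale experiment sizes

`synthetic_recovery()` is the package's scaled stand-in for a full-cohort
training run, with sizes chosen as a deliberate design point: 100 phantoms
per grade (300 train / 100 validation / 100 test), a width-reduced branch
(`N = 8`, giving a 16-dimensional descriptor), batch 16, 200 iterations
with validation every 50, three seeds (21, 42, 84). On phantoms this
configuration reaches held-out quadratic kappa well above 0.9 and
concentrates attention inside the joint-margin masks of grade-3/4 phantoms
(one-sided paired Wilcoxon on mean attention inside vs. outside the mask,
restricted to patch-covered pixels). The full-scale defaults
(`kl_train_config()`: batch 64, 50,000 iterations, evaluation every 500)
remain available for real cohorts.

## Degenerate inputs and edge conventions

* Constant images make percentile truncation ill-posed; it errors rather
  than divides by zero. Rescaling rounds half-to-even, then clips.
* Centre cropping with an odd margin drops the extra pixel from the
  top/left (it stays on the bottom/right), fixing crops deterministically.
* All resampling is endpoint-aligned bilinear with edge clamping; corner
  pixels are preserved exactly under pure resizing.
* An identically zero attention map renders as an all-zero overlay (the
  min-max step does not divide by zero).
* Max-pool gradient ties go to the first cell in scan order; snapshot-
  selection ties go to the earliest iteration.
* The "guided backpropagation" refinement of attention gradients is a
  no-op at the layer these maps are read from — no ReLU lies between the
  pre-GAP maps and the class score — so the package computes plain
  gradients and documents the equivalence rather than offering a mode
  switch.

## Known limitations

* Real-data inputs assume an upstream knee-joint localiser; the package
  consumes bounding boxes (`read_bbox_csv()`), it does not find joints.
* The DICOM reader covers uncompressed implicit/explicit little-endian
  single-frame files — standard radiography exports — not compressed
  transfer syntaxes or sequences.
* Channel widths per convolution block are a package default
  (`c(N/2, N/2, N, N, N)`, `N = 64`); the builder accepts any five-layer
  width vector satisfying the spatial-trace invariant.
* Phantom realism, as above; reported phantom metrics say nothing
  quantitative about clinical cohorts.
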