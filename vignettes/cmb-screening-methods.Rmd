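---
title: "Two-stage cerebral microbleed screening: models, phantoms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage cerebral microbleed screening: models, phantoms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cmbscreen)
```

## The problem

Cerebral microbleeds (CMBs) are small (2-10 mm) hemosiderin deposits that
appear as round hypointense foci on susceptibility-weighted MRI (SWI),
occupying only about 4-32 pixels on a typical slice. Screening a patient
means scanning a stack of SWI slices (commonly 130 per patient) for these
tiny targets while rejecting their *mimics*: cerebral calcifications,
which look identical on SWI but are diamagnetic and therefore *bright* on
the companion phase image, and vessel cross-sections, which are elongated
and persist across many consecutive slices.

`cmbscreen` implements a two-stage screening pipeline:

1. **Detection** — a lightweight anchor-free single-stage convolutional
   detector runs on SWI slices only and proposes candidate regions with
   high sensitivity.
2. **Classification** — each candidate is re-examined as a small 3D
   volume spanning the adjacent SWI slices and the matching phase slice,
   *fused with encoded clinical text prompts* (age, gender, box geometry,
   slice adjacency, optional history), and false positives are rejected.

All models run on a compact reverse-mode automatic-differentiation engine
written in the package (`R/autograd.R`), whose every primitive is checked
against central finite differences in the test suite. No GPU, network
access or external deep-learning runtime is required.

## Box geometry and the NWD loss

IoU-family similarities collapse for tiny boxes: a one-pixel diagonal
shift of a 3 px box drops IoU to 0.29 while the same shift of a 24 px box
leaves it at 0.92. The normalized Wasserstein distance (NWD) instead
models each box as a 2D Gaussian (mean at the center, standard deviations
half the extents) and maps the 2-Wasserstein distance through a decaying
exponential,

$$\mathrm{NWD}(A,B) = \exp\!\left(-\frac{\sqrt{\Delta c_x^2 + \Delta c_y^2
  + \left(\tfrac{w_A - w_B}{2}\right)^2
  + \left(\tfrac{h_A - h_B}{2}\right)^2}}{C}\right),$$

with $C = 12.8$ and a stability constant $\delta = 10^{-7}$ added inside
the radicand. Both worked configurations above score about 0.9 under this
form — the scale robustness that motivates mixing it into the regression
loss. The published formula for the center term multiplies the x- and y-
differences; taken literally that reading returns a similarity of
essentially 1 for any one-axis offset and cannot reproduce the published
comparison table, so the package implements the standard Gaussian-
Wasserstein form above and keeps the literal reading available as
`nwd_similarity(..., variant = "literal")` for comparison only.

The detector's box objective is the convex mixture

$$L_{box} = (1-\lambda)\,(1-\mathrm{CIoU}) + \lambda\,(1-\mathrm{NWD}),$$

`combined_regression_loss()`. The mixing weight is nowhere stated in the
source material, so it is a configuration field, default
$\lambda = 0.5$: an equal blend keeps the overlap-driven CIoU gradient
while the NWD term damps the loss jumps that one-pixel jitter causes for
small targets. The stability test in the acceptance suite descends a
predicted box toward a jittering 3 px target for 200 steps and verifies
the mixed objective's per-step loss variance does not exceed pure CIoU's.

`delta` is placed inside each squared difference before the square root,
so the self-similarity of a box is strictly below 1 and the gradient
never stalls at exactly zero distance.

## The saliency attention block

The block (`cmbs_mha()`) builds **query** tokens by adaptive *max*
pooling of the feature map — max pooling picks up salient extremes, such
as the strong local responses of hypointense CMBs — and **key/value**
tokens by adaptive *average* pooling, a smoothed "background board" of
local context. Multi-head attention relates each salient query to the
background and the attended tokens are bilinearly interpolated back onto
the spatial grid and added residually.

Whether "global" pooling should produce a single vector or a token grid
is an open design point; a single global query would make attention a
rank-one operation, so the package uses pooled token grids (queries
$4\times4$, keys $8\times8$ by default, shrunk automatically for coarse
feature maps). The output projection is zero-initialized, which makes an
untrained block an exact identity: it can be inserted anywhere in a
backbone without perturbing it, and the property is tested. Parameter
cost is exactly $4(C^2+C)$ for $C$ channels — a few hundredths of a
million parameters at backbone widths, matching the "cheap plugin"
character of the design.

## The detector

`build_detector()` assembles a small anchor-free single-stage network:
stem and three downsampling stages with residual C2f-style blocks, a
two-level neck (strides 8 and 16), and decoupled objectness/box heads.
Scales N/S/M/X6 reuse the conventional depth/width multiplier idiom
(widths 0.25/0.5/0.75/1.25 of a 16-32-64-128 base, repeats 1/1/2/3);
matching any published parameter count is explicitly a non-goal.
Attention blocks sit after the last two backbone stages and after the
neck merge, the two insertion points the design names, and are
configurable.

Each ground-truth box is assigned to the cell containing its center, at
stride 8 if its longer side is below `small_box_px` (16 px) and stride 16
otherwise. Positive cells regress center offset (tanh, one-cell range)
and size (softplus, in stride units); objectness is binary cross-entropy
with positives re-weighted adaptively (a quarter of the background/
foreground count ratio, capped at 150 — the cap and a global gradient-norm
clip at 5 keep near-empty batches from destabilizing training, which was
observed without them). Inference is per-slice: decode, clip, greedy NMS
at IoU 0.5 with deterministic tie-breaking (score, then slice, then
lexicographic coordinates), then a global top-100 per patient.

**What the smoke-training experiment shows.** The acceptance suite trains
the N-scale detector on about 200 phantom slices (96 px, diameters 4-24 px
so the largest object still fits the placement disk at that resolution)
for 15 epochs and requires held-out recall $\ge 0.7$ at IoU 0.3 against
CMB ground truth. Stage 1 is trained on *candidate* boxes — CMBs and
mimics alike — because the phantom makes mimics SWI-identical to CMBs by
construction; asking a detector to suppress them from SWI alone is
self-contradictory, and the two-stage design defers that decision to the
classifier. In pilot runs recall crossed 0.7 around epoch 9 and kept
climbing; 15 epochs leave margin. This demonstrates the detection
machinery trains and generalizes at desk scale; it says nothing about
clinical performance.

## The multimodal classifier

The classifier consumes a `candidate_volume()`: a three-channel
$(3, 4, H, W)$ crop stack in fixed slice order (SWI $i-1$, SWI $i$,
SWI $i+1$, phase $i$), zero-padded and flagged at stack edges. The image
branch applies two 3D convolutions with spatial stride 2 (slice stride
1) — normalization and GELU after the first, normalization after the
second — adds a learned position embedding, and merges channels and
slices into the token-channel axis: a $64\times64$ crop yields a
$16\times16$ token grid with `embed_channels` (default 512) channels,
$512\cdot4$ token-channels after the merge. The channel schedule is
$3 \to C/4 \to C$ (only the endpoints are fixed by the design).

Text statements are encoded to 768-wide vectors, projected to the
token-channel width, mean-pooled over statements (so the output shape is
independent of the statement count), broadcast over the token axis,
concatenated along channels, and mixed by a kernel-1 convolution over
tokens. The mixing convolution sits inside a zero-gated residual
connection (ReZero-style): `fused = image_tokens + g * conv([image;
text])` with randomly initialized convolution weights and a scalar gate
`g` initialized at 0. Fusion therefore starts as an exact no-op,
contributes nothing to early gradients, and enters only as fast as it
reduces the loss. The choice is empirical as well as principled: in
pilot runs an ungated mixing layer cost about nine validation-accuracy
points *even when fed constant text* — pure optimization drag at small
training budgets — and a zero-initialized residual convolution is
mathematically identical to an identity-initialized plain layer (same
gradients, same Adam updates), so only the gate actually removes the
drag (down to about two points).
With `with_text = FALSE` the fusion step is skipped entirely — a distinct
code path, not a zeroed input. Classification applies a further 3D
convolution, flattens to tokens, prepends a class token with its own
position code, runs `depth` pre-LN transformer blocks and reads the class
token through a sigmoid head. Variants S/B use depth 4/8 and token width
256/512 (about a 4x parameter ratio); the experiments here use reduced
widths (embed 16, token width 32) so they run in minutes on one CPU.

Crop modes mirror the fixed-vs-dynamic resolution comparison: `fixed32` /
`fixed64` crop native windows of that side; `dynamic` crops twice the box
side (minimum 16, rounded to a multiple of 4) and pads to the batch
maximum. Phase crops always share the SWI window. The `averaged2d`
branch mode averages the four slices into one 2D image first — by
construction this destroys the phase/SWI distinction, which is why the
acceptance suite requires it not to beat the volumetric mode on phantoms
whose mimics are phase-distinguishable.

## Text prompts and the offline encoder

Prompts instantiate three fixed templates — demographics, box geometry
("length" is the box height and "width" the box width, both rounded
half-up; the template does not bind the words to axes, so the package
fixes the convention and documents it), and slice-adjacency for the
previous and next slice — plus one optional statement per history or
lifestyle item. "Same position" for adjacency means a detection on slice
$i\pm1$ whose center lies within max(box side, 5 px), a tolerance the
design leaves open.

The default encoder is a deterministic feature-hashing sentence encoder:
word tokens and character trigrams hashed onto 768 dimensions with
hashed signs, L2-normalized, 32-bit-safe and byte-identical across
platforms for a fixed seed. It exists so the entire pipeline builds,
trains and tests offline; any pretrained sentence encoder can be dropped
in as a plain `function(string) -> numeric(768)`. The hash encoder has no
semantics: two ages share features only through digit trigrams, which is
the main reason the text ablation below leans on the gender token rather
than fine-grained age similarity.

## The synthetic phantom

`generate_patient()` renders, per patient, a stack of SWI and phase
slices (16 slices of 256 px by default at test scale; a full-scale
emulation would use 130) over Gaussian noise (SD 6) with a smooth bias
field, and implants inside a circular brain region:

* **CMBs** — Gaussian-smoothed hypointense disks, diameter 4-32 px,
  spanning 1-3 slices with partial-volume tapering at span ends; dark in
  phase as well. Only these receive evaluation ground truth.
* **Calcifications** — drawn from the *same* SWI size and depth
  distributions (so SWI statistics cannot deterministically separate the
  classes — a tested invariant), but phase-*bright*, with contrast
  magnitude $6 + \mathrm{Exp}(14)$: the sign is always correct, the
  magnitude often small, mirroring the partial-volume unreliability of
  phase contrast for small lesions.
* **Vessels** — elongated capsules persisting over at least 4 slices,
  dark in both modalities.

Cohort structure: 37% of patients are CMB-positive; positives are older
on average (Normal(65, 9) vs Normal(58, 9) years, clipped to 30-90);
60% male. The calcification rate is modulated by metadata,
$\lambda_{calc} = \min(6,\; r\,e^{m\,((age-60)/20 + 0.8(\mathrm{female}-0.5))})$
with strength $m$ (`metadata_effect`, default 1.5): younger female
patients carry relatively more calcification mimics among their
hypointense lesions, which is what makes the demographic prompts
genuinely informative. Object placement is largest-first with retries;
objects may share in-plane positions only when their slice ranges are
disjoint, and an infeasible configuration fails loudly rather than
silently overlapping.

Pixel values are rounded to the integer 0-255 grid so PNG round trips are
exact. Every record regenerates byte-identically from its seed, and a
dataset manifest (spec, seeds, split, checksums) regenerates the whole
dataset — a tested closure property.

**What the phantom does not emulate:** brain anatomy, susceptibility
physics, k-space artifacts, scanner heterogeneity, or the long-tailed
appearance of real mimics. Passing the synthetic experiments shows the
*machinery* — losses, attention, fusion, training loops, metrics — works
end to end under the statistical structure the method assumes; it is not
evidence of clinical accuracy.

## The text-ablation experiment

The acceptance suite builds ~190 labelled candidates from 45 phantom
patients (8 slices, 128 px, metadata effect 1.5 — the generator
default), trains the reduced classifier for 12 epochs at matched seeds
and budgets, and compares held-out accuracy with and without text
(direction only), additionally requiring the 2D-averaged branch not to
beat the volumetric branch. The problem sizes (patients, epochs, widths)
were chosen from pilot runs as a configuration that runs in minutes on
one CPU; the margin of the text contrast at this scale is small (a few
validation candidates), an honest reflection of how much signal a
hash-encoded demographic prior carries at desk scale. A diagnostic worth
recording: with *constant* text the gated model closely tracks the
image-only model, so the gain measured for real prompts is attributable
to the text content, not to extra capacity.

## Patient-level metrics

Region rates are exact ratios with *undefined* (not 0) results on zero
denominators. `fpavg` is total false positives over patients. The
patient-level accuracy indicator admits two readings, and the package
reports both: the **literal** rule credits a CMB-negative patient
whenever the count of *true* CMB predictions is zero — vacuously true for
any negative patient — while the **strict** rule requires zero positive
predictions of any kind (a false alarm on a healthy patient is an
error). The literal value is provably never below the strict one (a
tested property). `match_and_map` implements greedy score-ordered
one-to-one matching with 101-point interpolated AP at IoU 0.50-0.95 and
is checked against a rasterized brute-force oracle.

The inference-time model is closed-form bookkeeping,
$(N_{image} D_{image} + 100\, C_{image})/1000$ seconds per patient on
supplied per-stage constants; wall-clock measurement is never used for
acceptance.

## Numerical and degenerate-input choices

* Boxes are continuous, 0-based, half-open when rasterized; degenerate
  boxes are errors, never silently repaired (except label conversion,
  which clips out-of-bounds boxes with a warning unless `strict`).
* CIoU's aspect term uses the conventional detached mixing coefficient.
* Undefined rates propagate as `NA` markers.
* NMS ties: score, then lower slice index, then lexicographic
  coordinates.
* All training loops are seeded, gradient-clipped (global norm 5) Adam;
  identical seeds give identical traces.
* Batch normalization uses batch statistics (training-scale inference is
  per-candidate batches); the detector avoids normalization layers
  entirely and standardizes inputs to [0, 1] instead.

## Known limitations

* The engine is plain R + BLAS: a few hundred thousand parameters and
  ~100-200 px images are the practical envelope; the full-width
  (512-channel) classifier is exercised forward-only.
* The hash text encoder carries no semantics; with a real sentence
  encoder the text branch would generalize over paraphrases and ages,
  which the ablation here cannot show.
* The flip-equivariance of detection holds for the decode/NMS geometry,
  not for arbitrary convolution weights.
* Patient-level results on phantoms use small cohorts; they exercise the
  bookkeeping, not clinical operating points.
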