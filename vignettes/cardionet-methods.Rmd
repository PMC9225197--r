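---
title: "CardioNet: model, training protocol, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CardioNet: model, training protocol, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardionet)
```

## The problem

On a posterior–anterior chest radiograph the cardiothoracic ratio

$$\mathrm{CTR} = \frac{D_L + D_R}{M}$$

— the maximum horizontal cardiac diameter over the maximum horizontal
thoracic diameter — screens for cardiomegaly: values above 0.50 are
abnormal, the normal range being 0.42–0.50.  Measuring it automatically
requires pixel-accurate segmentation of the lungs and the heart (and, for
multi-class anatomy, the clavicles).  This package implements CardioNet, a
shallow dense-concatenation encoder–decoder designed for that segmentation
task, together with everything around it: the declarative architecture
schedule and its audits, the deterministic augmentation cascade, the
class-balanced training protocol, per-class evaluation metrics, the CTR
geometry, and a synthetic phantom generator that provides labelled data
with an analytic ground-truth CTR.

## The architecture

CardioNet has three parts:

* a **downsample block (DSB)**: four stages, each with two convolutions
  whose outputs are depth-wise concatenated, compressed by a 1×1
  bottleneck (with batch normalization and ReLU) and max-pooled 2×2.
  Stages 1–2 use standard 3×3 convolutions, stage 3 one standard plus one
  depth-wise separable convolution, stage 4 two depth-wise separable
  convolutions — the cheaper separable form replaces the standard one where
  channel counts are large;
* an **upsample block (USB)** mirroring the encoder, with max-unpooling
  that places activations back at the positions recorded by the paired
  pooling layer.  Each decoder stage concatenates its two convolution
  outputs with a dense skip from the corresponding encoder stage (the first
  convolution's output, before pooling), bottlenecks the result, and
  unpools;
* a **feature-boost block (FBB)** (the "B" variant only): a branch fed
  from the input image through a 1×1 stem that applies six 3×3
  convolutions at full input resolution, with no pooling at all.  Its
  32-channel output joins the final full-resolution concatenation, whose
  width is therefore 64 + 64 + 32 = 160 (128 for the "X" ablation without
  the block).

With dense concatenation, stage widths 64/128/256/256 and a four-stage
encoder, the concatenation widths are 128, 256, 512, 512 on the way down
and 512, 640, 320, 160 on the way up; the deepest decoder stage takes no
encoder skip (512 = 256 + 256).  At a 350-pixel input the smallest encoder
map is 21×21: pooling floors odd sides (350 → 175 → 87 → 43 → 21) and
unpooling restores them exactly through the recorded indices.  A 1×1
bottleneck with as many filters as classes, followed by a per-pixel
softmax and argmax, produces the segmentation.

The schedule is data, not code: `build_cardionet_schedule()` returns a
table with one row per layer, from which `propagate_shapes()`,
`count_layers()`, `count_parameters()` and the executable network all
derive, and `write_schedule()` serializes it for line-by-line diffing
against an external description.

### Resolved printing ambiguities

Two cells of the published layer tables cannot be taken literally, and the
audit flags both: the third encoder bottleneck is listed with 128 filters
but a 256-channel output (the output column is taken as authoritative:
256 filters), and the fourth boost convolution is listed with a 16-channel
kernel although its input has 8 channels (input 8 is used).  The printed
trainable-parameter totals (1.72 M for B, 1.57 M for X) are not reachable
from the layer tables under a straightforward counting convention;
`count_parameters()` therefore exposes the convention explicitly — bias
terms only on convolutions not followed by batch norm, batch-norm
scale/shift trainable, and 1×1 bottlenecks counted either dense
("ungrouped") or grouped with as many groups as filters — and
`audit_schedule()` reports the totals under both conventions side by side
(about 2.11 M and 1.58 M for variant B) rather than forcing agreement.

## Training protocol

Training minimizes pixel-wise cross-entropy weighted by **median-frequency
balancing**: for class $c$, $f_c$ is the pixel count of $c$ divided by the
total pixel count of the images containing $c$, and the class weight is
$\mathrm{median}_k(f_k) / f_c$.  Rare structures such as clavicles thus
weigh more than the background.  The optimizer is Adam (learning rate
0.001, batch size 4, defaults in `cardionet_control()`), with global L2
gradient clipping: if the concatenated gradient norm exceeds a threshold
(default 2; the accompanying epsilon is $10^{-6}$) the gradient is rescaled.
The published protocol names a "global L2 normalization with epsilon
$10^{-6}$" without defining the scheme; clipping at an explicit threshold is
the standard reading and both knobs sit in the control object.  Convolutions
marked as batch-normalized carry no bias (BN absorbs it); the remaining
convolutions keep a bias.  Weights start He-normal
($\sigma = \sqrt{2/\text{fan-in}}$), BN at scale 1 / shift 0, and training
is bit-reproducible for a fixed `seed` on CPU.

One deliberate consequence of following the printed layer annotations: the
final classifier bottleneck is itself batch-normalized and ReLU-activated,
so the softmax sees non-negative scores.  This trains fine in practice and
is kept for fidelity.

Two numerical paths implement the graph.  The double-precision primitives
(`src/layers.cpp`) define the reference semantics of every operation —
im2col+GEMM convolutions, depth-wise convolution, pooling with indices,
batch norm, weighted softmax cross-entropy — and are validated against
finite-difference gradients in the test suite.  Training and batched
prediction run on a single-precision executor (`src/model.cpp`) with
preallocated workspace, which the tests hold to agreement with the
reference path at single-precision tolerance.  On one CPU core a training
step at side 96 with batch 4 takes a few seconds.

## The augmentation cascade

`expand_fold()` implements the fully deterministic four-stage cascade: (1)
originals plus horizontal flips; (2) plus a translation of (X = 4, Y = −4);
(3) plus flips of stage 2; (4) two branches over the whole stage-3 set,
translating by (8, 8) and by (−12, −12), each branch keeping the
translated images together with their horizontal flips.  Each branch thus
doubles stage 3 and the returned set is the union of the two branches: a
fold of $n$ images becomes exactly $32n$
(124 → 248 → 496 → 992 → 1984 + 1984 = 3968); no randomness is involved,
so no seed is needed.  Conventions the source leaves open and
this package fixes: X moves columns (positive rightward), Y moves rows
(positive downward); vacated image borders are filled by edge replication
(a zero fill would fabricate dark bands at lung borders) while masks are
filled with background; masks translate with nearest-neighbour semantics
and are never interpolated — resizing uses bilinear interpolation for
images and nearest-neighbour for masks.  Cropping belongs to the announced
transformation vocabulary but not to the cascade and is provided only as a
utility (`crop_center()`).  Two-fold evaluation (`two_fold_protocol()`)
splits the data into odd- and even-numbered halves, augments the training
fold only, and averages the per-class metrics of the two directions.

## Metrics

Per class, one-vs-rest confusion counts give accuracy $(TP+TN)/\text{all}$,
Jaccard $TP/(TP+FP+FN)$ and Dice $2TP/(2TP+FP+FN)$, so $D = 2J/(1+J)$ and
$J \le D$ always.  (The published Dice denominator is typeset without the
factor 2 on $TP$; that reading would leave the range of $D$ undefined, so
the standard form is used.)  Over a test set the counts are summed before
scoring (micro-averaging) by default, with macro-averaging as an option —
the source does not state which it used.  A class absent from both masks
scores $J = D = 1$ (perfect agreement on absence); this matters for
clavicle-free phantoms.

## CTR geometry

`compute_ctr()` takes the horizontal extent of the heart class as
$D_L + D_R$ and of the combined lung fields as $M$.  Two conventions are
fixed and documented:

* **pixel distances are index differences** (`max_col − min_col`), applied
  identically to numerator and denominator, so the ratio is insensitive to
  the inclusive-vs-difference choice to within $1/M$.  The published worked
  example (126/304 = 0.4145) cannot disambiguate the convention; the same
  source also prints a ground-truth CTR of 0.4045 for distances 123/303,
  whose quotient is 0.4059 — the implementation computes the quotient and
  does not reproduce that printed value.
* **small-island suppression**: extents are measured after discarding
  connected components smaller than a fraction (default 0.1) of the class's
  largest component.  A fraction is used instead of "keep the single
  largest component" because the lung class legitimately consists of two
  similar-sized components; keeping only one would halve $M$.

The midline for reporting $D_L$ and $D_R$ separately is the midpoint of
the thoracic extent; since $(mid - min) + (max - mid) = max - min$, the
reported cardiac diameter never depends on where the midline sits.
Decisions: CTR > 0.50 cardiomegaly, 0.42–0.50 normal, < 0.42 below normal.

## The phantom generator

`make_phantom_dataset()` produces the labelled data every other module is
exercised with: two elliptical lung fields, a cardiac half-ellipse pair
straddling the midline and overlapping the medial-inferior lung borders,
two thin tilted clavicle bars, a smooth illumination gradient and additive
Gaussian noise (σ = 0.03 by default on a [0, 1] intensity scale).
Intensities are absolute attenuation levels with override semantics — air
dark (0.25), soft-tissue background 0.55, cardiac silhouette 0.66, bone
0.88 — so the heart/background boundary is deliberately low-contrast while
bone stays bright over lung, as on a film.  Mask labels follow the same
precedence (heart over lung, clavicle over lung), one label per pixel.

Geometry is snapped to a half-pixel grid: centers are integers, semi-axes
half-integers.  With that alignment the rasterized horizontal extent of
each structure is exactly its analytic width minus one index difference,
so the measured CTR $(C-1)/(S-1)$ sits within $2/M$ of the closed-form
$\mathrm{CTR} = (a_L + a_R)/S$ deterministically — the recovery tolerance
the tests assert, rather than a statistical statement.  Dataset generation
is a pure function of `(n, side, seed, parameters)`; the fraction of
phantoms with CTR above 0.50 is controlled by `p_cardiomegaly` (targets
drawn uniformly from (0.51, 0.60) or (0.40, 0.50)).

What the phantoms do **not** emulate: ribs and vasculature, pathology,
projection physics, scanner heterogeneity, or the inter-observer ambiguity
of real annotations.  Phantom segmentation is close to intensity-separable
by construction, so passing the desk-scale learning checks demonstrates
that the architecture, loss, and optimization are wired correctly — not
that real-radiograph accuracies would be reproduced.  Published JSRT/MC
accuracy tables require the real datasets and full-scale training and are
explicitly out of scope here.

## Problem sizes used by the checks

The test suite runs everything at desk scale, chosen as the package's own
test conditions: schedule conformance at the native 350 input;
gradient checks on a 32-pixel, three-class network; a single-phantom
overfitting sanity run at side 48 (150 steps, batch 1); and the learning
check at side 96 — 64 training phantoms, 16 held-out, 5 epochs, batch 4 —
where the B variant must reach a mean foreground Jaccard of at least 0.80
and must not trail the X ablation by more than 0.05.  CTR recovery is
checked on 200 seeded phantoms.  The full 350-resolution, 30-epoch
configuration remains available through `cardionet_control()`.

## Known limitations

* No DICOM ingestion and no pre-trained weights are shipped; training is
  always from scratch.
* The executor is single-threaded; large-resolution training is CPU-bound.
* `horizontal_extent()` assumes the mask's column axis is the anatomical
  horizontal; rotated radiographs must be rectified upstream.
* The cardiomegaly decision is a threshold on one ratio; it is a screening
  aid, not a diagnosis.
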