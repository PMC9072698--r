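---
title: "Continual-learning particle picking: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continual-learning particle picking: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centerpick)
```

## The detection model

`centerpick` treats particle picking as anchor-free keypoint detection.
A convolutional trunk reduces a standardized micrograph to feature maps at
output stride $R = 4$; three small convolutional heads regress

* a center-confidence heatmap $\hat Y \in [0,1]^{W/R \times H/R}$
  (sigmoid output),
* a two-channel sub-cell offset field $\hat O = (\delta\hat x, \delta\hat y)$
  that restores the precision lost to the stride,
* optionally a two-channel size field $\hat S = (\hat w, \hat h)$.

Peaks of $\hat Y$ (strict 3×3 local maxima above a score threshold) decode
to centers $(\hat x + \delta\hat x,\, \hat y + \delta\hat y)\cdot R$.
Size prediction is off by default: single-particle samples are homogeneous
in size, a constant per-sample box is assigned instead, and dropping the
head improves center accuracy. For size-sensitive targets such as
vesicles the head is enabled with `detector_config(predict_size = TRUE)`.

Ground truth for training is rendered by `render_targets()`: each
annotation splats an unnormalized Gaussian with peak exactly 1 at its
low-resolution cell $\tilde p = \lfloor p/R \rfloor$ and
$\sigma = \max(1, \mathrm{radius}/(3R))$, combined across particles by
elementwise max. The soft shoulders matter because the negative branch of
the focal loss is modulated by $(1-Y)^\beta$: cells near a true center are
penalized less for high predictions. The offset target at the peak cell is
$p/R - \tilde p$, which makes the render→decode round trip exact — a
property the test suite asserts to 0 px.

### Losses

The detection loss is $L_{OD} = L_k + \lambda_{off} L_{off} +
\lambda_{size} L_{size}$ with $\lambda_{off} = 1$,
$\lambda_{size} = 0.1$. $L_k$ is a pixel-wise focal loss with
$\alpha = 2$, $\beta = 4$; predictions are clamped to
$[10^{-4}, 1-10^{-4}]$ before logarithms (a numerical-safety choice).
With Gaussian-splatted targets, "cells with $Y = 1$" means exactly the
peak cells; every cell with $Y < 1$ takes the negative branch.

In sparse-annotation mode the center loss additionally (i) applies the
positive branch to unlabeled cells whose prediction exceeds
$\tau_1 = 0.7$ (a pseudo-label: a confidently detected but unlabeled
particle), and (ii) applies the negative branch only where the prediction
is below $\tau_2 = 0.5$. The band $[\tau_2, \tau_1]$ contributes nothing,
so potential unlabeled positives are not punished. With splatted targets
the gating applies to all cells with $Y<1$, which reconciles the binary
notation of the rule with soft targets. Whether the exemplar images
should use the sparse or dense variant during continual learning is
genuinely open; the package mirrors whatever mode is configured for the
new data (dense by default).

### The continual objective

A continual step trains branch B (initialized from the old model) while
branch A stays a frozen copy of it:

$$L_{Total} = L_{OD} + \lambda_d L_{Distill} + \lambda_r L_{Reg},
\qquad \lambda_d = 0.1,\ \lambda_r = 0.01 .$$

$L_{Distill}$ compares branch B's trunk features, center heatmap and
offset field to branch A's on *exemplar images only*, each term normalized
by its own element count; the size field is not distilled. $L_{Reg}$ is
the plain (unnormalized) sum of squared parameter differences from the old
model, guarding against overfitting the small exemplar. After training,
branch A is discarded — checkpoints always contain a single path.

Batches are mixed rather than alternated: a fraction `exemplar_mix = 0.5`
of every batch comes from the exemplar store. This realizes the averaged
gradient direction between old and new data at every step rather than at
epoch granularity. With `exemplar_mix = 0` and both weights zero, a
continual step follows the fine-tuning parameter trajectory exactly
(asserted bit-for-bit in the tests) — continual learning is a strict
superset of fine-tuning.

The exemplar itself is a contiguous run of 200 annotations in
annotation-file order, starting at a seeded random index and spanning
micrograph boundaries if needed; datasets with fewer annotations are kept
whole. A contiguous run (rather than a uniform subsample) keeps the
retained annotations spatially clustered on few micrographs, so the store
stays small. Entries are immutable once written.

## Training machinery

No deep-learning framework is involved: convolution and transposed
convolution are im2col reductions to base matrix products, with
analytically derived gradients (finite-difference-checked to ~1e-10 in
the tests) and an Adam optimizer (default learning rate 1.25e-4, the
usual keypoint-detector setting; the desk-scale benchmark uses 1e-3 to
converge within its 300-step budget). Two trunks are provided:

* `tiny` — three stride-2 3×3 conv blocks (16/24/32 channels) and one
  stride-2 transposed-conv block, reaching stride 4. This is the
  default and the backbone used by every test; the continual-learning
  machinery is backbone-agnostic.
* `dla34` — a config-gated deeper trunk in the spirit of deep layer
  aggregation: a stem, three stride-2 stages (32/64/128 channels), a
  transposed-conv upsampling path and an aggregation node fusing the
  stride-4 stage via a projected skip. It is a miniature, not a literal
  34-layer DLA: without pretrained weights the full architecture brings
  nothing at desk scale, while this variant keeps the
  hierarchical-aggregation idea testable on a CPU.

Augmentation is random horizontal/vertical flips (exact coordinate
mirroring) and optional random crops (annotations outside the window are
dropped, the rest shifted). Crops must be at least twice the output
stride. Input sizes must be multiples of $2R$; `pad_for_detector()` pads
with edge values.

## Preprocessing

Micrographs are down-sampled to a fixed width of 1024 px (height scaled
to preserve aspect), histogram-equalized globally on 256 bins, and
quantized to 8-bit. Down-sampling uses an exact area (local-mean) kernel
computed from cumulative sums — the standard anti-aliasing choice, exact
block averaging at integer ratios. Equalization runs *after*
down-sampling: it is cheaper on the reduced image, and quantizing last
guarantees the 256-level output contract. Picking tolerates the induced
centering error: the offset head recovers sub-pixel positions on the
reduced grid, and mapping back multiplies by the recorded
`preprocess_scale`, so the residual error stays below one preprocessed
pixel in original coordinates. Upscaling narrower inputs is refused
unless explicitly allowed.

## Evaluation

Matching is greedy in descending score with an IoU threshold of 0.5 and
single use of each ground-truth box; when size prediction is off, a
constant per-sample box side is assigned to both predictions and ground
truth. AP is the all-point-interpolated area under the precision–recall
curve swept over score thresholds, computed per micrograph and then
averaged (micrographs without ground truth are excluded with a warning);
AR is the per-micrograph recall at threshold 0, averaged. All-point
interpolation was chosen over the older 11-point scheme as the modern
default; an exhaustive threshold-enumeration oracle in the tests pins the
semantics to 1e-9. The complexity score $C = 100/10^{AP+AR}$ takes AP/AR
as fractions, giving the documented range $[1, 100]$ with $C=1$ at
perfect transfer and $C=100$ at total failure.

## Fiber tracing

The line tracing algorithm links picked points into chains: from a start
point, repeatedly connect the nearest unused point within radius
`r = 100` px (width-1024 scale) whose turning angle against the previous
segment is at most `ang`; nearer candidates failing the angle test are
skipped; when none qualifies the fiber closes and a new one starts, so
the result partitions the input. Two deliberate choices:

* The *first* link also honors the radius `r` (an unbounded first link
  could bridge distinct fibers); `first_link_unbounded = TRUE` restores
  the unrestricted behavior.
* Start points are seeded-random by default; `deterministic_start`
  (lowest unused index) makes benchmark recovery reproducible — note a
  mid-chain random start can legitimately split a chain in two, since the
  tracer cannot turn back through 180°.

Smoothing is a single left-to-right pass removing interior points whose
turn angle is below 0.1 rad; endpoints and corners survive. It does not
iterate to a fixed point; one pass already removes every point of a
straight run.

## The synthetic generator, and what passing tests mean

`make_particle_scene()` renders anti-aliased analytic shapes (disk, ring,
Gaussian blob, rod) with signed contrast on a flat background, plus
Gaussian white noise and large low-frequency contamination blobs;
`make_fiber_scene()` renders smooth point chains with bounded turning;
`make_vesicle_scene()` renders rings with known radii, optionally with a
guaranteed overlapping pair. Everything is deterministic under its seed,
and every rendered object carries exact ground truth.

The desk-scale benchmark uses two species chosen to be clearly distinct —
dark disks of radius 5 px versus bright rings of radius 8 px — on 64×64
scenes with 5 particles each (minimum separation 14 px, noise σ = 10),
16 training and 8 test scenes per species, 300 Adam steps at batch 4.
These sizes were chosen once so a full joint/fine-tune/continual
comparison over three seeds completes in minutes on one CPU. Under these
conditions fine-tuning on species B loses roughly half its average
precision on species A while the continual model retains it fully, and
both reach species B equally — the qualitative forgetting phenomenon and
its cure.

What this does *not* show: the generator has no contrast transfer
function, no dose or ice-thickness gradients, no structured noise, no
crowding or overlap between particles of interest, and the species are
far more separable than real protein datasets. Passing these tests
validates the algorithmic machinery (losses, rehearsal, distillation,
decoding, metrics) exactly, and the continual-learning behavior
qualitatively — not picking accuracy on real micrographs, which depends
on backbone capacity and data realism outside this package's scope.

## Degenerate inputs and numerical conventions

* Empty annotation sets render all-zero targets; the focal loss with
  $N = 0$ and no positives divides the negative term by 1 (a documented
  convention); the offset/size losses return 0.
* Two annotations in one heatmap cell produce a single positive cell
  (the first annotation's offset target wins) while $N$ still counts
  both particles.
* Equal-valued adjacent heatmap peaks within one 3×3 window decode to a
  single detection; ties break to the lowest row-major index.
* Precision and recall are 0 when their denominators are 0.
* Scene specs whose particle count times squared separation exceeds the
  field of view are rejected up front; feasible-looking specs that still
  cannot be placed fail after 500 bounded retries per particle.
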