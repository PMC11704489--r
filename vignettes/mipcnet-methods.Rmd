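---
title: "Mutual position/channel attention for boundary-accurate segmentation: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutual position/channel attention for boundary-accurate segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method it implements: the
model and its assumptions, the parameters that matter, how the synthetic data
are built and what they can and cannot show, and the numerical and design
choices made where the design was genuinely open.

## The problem and the block

Segmentation of medical images lives or dies at organ boundaries: region
overlap (Dice) can look respectable while outlines are several millimetres
off, which is what the Hausdorff distance exposes. The architecture here
targets boundaries by combining two complementary forms of self-attention —
over spatial positions and over feature channels — and, crucially, by letting
each one *gate* the other instead of running them independently.

All feature maps are `(batch, channel, row, col)` arrays. The core block has
three parallel parts, all fed the same input `X`:

**Part A — position-dominant.** The position attention module (PAM) computes
an `(H·W) × (H·W)` affinity `softmax(QKᵀ)` from 1×1-convolution projections
`Q, K` (width `max(1, C/8)`), applies it to a value projection `V`, and adds
the result back through a learnable scale: `PAM(X) = X + γ_p · AV`. A channel
summary gates it: global average pooling over space, a two-layer bottleneck
(reduction ratio `r`, hidden width `max(1, ⌊C/r⌋)`, ReLU between), then a
sigmoid, giving one gate per channel. Part A is the elementwise product.

**Part C — channel-dominant.** The channel attention module (CAM) computes a
`C × C` affinity as the row softmax of the Gram matrix `FFᵀ` of the
`C × (H·W)` channel descriptors and applies it back to the channels, again
with a learnable scale on the attended output. The gate comes from pooling
*across* channels: per-pixel max and mean maps, concatenated and passed
through a `k × k` convolution (default `k = 7`, zero padding) and a sigmoid,
giving one gate per pixel.

**Part B — residual.** Two 3×3 convolutions of the input, multiplied
elementwise, refined by a third 3×3 convolution. This path carries original
feature content past the attention machinery.

The outputs are added elementwise and passed through a classic residual tail
(3×3 conv → batch norm → ReLU → 3×3 conv → batch norm, identity shortcut,
final ReLU).

*Reading of the gating equations.* The source equations for Parts A and C
can be parsed as "sigmoid of the product" or "product with the sigmoid of the
gate path"; the accompanying prose ("following sigmoid processing of the
pooled summary, multiply elementwise") and the semantics of a gate — a
bounded multiplier on an unbounded carrier — both demand the second reading,
which is what the package implements.

*Mix variants.* We generalise the two parts by one rule: within each pair,
the **auxiliary** branch passes through the sigmoid and gates the **primary**
branch, which stays linear. The default is PAM primary / channel-pool
auxiliary in Part A and CAM primary / position-pool auxiliary in Part C. The
four permutations of this rule form the block-internals ablation grid; when a
pooled summary is primary, its (pre-sigmoid) output is broadcast to a full
map and the attended map, through a sigmoid, becomes the gate.

*CAM affinity.* Some dual-attention implementations replace the channel
affinity by `softmax(max(E) − E)`; the package uses the plain row softmax of
the Gram matrix, matching the plain "affinity softmax" description of the
module. This is a documented formulation choice, pinned by the oracle tests.

*Attention scale initialisation.* `attention_params(scale_init = )` defaults
to 0.1 rather than the conventional 0. At exactly 0 both attention modules
are identities **and their projection weights receive exactly zero
gradient** — the branch cannot start learning until the scale itself moves.
A small positive initial scale keeps the near-identity start while giving
every parameter gradient from the first step. `scale_init = 0` remains
available and is what the identity-limit tests use.

## The network

Three convolutional stages (conv–BN–ReLU twice, then 2×2 max pooling) halve
resolution and double width, `base·{1,2,4}`, emitting skips at 1/2, 1/4 and
1/8 resolution. The deepest features pass through a MIPC block (ablatable),
then patch embedding: the 1/8-resolution map is cut into `patch_size`-pixel
tokens (default 2, i.e. an effective 16-pixel patch at the input — at
224-pixel inputs the 1/8 map is 28 pixels, which a 16-pixel token could not
tile, so the published "patch 16" is interpreted as this effective size).
Tokens get a learned positional table and run through pre-norm transformer
layers (multi-head self-attention scaled by `1/√d_h`, GELU MLP), then are
re-gridded and projected back to `4·base` channels.

The decoder upsamples three times (bilinear ×2 + 3×3 conv — checkerboard-safe;
no transposed-convolution path is provided), purifies each skip with a
dual-attention (DA) block — parallel 1×1-conv → PAM → 1×1-conv and
1×1-conv → CAM → 1×1-conv branches, summed — and concatenates and fuses.

**Skip-residue.** At configured levels (default: level 1, the
highest-resolution skip only) the decoder feature at the matching resolution
is purified by its own MIPC block, projected by a 1×1 convolution, and
**added** to the already-DA-purified skip before fusion. Purification first,
then augmentation, matching the stated order of the two strategies. The
alternative wiring (tapping the final decoder output rather than the
per-level feature) is figure-only information in the source; the per-level
tap is the only shape-consistent choice that also gives the per-level
placement ablation its meaning.

**PC baseline.** With `mutual_inclusion = FALSE` the cross-gates are removed:
Part A becomes plain PAM, Part C plain CAM, Part B unchanged. The source
never specifies this baseline's internals; this is the minimal ablation that
removes exactly the mutual inclusion.

**Binary head.** `num_classes = 1` switches to a single-channel logistic
head with binary cross-entropy and foreground soft Dice.

## Loss and metrics

The training loss is `½·CE + ½·(1 − softDice)` with smoothing `ε = 1e−5` in
the Dice numerator and denominator. Soft Dice uses the probability maps and
averages over **all** classes including background (the usual convention for
this loss); evaluation, by contrast, excludes background from per-class
means.

Evaluation semantics, chosen to be brute-force verifiable:

- Dice = `2|T∩P|/(|T|+|P|)`; two empty masks agree perfectly (Dice 1).
- Hausdorff distance is the **full maximum** (not a percentile) over boundary
  pixels — foreground pixels 4-adjacent to background, with image borders
  counting as background — under Euclidean distance with per-axis spacing.
  Slice stacks are treated as one 3-D point set (per-slice boundary
  extraction, slice spacing applied). An empty mask makes HD undefined and
  raises an error; the case evaluator records such classes as missing rather
  than inventing a number. Whether the published evaluation used the full HD
  or HD95, 2-D or 3-D, is unstated; these local definitions are pinned by
  tests, not claimed to match the published evaluator.
- AC/PR/SP come from confusion counts pooled over all pixels and classes
  (one-vs-rest); a zero denominator yields `NA`, excluded from summaries.

## Synthetic phantoms

The generator emulates the geometry that matters for boundary metrics:
each image holds `K−1` non-overlapping star-convex blobs whose radius varies
smoothly with angle — an ellipse modulated by a truncated Fourier series
(harmonics 2–5, amplitude set by `boundary_roughness`) — with one mean
intensity per class plus Gaussian noise, clipped to `[0,1]` and quantised to
the 16-bit grid so disk round trips are pixel-exact. Star-convexity
guarantees closed boundaries, so HD is defined for every class in every
image. Placement resamples on overlap, progressively shrinking sampled radii
(floor 3 px), with a z-order fallback at the retry limit; the defaults
(semi-axes drawn from 0.10–0.20 of the image edge, roughness 0.08, noise
σ 0.04, `K = 4`, 64 px, 8 images) place reliably across seeds.
Per-image RNG substreams are derived by counter from the top-level seed, so
image *i* is independent of `n_images`.

What the phantoms do **not** emulate: texture, intensity inhomogeneity,
partial-volume edges, anatomy-dependent shape priors, class imbalance at
clinical scales, or inter-rater label noise. Passing tests on phantoms
demonstrates that the implementation optimises and evaluates correctly and
that the architecture can fit coherent region structure — not that it would
match published clinical-benchmark numbers, which additionally required
pretrained transformer weights and GPU-scale training, both out of scope.

## Numerical choices

- Reverse-mode autodiff on dense double-precision arrays; convolutions as
  `k²` BLAS products on a channel-last padded copy; every backward rule is
  tested against central finite differences.
- Batch norm: `ε = 1e−5`, running-statistics momentum 0.1; evaluation mode
  uses running statistics. Convolutions feeding a batch norm carry no bias.
- Initialisation: He-scaled normals for convolutions, `1/√fan_in` for linear
  layers, positional table σ = 0.02, all from a single model seed; rebuilding
  with the same configuration is bit-identical.
- Ties in max pooling and channel-max route the gradient to the first
  claimant in scan order, keeping backward passes deterministic.
- Softmax rows are max-shifted before exponentiation.
- Oracle-equivalence tolerances: relative 1e−5 / absolute 1e−6; exact
  equality is asserted only where the arithmetic is exact (integer counts,
  identity limits at zero weights).
- Training: SGD, lr 0.01, momentum 0.9, weight decay 1e−4 applied to all
  parameters, batch size 24 by default (desk-scale runs use 2), no schedule.
  Epoch counts are desk-scale choices; no published epoch count exists.

## Problem sizes

Tests and the acceptance script run at desk scale by choice: 32–64 pixel
images, 4–8 base channels, depth-2 transformers, 2–8 images per set. The
learning check trains the 64-pixel configuration (~125k parameters) on 8
phantoms with batch size 2 and stops at macro-Dice 0.95, which typically
occurs within 30–60 epochs; the published-scale preset (224 px, base 64,
depth 12, embed 768) is constructible through the same configuration object
but is not exercised by the tests.

## Known limitations

- CPU-only, double precision, single-device; no mixed precision, no
  flash/linear attention — spatial attention is the O((H·W)²) textbook form.
- No pretrained-weight loading; all results are from seeded random
  initialisation.
- The four mix variants and the PC baseline are principled reconstructions
  of configurations the source names but does not specify internally; they
  are pinned by structural tests, not by reference outputs.
- 2-D slices only; slice stacks are evaluated, not convolved over.
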