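# mipcnet

Boundary-focused medical-image segmentation in pure R: a U-shaped
encoder–decoder network built around a **mutual inclusion of position and
channel (MIPC) attention block**, with dual-attention-purified skip
connections and a *skip-residue* path that re-injects purified decoder
features into the skip stream. The package is aimed at methods researchers
who want to study this family of attention mechanisms — gating one attention
pathway by a compressed summary of the other — on fully controlled synthetic
data, without a GPU, external datasets or a deep-learning framework: the
network, its layers and a tape-based reverse-mode autodiff engine are
implemented from scratch on top of base R matrix algebra.

## The model

Feature maps are arrays `(batch, channel, row, col)`. The MIPC block combines
three parts computed from one shared input `X`:

- **Part A (position-dominant).** A channel gate
  `g = sigmoid(FC2(ReLU(FC1(GAP(X)))))` (squeeze–excitation style, one value
  per channel) multiplies the output of a position attention module
  `PAM(X) = X + gamma_p * softmax(Q K^T) V`, where `Q, K, V` are 1x1-conv
  projections and the softmax runs over the `(H*W) x (H*W)` spatial affinity:
  `A = g ⊙ PAM(X)`.
- **Part C (channel-dominant).** A spatial gate
  `s = sigmoid(Conv_k([max_c X ; mean_c X]))` (one value per pixel, CBAM-style
  pooling across channels) multiplies a channel attention module
  `CAM(X) = X + gamma_c * softmax(F F^T) F` with `F` the `C x (H*W)`
  channel-descriptor matrix: `C = s ⊙ CAM(X)`.
- **Part B (residual).** `B = Conv(Conv(X) ⊙ Conv(X))` with 3x3 kernels.

The block output is `Residual(A + B + C)` through a basic conv–BN–ReLU
residual tail. In every part the *auxiliary* branch passes through a sigmoid
and gates the *primary* branch; four mix variants permute which branch of
each pair is primary, reproducing the block-internals ablation grid.

The network wraps this block into a hybrid CNN–transformer U-shape: three
convolutional stages halve resolution and double width (`base * {1, 2, 4}`),
a MIPC block purifies the deepest features, patch embedding plus a pre-norm
transformer captures global context, and the decoder fuses three upsampled
stages with skip features that are purified by dual-attention (DA) blocks and
optionally augmented by the skip-residue injection. Training minimises
`L = 1/2 CE + 1/2 (1 - softDice)` with SGD (lr 0.01, momentum 0.9, weight
decay 1e-4). Evaluation reports per-class Dice and boundary Hausdorff
distance plus pooled accuracy / precision / specificity, each verifiable
against brute-force oracles.

## Worked example

```r
library(mipcnet)

# eight 64-pixel 4-class phantoms: smooth star-convex "organs" with
# per-class intensities and Gaussian noise
ds  <- generate_phantoms(phantom_spec(n_images = 8, seed = 1))

cfg <- tiny_config(seed = 2)        # 64 px, base 8, depth-2 transformer
m   <- build_model(cfg)
m
#> <mipc_model: 125,446 params>
#> <model_config 64px K=4 base=8 depth=2 embed=32 enc-mipc mix=pam_cpool.cam_ppool da=TRUE sr={1}>

fit <- train_model(m, ds, run_config(batch_size = 2, epochs = 150, seed = 3),
                   eval_every = 10, stop_dice = 0.95)
rep <- evaluate_model(m, ds)
rep
#> <metrics_report: mean DSC 0.9648 | mean HD 5.605 | AC 0.9956 PR 0.9714 SP 0.9980>
#> # A tibble: 3 × 4
#>   class mean_dsc mean_hd n_cases
#>   <int>    <dbl>   <dbl>   <int>
#> 1     1    0.960   14.4        8
#> 2     2    0.959    1.38       8
#> 3     3    0.975    1.05       8
```

Training stops once the macro Dice over the three foreground classes passes
0.95 (here after about 30 epochs). `mean DSC` averages the per-class overlap
between predicted and true masks (1 is perfect); `mean HD` is the largest
boundary disagreement in pixels, so single-digit values on 64-pixel images
mean the predicted organ outlines sit within a few pixels of the truth.
`tidy()`, `glance()` and `autoplot()` work on fits, metric reports and
phantom datasets.

A command-line pipeline wraps the same functions
(`inst/cli/mipcnet synth|train|eval|ablate`), including the three ablation
grids over the block's variants (mutual inclusion on/off, the four
primary/auxiliary mixes, and six skip-residue placements).

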