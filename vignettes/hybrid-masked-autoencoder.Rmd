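---
title: "A supervised masked autoencoder with a hybrid convolution-transformer encoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A supervised masked autoencoder with a hybrid convolution-transformer encoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridmae)
```

## The problem

Identifying medicinal plants from photographs is hard in exactly the places
where it matters: many classes are *processed variants of the same species*
(the same fruit fried, charred, or lime-treated), so the discriminating cues
are subtle differences in color, surface texture and local morphology rather
than gross shape. Real collections are also imbalanced — some preparations
are photographed far more often than others — so a classifier trained
naively overfits the majority classes.

`hybridmae` implements a pipeline built around three ideas:

1. **Imbalance-aware random local augmentation.** Random square shadows
   (each channel value inside a random region is decreased by a fixed
   intensity and clamped at zero, applied with probability `dark_rate`) and
   random local crops whose window size is modulated by the class
   proportion, plus random rotation/flip.
2. **Masked-autoencoder pre-training with a hybrid encoder.** Images are cut
   into non-overlapping patches; a large fraction is hidden and a
   transformer encoder sees only the visible patches. A light decoder, given
   one shared learnable mask token per hidden position, reconstructs every
   patch's pixels. Transformer blocks are refined by a depthwise
   convolution over the token grid to restore the local detail that global
   self-attention tends to smooth over.
3. **A parallel supervised branch.** During pre-training a classification
   head on the class token is trained *jointly* with the reconstruction,
   so label information regularizes the encoder; the combined objective is
   a reconstruction mean-squared error plus a label-smoothed cross entropy.

## Model

An `h x w x C` image is split into `N = h*w/P^2` patches of side `P`
(row-major order, 0-based indices). A random subset `X_m` of
`round(mask_ratio * N)` patches is masked; the rest `X_v` stay visible, and
the two sets always partition the patch indices (`X_m ∪ X_v = X`,
`X_m ∩ X_v = ∅`). Each visible patch is projected to a `d`-dimensional
token, gets the positional embedding of its *original* grid index, and a
class token is prepended:

```
z = [x_cls, x_p1 E, x_p2 E, ...] + E_pos
```

Each encoder block applies multi-head scaled dot-product attention
(`Softmax(Q K' / sqrt(w)) V` per head, so every attention row sums to 1)
with a pre-norm residual, then a residual two-layer GELU feed-forward
network under an outer layer norm:

```
Z  = z + MHSA(LN(z))
y' = LN(Z + FFN(LN(Z)))
y  = y' + DepthConv(y')     # depthwise refinement, class token bypasses
```

One reading note on the block form: the published block equation writes the
attention output without an explicit residual around the attention itself.
We use the standard pre-norm residual (`z + MHSA(LN(z))`) because without
it a deep stack cannot propagate the identity and masked pre-training does
not train; the residual form is the convention in the vision-transformer
family this model extends, and the rest of the equation (residual FFN under
an outer layer norm) is kept exactly as written.

The depthwise refinement is a per-channel `k x k` convolution (default 3,
stride 1, zero same-padding) over the tokens arranged on their 2-D grid,
added residually. It needs a *full* grid, so during masked pre-training it
acts inside the decoder blocks (where the sequence has been restored to all
`N` positions), and during fine-tuning — when every patch is visible — it
acts inside the encoder blocks. Its kernels are initialized at zero so the
refinement starts as an identity map.

The decoder embeds the encoder output into `decoder_dim` dimensions,
inserts the one shared learnable mask token at every masked index, restores
the original (unshuffled) order, re-adds positional embeddings, runs
`decoder_depth` transformer blocks and predicts `P^2*C` pixels per patch —
for **all** `N` patches, visible ones included. Because a masked position's
embedding is a mixture of the visible tokens through attention, the decoder
interpolates hidden content globally, not just from nearby patches.

The classification head layer-normalizes the class token of the encoder
output and maps it linearly to `n_classes` logits. It runs in parallel with
the decoder on the same encoder output.

### Objective

```
Loss = w_mse * Loss_MSE + w_cls * Loss_LS        (defaults 1, 1)
```

`Loss_MSE` is the mean of squared pixel errors over the selected patches.
The source prints the reconstruction term as the *reciprocal* of the error
sum, which cannot serve as a minimization objective (it would reward bad
reconstructions); we implement the standard mean of squared errors, which
is also what the masked-autoencoder line of work uses. Scope defaults to
`all_patches` (the architecture computes the loss for every patch);
`masked_only` is available as the classic alternative.

`Loss_LS` is the label-smoothed cross entropy with smoothed targets
`y(i) = ε/n` off-target and `1 − ε + ε/n` on target, `ε = 0.25` by default.
The target always sums to 1, and the loss is bounded below by the entropy
of `y` (Gibbs), with equality exactly at `softmax(logits) = y`.

## Augmentation

* **Shadow** (`shadow_config`): defaults `shadow_size = 32`,
  `shadow_intensity = 30`, `dark_rate = 0.3` — the optimum of the published
  parameter sweep. Arithmetic is done in doubles, so the subtraction cannot
  underflow before the clamp at 0.
* **Crop** (`crop_config`): nominal side up to `crop_size` (default 128 at
  224-pixel resolution), modulated by `γ = 1 ± (1 − A) · d/d_max` where `A`
  is the class proportion and `d` the anchor's distance from the image
  center. Two conventions here are ours, because the source states neither:
  the distance enters *normalized* (`d/d_max`, default `d_max = 112`), since
  a raw pixel distance would blow the factor up to hundreds instead of a
  usable scale modulation; and the `+` branch (larger windows) applies to
  classes at or below the median proportion, the `−` branch above, which
  realizes "higher thresholds for fewer classes". Crops are clipped to the
  image and resized bilinearly to the model resolution.
* **Rotation/flip**: a uniform element of {0°, 90°, 180°, 270°} ×
  {identity, horizontal flip}; a pure pixel permutation.
* Order during training is fixed and documented: crop → shadow →
  flip/rotate.
* The budget planner (`plan_augmentation`) emits an exact per-class number
  of augmentation jobs (e.g. 1000 per class for shadows, or a per-class
  census table for crops), sampling sources uniformly with replacement.
  Whether the two published budgets are cumulative is not stated in the
  source; the planner takes whatever per-class targets the caller supplies,
  so either reading is expressible.

## Training

Defaults mirror the published recipe: AdamW (betas 0.9/0.999 — unstated in
the source, standard values; decoupled weight decay 0.05 on projection
matrices only), initial learning rate 1e-3, batch 32, StepLR with gamma 0.1
for pre-training (the step size is unstated; we decay at 50% and 75% of the
run), cosine annealing for fine-tuning, 400/200 epochs nominal, 70/15/15
stratified split. Gradient clipping at global norm 1.0 is on by default; it
stabilizes small-batch CPU runs. Fine-tuning forces the mask ratio to 0,
drops the decoder (whether it should keep training is unstated; dropping it
is the cheaper and standard choice), optimizes the classification term
only, evaluates validation accuracy each epoch and retains the best
parameters. Augmentation applies to the training split in both phases
(also unstated in the source; both-phases is the conservative reading).

The whole stack — forward pass, backward pass, optimizer — is written in
base R matrix algebra, with no deep-learning framework behind it. The
analytic gradients of every layer are validated against central finite
differences in the test suite, and training is bitwise deterministic on CPU
for a fixed seed, including checkpoint resume (checkpoints carry the
optimizer moments and the random-stream state).

### Ablation switches

`model_config` exposes the three architecture toggles so the published
ablation grid is expressible: `use_conv_stem` (two inverted-residual
convolution blocks before patch projection — default **off**, since the
enlarged receptive field leaks masked content into visible patches and
hurts accuracy), `use_depthwise_conv`, and `use_cls_branch`. With all
three off the forward pass reduces to a plain masked autoencoder, which the
tests verify against an independently written reference implementation.
Loading externally pre-trained weights is supported by the checkpoint
format but no weights ship with the package.

## Synthetic data

`fixture_spec`/`generate_dataset` produce the class-structured images all
tests run on: a sinusoidal textured background and a filled ellipse
("fruit") per image, with class identity encoded in base hue and texture
frequency and per-image jitter in blob position, rotation and scale, plus
mild Gaussian pixel noise. Defaults: 6 classes with counts
120/100/80/60/40/30 (imbalanced like a real census), hues evenly spaced on
the color wheel. These images emulate the *statistical* properties that
matter for exercising the pipeline — distinct per-class color/texture,
imbalance, intra-class variation — and nothing else: passing tests show the
machinery is correct and that pre-training helps on separable data; they do
not certify accuracy on photographs of real specimens, where class cues are
far subtler. Mean-hue separation is by construction large enough that a
nearest-centroid classifier on mean color reaches ≥ 90% accuracy, which is
asserted in the tests so that the training targets below are meaningful.

## Problem sizes used by tests and the acceptance script

All training tests use the desk-scale configuration (32×32 images, P = 8,
d = 64, encoder depth 2, 4 heads, decoder 32×2): large enough to show
learning, small enough that the full suite runs in a few minutes on one
CPU. The acceptance script generates the default 430-image fixture set,
pre-trains 10 epochs, fine-tunes 20, and evaluates on the held-out test
split. The three-seed pretrain-vs-scratch comparison uses a 12-image
per-class subset at equal total epochs per arm; it asserts the
*directional* claim that masked pre-training does not hurt and typically
helps — not any published accuracy value, which would require the original
photographs and multi-hundred-epoch GPU schedules.

## Numerical conventions

* Pixels are `[0, 255]` doubles at the augmentation layer (so the shadow
  decrement is an integer subtraction with a clamp) and `[0, 1]` inside the
  model.
* Layer norm uses eps 1e-6; softmax subtracts the row maximum; GELU is the
  exact `x·Φ(x)` form.
* Weights are truncated-normal (sd 0.02); depthwise kernels and the stem
  projection start at zero (identity residuals).
* Bilinear resizing is delegated to `EBImage::resize`; PNG I/O to the `png`
  package.
* Zero-denominator metric cells (a class never predicted, or absent) report
  0 with a warning; one-vs-rest AUC uses the midrank Mann-Whitney statistic,
  which equals trapezoidal ROC integration; a class absent from the truth
  yields `NA`, excluded from the macro average.
* The mask ratio is unstated in the source; we default to 0.75, the
  masked-autoencoder convention it builds on. Positional embeddings are
  learnable.

## Known limitations

* Pure-R training is desk-scale: hundreds of images at 32–64 px, not
  thousands at 224 px. The architecture accepts the full-size configuration,
  but wall-clock time makes it impractical without a compiled backend.
* The synthetic generator does not model lighting, specular highlights,
  backgrounds, or the near-duplicate classes that make the real task hard.
* Published headline accuracies are not reproducible here: they require the
  original dataset and long GPU schedules. What this package reproduces
  exactly is every formula-level quantity checkable from printed inputs,
  and the qualitative behavior of the method at desk scale.
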