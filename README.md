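# hybridmae

A supervised masked autoencoder with a hybrid convolution–transformer
encoder, for classifying medicinal-plant images — written for researchers
who want the full method (imbalance-aware augmentation, masked
pre-training, joint supervised branch, metric suite) as an inspectable,
deterministic R implementation that runs on one CPU.

The hard version of this classification problem is distinguishing
*processed variants of the same species* — the same fruit fried, charred,
or lime-treated — where the cues are subtle color and texture differences
and the class counts are strongly imbalanced.

## Method

An image is split into `N = h·w/P²` non-overlapping patches. During
pre-training a random subset `X_m` (`|X_m| = round(mask_ratio · N)`,
default ratio 0.75) is hidden; the visible patches are embedded with
positional information plus a class token,

```
z = [x_cls, x_p¹E, x_p²E, …] + E_pos
```

and pass through transformer blocks

```
Z  = z + MHSA(LN(z)),   MHSA = Softmax(QKᵀ/√w)V per head
y′ = LN(Z + FFN(LN(Z)))
y  = y′ + DepthConv(y′)      # per-channel k×k conv over the token grid
```

A light decoder inserts one shared learnable mask token at every masked
index, restores the original order, and predicts the pixels of **all** `N`
patches. In parallel, a classification head reads the class token. The
joint objective is

```
Loss = Loss_MSE + Loss_LS
Loss_LS = −Σᵢ y(i) log p(xᵢ),   y(i) = ε/n (i ≠ target), 1 − ε + ε/n (i = target)
```

with ε = 0.25. Fine-tuning disables masking, drops the decoder, and trains
the classification branch under a cosine schedule. Evaluation produces the
confusion matrix, per-class precision / recall / specificity / F1
(`F1 = 2PR/(P+R)`), and one-vs-rest ROC AUC via the midrank statistic.

Augmentation implements random square shadows
(`X(i,j,c) = x(i,j,c) − shadow` inside a random region, clamped at 0,
applied with probability `dark_rate`) and class-proportion-aware random
crops (`γ = 1 ± (1−A)·d/d_max` modulates the window size, so minority
classes get stronger modulation), plus rotation/flip — with a planner that
emits exact per-class augmentation budgets.

Everything — forward pass, hand-derived backward pass, AdamW, schedules —
is base R matrix algebra; gradients are verified against finite differences
in the test suite, and all randomness is seed-deterministic.

## Worked example

A deterministic synthetic dataset (6 classes, imbalanced counts, distinct
hue/texture per class) stands in for real photographs, so the example runs
anywhere in ~1 minute:

```r
library(hybridmae)

data_dir <- file.path(tempdir(), "demo")
spec <- fixture_spec(n_classes = 6, counts_per_class = c(40, 35, 30, 25, 20, 15),
                     image_size = 32, seed = 1)
generate_dataset(spec, data_dir)
splits <- split_dataset(scan_dataset(data_dir), seed = 1)   # 70/15/15, stratified

cfg   <- tiny_model_config(n_classes = 6)    # 32 px, P = 8, d = 64, depth 2
model <- init_model(cfg, seed = 1)
pt <- pretrain(model, splits$train, train_config("pretrain", epochs = 5, seed = 1),
               loss_config(n_classes = 6))
pt$log
#>   epoch loss_mse loss_cls loss_total
#> 1     1   0.1900   1.7024     1.8924
#> 2     2   0.1251   1.4136     1.5388
#> 3     3   0.1090   1.3390     1.4479
#> 4     4   0.1013   1.3278     1.4291
#> 5     5   0.1010   1.3267     1.4277
```

Both loss terms fall as the encoder learns to reconstruct hidden patches
*and* separate the classes. Fine-tuning then reads out the classifier:

```r
ft <- finetune(pt$model, splits$train, splits$val,
               train_config("finetune", epochs = 10, seed = 2))
tail(ft$log[, c("epoch", "loss_cls", "val_acc")], 3)
#>    epoch loss_cls val_acc
#> 8      8   1.0033       1
#> 9      9   0.9854       1
#> 10    10   0.9830       1

report <- evaluate_model(ft$model, splits$test)
round(c(accuracy = report$accuracy, macro_f1 = report$macro[["f1"]],
        macro_auc = report$auc$macro), 3)
#>  accuracy  macro_f1 macro_auc
#>         1         1         1
```

Validation accuracy reaches 100% within a few epochs and the held-out test
split is classified perfectly — expected on these deliberately separable
fixtures (their hues are spread around the color wheel; a mean-color
classifier already reaches ≥ 90%). The classification loss settles near
0.98 rather than 0 because the label-smoothed objective is bounded below by
the entropy of the smoothed target, not by zero.

A command-line wrapper covers the same stages
(`make-fixtures`, `augment`, `pretrain`, `finetune`, `evaluate`):

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/hybridmae.R", package="hybridmae"))')" \
    make-fixtures --out data/ --classes 6 --counts 40,35,30,25,20,15 --size 32 --seed 1
```

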