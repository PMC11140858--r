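Package: hybridmae
Title: Supervised Masked Autoencoder with a Hybrid Convolution-Transformer
    Encoder for Plant Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a supervised masked-autoencoder (MAE) pipeline for
    identifying medicinal-plant images: imbalance-aware random local
    augmentation (random shadow, class-proportion-thresholded random crop,
    rotation and flip), ViT-style patch tokenization with random masking,
    transformer encoder blocks refined by depthwise convolution, a
    reconstruction decoder with a shared learnable mask token, a parallel
    supervised classification head, a combined mean-squared-error plus
    label-smoothing objective, seeded CPU training loops (AdamW, StepLR and
    cosine schedules), and a multiclass evaluation suite (per-class
    precision, recall, specificity, F1, confusion matrix, one-vs-rest
    ROC/AUC). Ships a deterministic synthetic image generator producing
    class-structured, imbalanced datasets so the full pipeline is testable
    without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    EBImage,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
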