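Package: segloss
Title: Loss Functions and Per-Class Evaluation for Multiclass Image Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements a family of segmentation loss functions for multiclass
    medical images -- class-weighted cross entropy, class-averaged IoU (Jaccard)
    and dice losses, a Tversky-style weighted IoU with separate false-positive
    and false-negative penalties (alpha + beta = 2), and no-background variants
    -- in both a hard form on labelmap pairs and a soft differentiable form on
    per-pixel class-probability maps. Provides per-class confusion counting and
    a metric suite (accuracy, sensitivity, specificity, precision, IoU, dice),
    a seeded phantom generator for multi-organ style images with controlled
    class imbalance and perturbed predictions, patient-wise k-fold
    cross-validation with fold statistics (mean, sample sd, 90% CI, pooled
    two-sample t-test), an alpha sensitivity sweep, uniclass problem
    derivation, and a small trainable per-pixel segmenter for exercising the
    losses end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    png,
    yaml,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
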