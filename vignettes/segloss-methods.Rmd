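---
title: "Loss functions for imbalanced multiclass segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Loss functions for imbalanced multiclass segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segloss)
```

## Why per-class metrics, and why a loss family

A segmentation output and its groundtruth are *labelmaps*: images whose
pixels hold class ids rather than intensities, with class 0 the background
by convention. In medical images the background is simultaneously dominant
(often ~95% of pixels) and easy (it is nearly constant across slices and
patients), so any score pooled over all pixels is inflated by it: the
all-background classifier on a 95%-background image scores 95% accuracy
while segmenting nothing. The TN count is similarly enormous, which rules
out specificity, FPR and ROC/AUC as segmentation-quality measures; and
sensitivity alone ignores false positives entirely.

`segloss` therefore computes every metric *per class*, one-vs-rest: for
class $c$, $TP_c$ counts pixels labelled $c$ in both maps, $FN_c$ pixels
labelled $c$ only in the groundtruth, $FP_c$ only in the prediction, and
$TN_c$ the rest, so $TP_c + FP_c + FN_c + TN_c$ equals the pixel count for
every class. The informative per-class measures are the Jaccard index
$JI_c = TP_c/(TP_c+FP_c+FN_c)$, the dice coefficient
$DSC_c = 2TP_c/(2TP_c+FP_c+FN_c) = 2JI_c/(JI_c+1)$, and
precision/recall taken together. Class averages are reported with and
without the background class (noBK).

A training loss must collapse this per-class view back to one number, and
the choices made in that collapse are exactly what the loss family
parameterises:

* `crossE`: mean over pixels of $-w_c \log s_{\text{true}}$, with optional
  inverse-frequency class weights $w_c$;
* `iou`: $1 - \frac{1}{C}\sum_c TP_c/(TP_c + \alpha FP_c + \beta FN_c)$
  with $\alpha+\beta = 2$, $\alpha,\beta \ge 0$ ($\alpha=\beta=1$ is plain
  class-averaged IoU; other settings form a Tversky-style index trading
  false positives against false negatives);
* `dice`: as `iou` with numerator $2TP_c$ and denominator $2TP_c + \alpha
  FP_c + \beta FN_c$;
* every overlap loss has a noBK variant that averages over foreground
  classes only. For `crossE` the same intent is expressed by a zero
  background weight, which keeps the per-pixel probability simplex intact.

## Hard and soft forms

Each overlap loss exists in two forms with one implementation:

* **hard** — the prediction is a labelmap; counts are exact integers from
  the per-class confusion. This is the evaluation form and the oracle in
  tests.
* **soft** — the prediction is an $H \times W \times C$ probability map;
  counts are probability-weighted, $TP_c = \sum s_c t_c$,
  $FP_c = \sum s_c(1-t_c)$, $FN_c = \sum (1-s_c)t_c$. On a one-hot map the
  soft counts coincide with the hard ones exactly, which the test suite
  asserts over a thousand random pairs. The soft form is differentiable;
  analytic gradients are returned on request and verified against central
  finite differences (tolerance 1e-4).

Numerical choices, all deliberate:

* **Smoothing.** A constant `eps` (default 1e-6) is added to numerator and
  denominator of each per-class ratio. A class absent from both maps (or
  from a minibatch) then contributes a ratio of 1 — i.e. zero loss —
  instead of 0/0. The default is small enough that it perturbs any
  non-degenerate ratio by far less than the 1e-6 soft/hard agreement
  tolerance.
* **Undefined metrics.** In *evaluation* (as opposed to loss) a 0/0 metric
  is reported as `NA` and excluded from class averages, numerator and
  denominator alike. Defining 0/0 as 1 (or 0) would silently reward (or
  punish) absent classes in per-class means.
* **Averaging order.** Per-pixel cross-entropy terms are averaged, not
  summed, so loss magnitude is resolution-independent. Within a training
  minibatch, counts are pooled over all images *before* forming per-class
  ratios (micro-averaging), which stabilises the terms of classes with few
  pixels per image.
* **Unboundedness of crossE.** The overlap losses live in $[0,1]$ and
  vanish exactly when the argmax prediction matches the groundtruth.
  Cross entropy is bounded below by 0 but unbounded above for confidently
  wrong predictions; it is not clamped, only its scores are clamped at
  `eps` before the log.
* **Argmax ties** resolve to the earlier class in the class set (so to
  background first), deterministically.

## The phantom generator

No external dataset is required: the generator emulates the *geometry* of
the imbalance problem rather than anatomy. Each phantom is a square image
with `C - 1` elliptical "organs" placed one per grid cell (so they never
overlap), sized to hit a target background fraction (default 0.95, the
canonical imbalance regime), with per-class mean intensities and Gaussian
noise. Defaults: 64 px side, 5 classes, noise SD 0.02, radius/aspect
jitter 0.25. With zero noise the classes are perfectly separable by
intensity, giving an absolute sanity oracle (a threshold classifier
reaches IoU 1). An `exact_bg` option trims or grows organ boundaries pixel
by pixel so the realised background count is exact, which matters only for
illustrations that need an exact ratio, such as the 95%-accuracy trap.

Patient cohorts re-render one per-patient geometry with small per-slice
jitter, so slices within a patient correlate more than slices across
patients — precisely the structure that makes patient-wise (not
slice-wise) cross-validation necessary to avoid leakage.

Perturbations create predictions with *known* error structure for testing
the FP/FN weighting: erosion of a class by a disc (EBImage morphology)
creates only false negatives for that class, dilation only false
positives; boundary and uniform label flips add unstructured noise.
Augmentation samples one affine transform per call (defaults: translation
up to 10 px, rotation up to 10°, shear up to 10 px, scaling up to 10%) and
applies it jointly to image and labelmap; labels are resampled
nearest-neighbour, since any interpolation that invents class ids is
invalid, and uncovered canvas is filled with background.

What the phantoms do *not* emulate: anatomical shape variability, partial
volume effects, intensity non-uniformity, inter-organ contact and contrast
failures. Passing tests on phantoms therefore validates the arithmetic,
the contracts and the qualitative loss behaviours — not clinical
performance on real MRI/CT/EFI data.

## The experimental protocol

* **Folds.** `make_folds` assigns whole patients to `k` folds (default 5,
  the 80%/20% protocol), sizes differing by at most one, deterministic
  under a seed. Train/test disjointness at patient level holds for every
  split by construction and is asserted in tests.
* **Uniclass derivation.** `to_uniclass` relabels every non-target
  foreground class as background, producing the $n$ binary problems of
  the one-network-per-structure alternative.
* **Alpha sweep.** `alpha_sweep` walks $\alpha \in \{0, 0.25, \ldots, 2\}$
  with $\beta = 2-\alpha$ (9 points at the default step) and feeds each
  pair to a caller-supplied evaluation; the $\alpha = 1$ entry is
  bit-identical to the plain IoU condition because the weighted loss at
  $\alpha=\beta=1$ *is* the IoU loss, same code path.
* **Fold statistics.** `fold_stats` reports the arithmetic mean, sample
  (n−1) SD, a symmetric 90% Student-t confidence interval
  $\bar{x} \pm t_{0.95,\,n-1}\, s/\sqrt{n}$, and a two-sided two-sample
  *pooled-variance* t-test against a reference condition's fold values.
  The pooled test was chosen over Welch or paired alternatives because,
  on the bundled reference fold table, it reproduces the independently
  reported p-values at all three comparisons (6.7e-6, 1.5e-4, 0.007);
  a Welch test does not. The reference table's published SD and CI
  columns are *not* reproducible from its fold values by any standard
  formula (the published CIs are asymmetric around the mean), so the
  package asserts only the means and p-values against it.

## The training harness

The harness exists to exercise losses, not architectures. The model is a
per-pixel multinomial-logistic (softmax) segmenter over a fixed feature
bank — a constant, the pixel intensity, box-filtered intensity at radii
1, 2 and 4, and the two normalised pixel coordinates — trained by
stochastic gradient descent with momentum (default momentum 0.9, initial
learning rate 0.005 dropping to 90% every 20 epochs, the schedule used for
full-scale segmentation networks, at a reduced default of 50 epochs). The
gradient reaches the weights analytically through the soft loss and the
softmax Jacobian. This deliberately small, convex-ish model is sufficient
for intensity-separable phantoms (held-out IoU > 0.9 on noiseless
two-class cohorts) and trains any `loss_spec` through one uniform
contract; it is not a stand-in for a deep encoder–decoder and makes no
claim about absolute scores on real data.

Two directional properties are checked end to end, each at 5 seeds with a
median rule to absorb SGD stochasticity (sizes chosen to keep the whole
suite fast: 24–32 px images, 7 patients, 30 epochs):

* on noisy small-foreground phantoms, training with $\beta = 1.5$ yields
  foreground sensitivity at least that of $\beta = 0.5$ — the
  recall/precision trade the FP/FN weights exist for;
* on tiny-foreground (95% background) noisy phantoms, dice noBK yields
  foreground mean IoU at least that of dice with background — the regime
  where the easy background term swamps the class average and the
  all-background collapse becomes attractive.

Both are qualitative analogues of published full-scale findings; no
absolute value is claimed, only the direction.

## Known limitations

* The metric suite and losses are 2D; volumes are handled slice-wise.
* `class_balance_weights` applies to cross entropy only: the overlap
  losses are already class-averaged, so every class contributes $1/C$
  regardless of its pixel count, which is the imbalance correction.
* Labelmap PNG interchange stores the class id as an 8-bit single-channel
  value (ids 0–255); it is integer-exact but carries no colour palette.
* The linear harness cannot learn shape priors; phantoms whose classes
  overlap heavily in intensity bound its achievable IoU well below 1,
  which is why the directional tests compare conditions rather than
  absolute levels.
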