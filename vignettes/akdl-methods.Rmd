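---
title: "AK-DL: model, preprocessing chain and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AK-DL: model, preprocessing chain and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Actinic keratosis (AK) is a common precancerous skin lesion that is easily
confused with benign keratosis (BK) in dermoscopy images; distinguishing
the two currently requires histopathology.  This package implements a
complete desk-scale replica of a screening pipeline for that binary
decision: a deliberately *shallow* convolutional network (AK-DL), the
preprocessing chain it trains on, a classical
histogram-of-oriented-gradients (HOG) baseline with three standard
classifiers, and a common evaluation harness.  Because the underlying
dermoscopy archive (HAM10000, with diagnosis codes `akiec` and `bkl`)
requires an accession download, the package also ships a seeded synthetic
image generator so every stage is exercised end to end without any
external data.

## The AK-DL network

The architecture descends from LeNet-5, widened to color input:

```
64x64x3 -> conv(6 @ 5x5, stride 1, pad 2) -> LeakyReLU(0.01)
        -> maxpool(2x2, stride 2)
        -> conv(16 @ 5x5, stride 1, pad 2) -> LeakyReLU
        -> flatten (16384)
        -> fully connected (120) -> LeakyReLU -> dropout(0.5)
        -> fully connected (2) -> softmax
```

There is exactly one pooling stage, after the first convolution.  The
stride-1, padding-2 arithmetic keeps spatial size, so the intermediate
shapes are 64x64x6, 32x32x6, 32x32x16, and a 16384-long flatten.
Parameter counts per layer are closed forms: (5·5·3+1)·6 = 456 for conv1
and (5·5·6+1)·16 = 2416 for conv2.

Training uses mini-batch SGD with classical momentum:
v ← m·v − lr·(∇L + λw), w ← w + v, with m = 0.9, lr = 1e-4, batch size
10 and L2 weight decay λ = 5e-4 applied to weights only (biases are not
decayed) — the published AK-DL optimizer settings.  The loss is
cross-entropy on the softmax output.  The final partial mini-batch of an
epoch is used, not dropped, so sample counts are reproducible.

Several quantities the original description leaves open are fixed here as
documented defaults rather than guesses hidden in code:

* **Fully connected width** — 120 units, the width of LeNet-5's first
  fully connected layer, from which the architecture is derived.
* **Epochs** — default 30, a conventional budget at which training on the
  package's synthetic task has converged.
* **Loss** — cross-entropy, the standard choice for a softmax head.
* **Initialization** — seeded He-uniform fan-in,
  U(−√(6/fan_in), √(6/fan_in)) per weight with zero biases: the standard
  scheme for ReLU-family activations, which keeps activation variance
  stable through the LeakyReLU stack so the fixed 1e-4 learning rate
  makes progress from the first epochs.  The scheme is a documented
  constant; the seed (`init_seed`) makes building a network a pure
  function of its configuration.

### Numerical choices and determinism

Parameters are stored and trained in IEEE float32, the customary
precision for convolutional networks; initial weights are rounded to
float32 immediately, so a zero learning rate reproduces the initial
weights bit for bit.  Convolutions are evaluated as im2col + GEMM.  One
RNG stream, seeded by `shuffle_seed`, produces per epoch the sample order
and then the uniform variates behind the dropout masks; training is
therefore a pure function of `(init_seed, shuffle_seed, data)`, which the
test suite asserts.  Dropout is inverted (activations are rescaled by
1/(1−p) during training), so inference applies no correction and dropout
is exactly a no-op at prediction time.  Max-pooling ties break toward the
first element in column-major order.  The per-epoch `history` records the
running loss and accuracy of the training-mode forward passes (the usual
convention), not a second evaluation pass over the training set.

## Preprocessing

The chain runs in a fixed order — augment, equalize, convert color,
standardize — matching the narrative order of the original pipeline
(equalization is described as applied to the *amplified* images, and Lab
conversion after enhancement):

1. **Augmentation.**  Each selected image contributes itself plus its
   90° rotation, horizontal flip and vertical flip — exactly 4 samples
   per source.  Including the originals is forced by the published count:
   327 AK sources became 1308 samples, and 1308/327 = 4.  By default only
   the class with the *strictly* smaller count is augmented (the stated
   motivation is the limited number of AK images, and 1308 ≈ 1099
   balances the classes); on balanced data nothing is augmented.
   Derivative identifiers are suffixed and provenance is tracked so
   cross-validation can refuse to train on derivatives of test images.
2. **Histogram equalization**, by default per RGB channel independently.
   The channel policy is not stated in the original description, so it is
   a plan field; `luminance_only` equalizes the BT.601 luma and rescales
   chroma proportionally.  The remapping is the classic min-shifted CDF
   form y = round(255·(CDF(v) − CDF_min)/(N − CDF_min)), which maps a
   uniform-histogram image to itself and leaves constant channels
   untouched.
3. **CIELAB conversion** (D65), via R's reference `convertColor`.
4. **Standardization**: bilinear resize to 64x64 and fixed affine maps to
   [0, 1] — v/255 for RGB, and L/100, (a+128)/255, (b+128)/255 for Lab.

The network trains on the Lab tensor by default; an RGB toggle exists
because the deployed variant of this model consumed raw RGB frames.  Both
paths are first-class (`preprocess_plan(input_space = )`).  Grayscale or
four-channel inputs are rejected, not coerced.

## The HOG baseline

The classical pipeline resizes to 200x200, converts to grayscale
(BT.601 luma, rounded half up for bit-exactness), and computes HOG with
32x32-pixel cells and 2x2-cell blocks.  The published descriptor length,
900, forces the remaining geometry: 200/32 gives 6 whole cells per axis
(floor division; the trailing 8-pixel margin is excluded), a 1-cell block
stride gives 5x5 block positions, and 900 = 5·5·2·2·B forces B = 9
orientation bins — also the descriptor's classic default, unsigned over
0–180°.  Gradients are central differences with edge replication; votes
are magnitude-weighted with linear interpolation between the two nearest
bin centers; blocks are L2-normalized with ε = 1e-6.  An independent
per-pixel reference implementation lives in the test suite and the
optimized descriptor must match it to 1e-6.

HOG is computed on the *original* images by default (the classical
pipeline is described independently of the network's
equalization/Lab chain); a flag routes it through equalization for
comparison studies.  The classifiers are e1071's RBF SVM (cost 1, gamma
1/900, with the standard column scaling), a 100-tree random forest, and
k-nearest neighbours with k = 5 — conventional defaults, overridable, with
an optional seeded cross-validated grid search since the original work
reports that classifier optimization was performed but not what was
searched.  Scores for ROC curves are the signed SVM decision value, the
forest's positive vote fraction, and the positive-neighbour fraction.

## Evaluation

`confusion_counts` treats AK as positive.  The five metrics are the count
formulas Acc = (TN+TP)/N, Sens = TP/(TP+FN), Spec = TN/(TN+FP),
Prec = TP/(TP+FP) and the Matthews correlation coefficient; a zero
denominator yields NaN plus a warning flag rather than a silent 0.  (The
source text calls TP/FP/TN/FN "proportions", but its own MCC formula is a
count formula; counts make both readings consistent.)  ROC curves sweep
the unique score values, grouping ties into single steps, and AUC is the
trapezoidal integral — which the tests require to equal the tie-corrected
Mann–Whitney rank statistic to 1e-10.

Cross-validation defaults to 10 stratified folds.  Stratification is a
documented, switchable choice: the original protocol says only "chosen
randomly", and stratification is the safer convention for an imbalanced
~1308/1099 design.  Augmentation, when enabled, happens *inside* each
fold on training data only; the identifier provenance check makes leakage
of a flipped copy of a test image structurally impossible.  The decision
threshold for confusion metrics is 0.5 on the positive-class probability
(the classical classifiers use their native decision rules).  Wall-clock
training time is logged per fold but never asserted — it is
hardware-dependent.

## The synthetic generator

`generate_dataset` emulates just enough dermoscopy structure to make the
pipeline's claims testable: a skin-toned background with a per-image
global color jitter, an elliptical "lesion" with a soft edge, an oriented
sinusoidal texture, and Gaussian pixel noise (sd 8 on the 8-bit scale),
clipped to [0, 255] and quantized.  The two classes differ only through
the `separation` parameter, in two coupled ways chosen so that both
pipelines can see them:

* **texture frequency** — 2 cycles/image for BK-like images versus
  2 + 8·separation for AK-like ones (±0.5 jitter per image).  At low
  frequency the texture gradient is weaker than the noise floor and HOG
  cells are noise-diffuse; at high frequency the oriented gradient
  dominates, concentrating the orientation histograms.  This is what
  makes the class difference HOG-visible despite per-block
  normalization.
* **patch hue** — the ellipse shifts from a tan tint toward red
  ((+35, −28, −18)·separation on RGB), the color signal the network's
  Lab input sees directly.

At `separation = 0` the class-conditional distributions are *identical*
(the class label only selects a different random substream), so any
held-out AUC near 0.5 certifies the absence of leakage through the
harness.  Each image's parameters come from a substream seeded by
(seed, class, index), so growing a dataset appends images without
re-rolling existing ones.  The generator does not attempt photorealism:
no hair, rulers, gel bubbles, vignetting, or camera response — so a green
test suite certifies the pipeline's mechanics and its separability
ordering, not clinical performance on real dermoscopy data.

## Problem sizes used by the tests and the acceptance script

The headline check trains the network with 10-fold cross-validation on
400 synthetic images (200 per class, separation 1, 30 epochs) — about
100k sample-passes — and expects mean accuracy at least 0.95, with the
HOG+SVM baseline at least 0.90 on the same folds, and chance-level AUC
(0.5 ± 0.1) at separation 0.  These sizes were chosen as the smallest at
which the two pipelines' behaviour is unambiguous; unit tests use
16–64 px images and 2–4 epochs.  The float32 engine makes the full run a
few minutes on one CPU core.

## Known limitations

* Real-data headline numbers (accuracy 0.925, AUC 0.887 on the keratosis
  subset of HAM10000) are not asserted: they require the archive download,
  and unstated choices (fold stratification, augmentation/split order,
  epoch budget, fully connected width) make exact replication
  unverifiable.  The package reproduces the *method*; `load_manifest`
  accepts the archive's metadata layout directly for users who fetch it.
* The network supports exactly one pooling stage and stride-1
  convolutions — the AK-DL design — not a general CNN toolkit.
* `equalize_histogram`'s luminance mode clips chroma after rescaling;
  highly saturated pixels can shift hue slightly.
* k-NN scoring materializes the full test-by-train distance matrix; fine
  at desk scale, not for archives of millions of images.
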