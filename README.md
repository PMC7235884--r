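# akdl

Recognizing **actinic keratosis (AK)** — a common precancerous skin
lesion — against **benign keratosis (BK)** in dermoscopy images, with a
deliberately *shallow* convolutional network and a classical
machine-learning baseline under one evaluation harness.

Skin-lesion classification is usually attacked with large pretrained
CNNs, but keratosis texture is comparatively simple, and a small network
can match or beat deep models on this binary task while training in
minutes on a CPU.  This package provides, as plain R with a compiled
numerical core:

* **AK-DL**, a LeNet-style network — `conv(6@5×5) → LeakyReLU →
  maxpool(2×2) → conv(16@5×5) → LeakyReLU → fc(120) → dropout(0.5) →
  fc(2) → softmax` on 64×64×3 inputs — trained with momentum SGD
  (m = 0.9, lr = 10⁻⁴, batch 10, L2 weight decay 5·10⁻⁴),
* the preprocessing chain it consumes: minority-class augmentation
  (original + 90° rotation + horizontal flip + vertical flip, so 327 AK
  sources become 1308 samples), histogram equalization, sRGB→CIELAB
  conversion, bilinear standardization to the unit interval,
* a **HOG baseline**: 200×200 resize, 32×32-pixel cells, 2×2-cell
  blocks, 9 unsigned orientation bins — a 900-dimensional descriptor —
  classified by an RBF SVM, a random forest, or k-nearest neighbours,
* the evaluation protocol: stratified 10-fold cross-validation with
  accuracy, sensitivity, specificity, precision, the Matthews
  correlation coefficient
  (MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))) and
  trapezoidal ROC/AUC,
* a **seeded synthetic dermoscopy generator** with a single
  class-`separation` dial, so the whole pipeline runs and is tested
  without downloading any archive.

Real data in the HAM10000 metadata dialect (`image_id,dx` with
`akiec`/`bkl` codes) is read directly by `load_manifest()`.

## Worked example

```r
library(akdl)

# 60 synthetic images per class, clearly separated classes
ds <- generate_dataset(synth_config(n_per_class = 60, separation = 1,
                                    seed = 7))
ds
#> <image_set> 120 samples (60 AK, 60 BK), first image 64x64 px

# train AK-DL (preprocessing: equalize -> Lab -> standardize)
model <- akdl(ds, control = train_config(epochs = 30, shuffle_seed = 7))
model
#> AK-DL shallow convolutional network
#>   input 64x64x3 -> conv(6@5x5) -> pool -> conv(16@5x5) -> fc(120) -> dropout(0.50) -> 2 classes
#>   parameters: 1969314; input space: lab
#>   trained 30 epochs; final loss 0.1116, training accuracy 0.983

predict(model, ds[1:2])           # probability rows sum to 1
#>              bk        ak
#> [1,] 0.02004325 0.9799567
#> [2,] 0.08628100 0.9137190

# classical baseline on the same images
f <- hog_features(ds)             # 120 x 900 descriptor matrix
fit <- fit_baseline(f, ds$labels, baseline_spec("svm"))
mean(predict(fit, f) == ds$labels)
#> [1] 1

# the full benchmark: one fold plan, four models, report files
cfg <- run_config(synthetic = synth_config(n_per_class = 60,
                                           separation = 1, seed = 7),
                  output_dir = "bench_out", folds = 5, seed = 7)
res <- run_benchmark(cfg)
res$table[, c("model", "Acc", "MCC", "AUC")]
#>  model   Acc       MCC AUC
#>   akdl 0.975 0.9530041   1
#>    svm 1.000 1.0000000   1
#>     rf 1.000 1.0000000   1
#>    knn 1.000 1.0000000   1
```

The report directory holds `report.csv` (the table above plus wall-clock
training time), `report.json` with per-fold detail, per-model ROC point
files, and the resolved `config.json` from which the run can be
reproduced exactly (metrics are deterministic given the configuration;
only the timing column varies).

At `separation = 0` the two synthetic classes are *identical*
distributions, and held-out AUC drops to chance — a built-in negative
control for leakage anywhere in the harness.

A thin command-line wrapper ships in `inst/cli/akdl.R`
(`benchmark`, `synth`, and single-image `predict` subcommands).

## Scope

Transfer-learning comparators (AlexNet, GoogLeNet, ResNet) are out of
scope — they need pretrained ImageNet weights — but `cross_validate()`
accepts any recipe exposing the same `fit/score/predict` contract, so
external scorers can be benchmarked under the identical fold plan.
Mobile/web serving is likewise out of scope; the `predict` CLI subcommand
replaces it for single images.
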