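# BeakFusion

Species identification of cephalopod beaks from photographs, by fusing
local shallow image descriptors with global deep features.

## Why

Cephalopod beaks resist digestion, so beaks recovered from the stomachs of
whales, dolphins, sharks and seabirds are the standard evidence for which
squid or octopus species a predator ate. Telling four ommastrephid squids
apart from a beak photograph is genuinely hard — inter-species differences
are subtle and within-species variation (growth, sex, pigmentation) is
large. No single representation suffices: texture descriptors, morphology
descriptors and learned convolutional features each capture a different
part of the signal.

`BeakFusion` implements the complete pipeline in R:

* **LBP** — circular, interpolated, uniform local binary patterns.
  Each interior pixel gets a P-bit code, `LBP(x_c, y_c) = Σ_p 2^p S(i_p − i_c)`
  with `S(x) = 1` iff `x ≥ 0`, sampling point *p* at
  `(x_c + R cos(2πp/P), y_c − R sin(2πp/P))`; uniform codes (≤ 2 circular
  transitions) get dedicated bins, everything else one catch-all, so the
  global histogram has `P(P−1)+3` = **59** bins at `R = 1, P = 8`
  (512 × 512 input).
* **HOG** — histograms of oriented gradients from central differences
  `G_x = I(x+1,y) − I(x−1,y)`, `G_y = I(x,y+1) − I(x,y−1)`, magnitude
  `√(G_x² + G_y²)`, 9 unsigned orientation bins per `C × C` cell,
  L2-normalized 2 × 2-cell blocks at 1-cell stride: **8100 / 1764 / 324**
  dimensions at `C = 16 / 32 / 64` on a 256 × 256 input.
* **Deep features** — the pooled penultimate activation of a residual
  CNN. The `reference50` profile is the 50-layer bottleneck network
  (stages 3, 4, 6, 3) with a **2048**-dimensional feature at 224 × 224;
  the `deskSmall` profile is a 5-convolution residual network that trains
  from scratch on one CPU in seconds. Convolutions, batch norm, pooling
  and backpropagation are implemented natively in R (im2col + BLAS);
  training is SGD with momentum (batch 16 and the 1e-3/1e-4 epoch
  schedule by default).
* **Fusion** — vector stacking `y₁ = [x_hog, x_deep]`,
  `y₂ = [x_lbp, x_deep]` (→ 3812 and 2107 dimensions for the
  configurations above).
* **Classification** — one-vs-rest RBF SVM (`C = 10`, standardized
  features, variance-scaled kernel width), via libsvm/e1071.
* **Evaluation** — confusion matrix; per-class and macro accuracy,
  precision, recall, F1.
* **Synthetic data** — a parametric generator of beak-like images
  (class-specific hooked-wedge contours and pigmentation striping at
  controllable shape/texture separation) so every stage is testable
  without any external download.

## Worked example

```r
library(BeakFusion)

imgs <- generateBeakDataset(SynthConfig(nPerClass = 30, imageSide = 128,
                                        views = "upper",
                                        shapeSeparation = 0.5,
                                        textureSeparation = 0.5, seed = 11))
res <- runBeakExperiment(imgs,
                         featureKinds = list("lbp", "hog", "deep",
                                             c("hog", "deep")),
                         lbpSide = 128, hogSide = 128,
                         hogConfig = HOGConfig(cellPx = 16), seed = 5)
round(res$accuracy, 3)
#>      lbp      hog     deep hog+deep
#>    0.625    0.708    0.792    0.792

res$reports[["hog+deep"]]
#> MetricsReport
#>  aggregate: accuracy=0.7917 precision=0.7929 recall=0.7917 f1=0.7902
#>          class accuracy precision recall     f1
#> 1      D_gigas   1.0000    1.0000 1.0000 1.0000
#> 2   E_luminosa   0.5000    0.6000 0.5000 0.5455
#> 3 I_argentinus   0.6667    0.5714 0.6667 0.6154
#> 4  O_bartramii   1.0000    1.0000 1.0000 1.0000
```

This medium-difficulty setting (separations 0.5) shows the intended
ordering: each shallow descriptor alone is weakest, the trained deep
features are stronger, and fusing shallow with deep matches or beats
either part. At the default high separation (0.8) with 50 images per
class the fused pipeline exceeds 95% test accuracy, and at separation 0
it sits at the 25% chance level — both are asserted by the test suite.

A staged command-line interface wraps the same workflow with on-disk
artifacts and config-hash manifests:

```sh
Rscript inst/scripts/beakpipe.R all --workdir run1 --seed 1
Rscript inst/scripts/beakpipe.R evaluate --workdir run1 --seed 1
```

Stages: `synth`, `split`, `augment`, `extract_lbp`, `extract_hog`,
`train_backbone`, `extract_deep`, `fuse`, `train_svm`, `evaluate`. The
`fuse` stage refuses feature tables produced under different
configuration hashes, and augmentation only ever touches training-set
images.

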