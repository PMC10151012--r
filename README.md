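# frunet

Fourier channel attention U-Net (FRUNet) for nuclei and gland
segmentation in biomedical images, implemented natively in R.

Segmenting nuclei and glands in microscopy and histopathology images is
a prerequisite for quantitative pathology, and the informative part of
those images — object edges — lives in the high-frequency band of the
spectrum. FRUNet is a lightweight U-shaped encoder–decoder (3
downsampling stages, 64 channels throughout) whose residual units are
built from **Fourier channel attention (FCA) blocks**: spatial features
`s` from two GELU-activated 3×3 convolutions are moved to the frequency
domain, and per-channel weights

```
w = sigmoid( GAP( ReLU( conv1x1( |DFT2(s)|^γ ) ) ) ),   out = x + w ⊙ s
```

gate the spatial features before an internal skip connection (γ = 0.8
compresses dominant low-frequency magnitudes, raising the relative
high-frequency contribution). Training minimises the sum of pixel-mean
binary cross-entropy and smoothed Dice loss,

```
L = L_BCE + L_DCS,   L_DCS = 1 − (2·Σ y·ŷ + 1) / (Σ y + Σ ŷ + 1)
```

and evaluation reports Dice, mean IoU (foreground + background), recall,
precision and F1. The package is aimed at researchers who want a fully
inspectable, seeded, CPU-scale implementation of the method: every layer
forward **and backward** pass is implemented here (convolution core in
C++), with Adam, a plateau learning-rate schedule (1e-4 → 5e-5), 5-fold
cross-validation, ablation variants (no Fourier transform / no attention
/ single-loss objectives), structural variants with parameter counting,
image/mask IO with augmentation, and a seeded synthetic nuclei/gland
generator so everything runs without external datasets.

## Worked example

Train the width-reduced network on seeded synthetic nuclei and evaluate
on held-out images:

```r
library(frunet)

train <- generateSynthetic(synthConfig("nuclei", nImages = 200, seed = 101))
val   <- generateSynthetic(synthConfig("nuclei", nImages = 24,  seed = 102))
test  <- generateSynthetic(synthConfig("nuclei", nImages = 50,  seed = 103))

model <- buildVariant("base", channels = c(16, 16, 16, 16), seed = 1)
model
#> FRUNet segmentation model
#>   input channels: 1 | levels: 3 | widths: [16,16,16,16]
#>   FCA: fft=TRUE attention=TRUE gamma=0.8
#>   trainable parameters: 83265

run <- trainModel(model, train, val,
                  trainConfig(maxEpochs = 30, seed = 2), verbose = TRUE)
#> epoch   1  train 3.4419  val 3.1741  dice 0.0208  lr 0.0001
#> epoch   2  train 2.5693  val 2.2625  dice 0.1084  lr 0.0001
#> epoch   3  train 1.8020  val 1.5814  dice 0.2640  lr 0.0001
#> ...

rep <- evaluateModel(run$model, test)
rep[rep$id == "mean", "dice"]   # mean over the 50 held-out images
#> [1] 0.9300466
```

The summary row of `rep` holds the five metrics averaged over images
(here Dice 0.930, mean IoU 0.925, recall 0.941, precision 0.920, F1
0.930): the trained network recovers almost all nucleus pixels with few
false positives, while the untrained model scores 0 (it predicts only
background). Parameter counts for the structural comparison:

```r
countParameters(buildVariant("base"))          # 3-level, 64-channel model
countParameters(buildVariant("no_fft"))        # identical: the DFT is parameter-free
countParameters(buildVariant("no_attention"))  # smaller: the 1x1 gates are gone
```

A thin command-line wrapper for shell use lives at
`inst/cli/frunet.R` (`synth`, `train`, `evaluate`, `predict`,
`crossval`, `ablate`, `count-params`).

## Package layout

- `R/fca.R` — FCA block, residual unit, and their backward passes
- `R/model.R` — encoder–decoder assembly, variants, checkpoints
- `R/losses.R`, `R/metrics.R` — objective and evaluation metrics
- `R/data-io.R` — image/mask loading, augmentation, splits
- `R/synthetic.R` — seeded synthetic nuclei/gland generator
- `R/train.R` — Adam loop, LR schedule, cross-validation, ablations
- `src/conv_ops.cpp` — im2col/GEMM convolution core and layer kernels
- `vignettes/frunet-methods.Rmd` — model, assumptions, design decisions
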