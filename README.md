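# fundusseg

Pixel-wise segmentation of diabetic retinopathy lesions — microaneurysms
(MA), hard exudates (EX), soft exudates (SE) and hemorrhages (HE) — in
color fundus photographs, for researchers studying class-imbalanced
biomedical segmentation.

At its core is a feature-fusion U-Net: an encoder-decoder network whose
encoder stages are **multiscale feature-fusion (MSFF)** blocks (a dilated
3×3 entry convolution followed by three channel-splitting steps that retain
⌊C/3⌋ channels through 3×3 kernels and pass the rest on through 5×5
kernels, reassembled by a 1×1 convolution with a residual skip), whose
downsampling is done everywhere by learned 3×3 stride-2 convolutions (no
pooling), and whose decoder stages fuse each skip connection SK with the
upsampled lower-resolution decoder map LD through **contextual channel
attention (CCA)**:

    C_LD = Conv1(RReLU(Conv1_BN(GAP(UP(LD)))))
    C_SK = Conv1(RReLU(Conv1_BN(GAP(SK))))
    gate = RReLU(C_LD ⊕ C_SK)
    F    = Concat(gate ⊗ UP(LD), gate ⊗ SK)

with randomized leaky ReLU activations throughout and He initialization.
Training uses the **Balanced Focal Loss**

    L = Σ_i  w · |y_i − Q_i^γ| · ( −[(1 − y_i) log(1 − Q_i) + y_i log Q_i] )

(γ = 2; w = lesion-pixel fraction of the training masks), which keeps
nearly the full weighted cross-entropy on misclassified pixels while
damping easy ones — at y = 1, Q = 0.9, w = 0.1 it evaluates to 0.002,
about 5× below weighted cross-entropy (0.010), where the standard focal
loss drops 100× (0.0001).

Around the network, the package implements the full tile-based pipeline:
Otsu + largest-component ROI cropping, 3×3 Gaussian denoising, CLAHE on
the LAB L channel, dataset mean/std normalization, paired geometric
augmentation, 256×256/stride-64 sliding-window dicing with background-tile
elimination, and overlap-averaged probability reconstruction (16
overlapping windows per interior pixel). Evaluation reports SEN, IOU and
DICE from pooled pixel confusion counts. A deterministic synthetic fundus
generator produces image/mask pairs with the right statistical structure
(bright field-of-view disc, vessel-like clutter, per-class lesion scales)
so everything is testable without external data. The network, its
backward pass and Adam are implemented in the package itself (R +
RcppArmadillo im2col kernels) and verified against finite differences.

## Worked example

```r
library(fundusseg)

# 8 synthetic hard-exudate images with ground-truth masks
base <- synth_config(image_height = 64, image_width = 64,
                     disc_radius_fraction = 0.5, vessel_count = 2,
                     lesion_class = "EX", lesion_count_range = c(1, 3),
                     lesion_radius_range = c(3, 7), noise_sigma = 3,
                     seed = 42)
ds    <- generate_dataset(8, base, negative_fraction = 0.25)
stats <- compute_dataset_stats(lapply(ds, function(d) d$image))
tiles <- lapply(ds, function(d)
  list(image = normalize_image(d$image, stats)$pixels,
       mask  = d$mask$pixels))

model <- build_ffunet(ffunet_config(depth = 2, base_channels = 9), seed = 1)
model
#> Feature-fusion U-Net: depth 2, base width 9, 1 output map(s), rrelu gate
#>   89,074 parameters

fit <- train_ffunet(model, tiles,
                    train_config(epochs = 200, batch_size = 8,
                                 val_fraction = 0, seed = 7))

xb <- fundusseg:::stack_batch(lapply(tiles, `[[`, "image"))
yb <- fundusseg:::stack_batch(lapply(tiles, `[[`, "mask"))
ev <- evaluate_prediction(ffunet_forward(fit$model, xb), yb)
round(c(sen = ev$sen, iou = ev$iou, dice = ev$dice), 3)
#>   sen   iou  dice
#> 0.913 0.792 0.884
```

The model memorizes the 8 tiles (training DICE ≈ 0.88): the optimization,
loss and architecture plumbing all work end to end. Numbers come from the
run above with the seeds shown; training takes a few minutes on one CPU.
For whole images, `predict_image()` runs crop → denoise → CLAHE →
normalize → dice → per-tile forward → overlap-average and returns a
full-resolution probability map.

A thin command-line interface over these functions is installed at
`inst/cli/fundusseg.R` with subcommands `synth`, `preprocess`, `dice`,
`train`, `predict` and `evaluate`.

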