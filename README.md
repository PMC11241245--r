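# ecsanet

Multi-class classification of breast-tumor histopathology images with an
attention-augmented convolutional network, for researchers who work with
BreakHis-style image collections (magnification → tumor class → PNG) and
want a fully inspectable, end-to-end pipeline in R: stain normalization,
imbalance-aware augmentation, training, a complete evaluation suite, and
Grad-CAM explanations — all runnable on synthetic fixtures with no external
downloads.

## The model

ECSAnet is an EfficientNetV2-S-style backbone refined by a convolutional
block attention module (CBAM) and an enlarged fully connected head. Given a
feature map `F ∈ R^{C×H×W}`, CBAM applies sequential channel and spatial
gating:

    F'  = M_c(F) ⊗ F          M_c = σ(MLP(avgpool F) + MLP(maxpool F)) ∈ R^{C×1×1}
    F'' = M_s(F') ⊗ F'        M_s = σ(conv_{7×7}[avg_c F'; max_c F'])  ∈ R^{1×H×W}

The assembled network is: stem conv (3×3, stride 2) → three Fused-MBConv
stages (expansions 1, 4, 4) → three MBConv+SE stages (expansions 4, 6, 6,
SE ratio 0.25) with stage channels 24, 24, 48, 64, 128, 160, 256 → one CBAM
block (reduction ratio 16, 7×7 spatial kernel) → 1×1 conv to 1280 → global
average pooling → FC(1280→1024) → FC(1024→1024) → FC(1024→8). The stride
product is 32, so a 384×384 input yields a 12×12 final feature map.

Around the model, the package implements:

* **Reinhard stain normalization** in CIELAB (D65): each Lab channel of a
  source image is recentred and rescaled to a reference image's per-channel
  mean and population standard deviation,
  `C' = (C − μ_src)·(σ_ref/σ_src) + μ_ref`.
* **Balanced oversampling**: every class is streamed up to a common target of
  `3 × max_class_count` training images per epoch; classes smaller than the
  largest receive AugMix augmentation (Dirichlet-weighted blends of
  stochastic transformation chains), and every training item receives a
  geometric transform (flips p=0.5, rotation ±45°, translation ≤10%,
  scale 0.8–1.2, shear 0–10°) plus channel standardization
  `(x − μ_c)/σ_c`.
* **Training**: SGD (`w ← w − γ(g + λw)`, decoupled weight decay, optional
  momentum), cross-entropy loss, plateau-based learning-rate reduction
  (×0.1), early stopping, per-epoch history.
* **Evaluation**: per-class precision / sensitivity / specificity / F1,
  macro and support-weighted aggregates, accuracy, multiclass Jaccard,
  one-vs-rest macro ROC-AUC, confusion matrices.
* **Explainability**: Grad-CAM heat maps, by default at the CBAM output.

The network core (convolutions, batch norm, SE, MBConv/Fused-MBConv, CBAM,
backpropagation) is implemented in the package itself (R with
Rcpp/Armadillo im2col convolutions); every layer's backward pass is verified
against finite differences in the test suite.

## Worked example

A desk-scale run on a synthetic three-class fixture task (nucleus density
and stain color differ by class), with a width- and depth-scaled model:

```r
library(ecsanet)

spec <- fixture_spec(
  classes = c("C1", "C2", "C3"), counts = 60, side = 64, seed = 11,
  texture_params = tibble::tibble(
    class = c("C1", "C2", "C3"),
    density_min = c(3, 20, 45), density_max = c(6, 24, 50),
    radius_min = 2, radius_max = 4, ecc_min = 0.1, ecc_max = 0.6,
    cast_r = c(25, 0, -20), cast_g = 0, cast_b = c(-20, 0, 25)))
root <- file.path(tempdir(), "demo")
generate_dataset(spec, root, force = TRUE)

idx  <- stratified_split(index_dataset(root, "40X"), seed = 7)
plan <- plan_balance(idx)
print(plan)
#> Balanced oversampling plan
#>   classes: 3  max class count: 42  target/class: 126  epoch length: 378

arch <- architecture_config(num_classes = 3, width_scale = 0.25,
                            depth_scale = 0.2, input_side = 64L, dropout = 0.1)
arch$pipeline$stain_norm <- FALSE    # class signal here is partly chromatic
sc <- configure_stream(arch, side = 64L, seed = 3)
train_stream <- materialize_balanced_epoch(plan, sc)
val_stream   <- collect_eval_stream(idx, "val", sc)

model <- assemble_ecsanet(arch, seed = 1, class_labels = plan$classes)
model_summary(model)
#>   stage channels: 8, 8, 16, 16, 32, 40, 64, 64, 320
#>   head widths:    320, 1024, 1024, 3
#>   parameters:     1,636,162

run <- train_ecsanet(model, list(train = train_stream, val = val_stream),
                     training_config(lr = 0.01, momentum = 0.9, max_epochs = 10,
                                     scheduler_patience = 10, seed = 5))
glance(run)
#>   epochs best_val_loss best_val_acc final_train_acc final_lr stopped_early
#> 1     10        0.0159            1           0.987     0.01 FALSE

report <- evaluate_model(run$model, collect_eval_stream(idx, "test", sc))
print(report)
#> Metrics report (n = 18)
#>   label    precision sensitivity specificity    f1 support
#> 1 C1             100         100         100   100       6
#> ...
#> accuracy 100.00%  jaccard 100.00%  AUC 100.00%
```

`glance(run)` summarizes the run: the best-validation-loss checkpoint
(retained in `run$model`) classifies the held-out validation set perfectly
(`best_val_acc = 1`), and the test report shows per-class and aggregate
metrics, all at 100% on this deliberately separable task. A Grad-CAM
explanation for any test image is one call away:

```r
x <- eval_item(idx$path[idx$split == "test"][1], sc)
grad_cam(run$model, x)
#> <gradcam_heatmap> class C1 @ layer cbam, 64 x 64, range [0.00, 1.00]
```

A thin command-line interface over the same functions ships in
`inst/cli/ecsanet.R` (subcommands `fixtures`, `prepare`, `normalize`,
`train`, `evaluate`, `explain`).

Attempting the full-scale BreakHis experiment requires the real dataset
(magnification/class/PNG layout) and is a matter of pointing `prepare` and
`train` at its root with `--side 384 --width-scale 1` and the default
training configuration; expect long CPU training times.

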