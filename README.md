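# switchnet

Multi-modal skin lesion classification with cross-modal information
switching, in pure R.

Dermatological imaging produces several co-registered views of the same
lesion — the five VISIA modalities (spots, red marks, UV spots,
porphyrins, brown spots) for disfiguring dermatoses, or clinical +
dermoscopic pairs for melanoma — and part of the diagnostic signal lives
only in the *interaction* between views. `switchnet` implements an
end-to-end classifier built around an **information-switching module
(ISM)**: at every stage *s* of a fully shared 8-stage MBConv/Fused-MBConv
backbone, the *n* modality feature vectors at each spatial location are
treated as a length-*n* token sequence, exchanged by multi-head
self-attention

&nbsp;&nbsp;&nbsp;&nbsp;H = softmax(QKᵀ/√d)·V,

and blended back with the originals through a learnable per-stage weight
α ∈ [0, 1]:

&nbsp;&nbsp;&nbsp;&nbsp;Z⁽ˢ⁾ᵢ = α X⁽ˢ⁾ᵢ + (1 − α) Σⱼ≠ᵢ Y⁽ˢ⁾ⱼ.

A shared 1×1 reduction + global average pooling head concatenates the
modalities, and training minimises class-weighted cross-entropy
L = −Σ wₖ yₖ log Pₖ with SGD and cosine annealing. The package covers the
whole pipeline: dataset manifests and deterministic stratified splitting,
per-modality z-score normalization, synchronized cross-modal
augmentation, the network itself (forward and backward passes are
hand-written vectorized R over BLAS), mAP/precision/recall evaluation,
Grad-CAM heatmaps with lesion contouring, and synthetic multi-modal
fixture generators with ground-truth masks so every claim is testable on
one CPU.

## Worked example

The two-modality synthetic fixture plants one lesion per sample whose
appearance in each modality encodes a binary attribute; the class label
is the XOR of the two attributes, so *neither modality alone* predicts
it — only their combination does:

```r
library(switchnet)

m <- generate_derm7pt_fixture(96, 32, positive_fraction = 0.5,
                              seed = 11, out_dir = "xor-fixture")
#> <switchnet_manifest> 96 samples, 2 modalities, 2 classes
#>   modalities: clinical, dermoscopic
#>   classes: nmsc, mm

fit <- train(m, ablation_config(seed = 1))
fit
#> <switchnet_fit> 40 epochs; best val accuracy 1.000 at epoch 12

ev <- evaluate(fit$model, m, fit$stats, fit$split$test_ids, 32)
glance(ev)
#> # A tibble: 1 × 7
#>     mAP accuracy precision recall    f1 averaging     n
#>   <dbl>    <dbl>     <dbl>  <dbl> <dbl> <chr>     <int>
#> 1     1        1         1      1     1 weighted     14
```

The model reaches perfect held-out accuracy because the interleaved
exchange lets it form interaction features; the same architecture with
the ISM off is additively separable across modalities and caps near 0.75
on this task (`run_ablation()` runs the matched comparison). Grad-CAM
localises the decision evidence on the planted lesion:

```r
s <- load_sample(m, fit$split$test_ids[1])
predict(fit, s)$class_name
#> [1] "nmsc"
cam <- grad_cam(fit, s, target_class = s$label, stage = 3)
sapply(1:2, function(j) cam_roi_overlap(cam$heatmaps[[j]], s$masks[[j]]))
#> [1] 0.439 0.440
render_overlay(s, cam, "overlays")   # original / heatmap+contours / mask panels
autoplot(cam)                        # heatmap facets per modality
```

`tidy()`, `glance()` and `autoplot()` methods exist for splits, fits,
evaluation reports, ablation results and heatmaps; a thin command-line
wrapper with `generate` / `split` / `fit-stats` / `train` / `evaluate` /
`explain` / `ablate` verbs ships in `inst/cli/switchnet`.

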