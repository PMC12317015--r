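# dualgland

Dual-generator adversarial augmentation for multi-channel fluorescence
cell images.

Protein subcellular localization datasets — images with a protein-of-interest
channel plus nuclear, microtubule and ER reference stains, each image tagged
with one or more of 19 localization classes — are severely imbalanced: the
most common pattern (nucleoplasm) outnumbers the rarest (mitotic spindle) by
about 21:1, and high-resolution acquisitions suffer missing-pixel artifacts.
`dualgland` implements a biologically motivated generative-augmentation
framework for this setting, together with the full evaluation stack needed to
judge whether synthetic images help, and a seeded simulator so everything
runs end-to-end on a laptop CPU with no external data.

## The model

Two specialized generators share one discriminator. The adversarial value
function is

```
L_GAN = E[log D(x)] + E[log(1 - D(G_SG(z)))] + E[log(1 - D(G_PG(z)))]
```

and each generator adds its own reconstruction loss:

* **SG loss** (secretory-pattern recovery) — a multi-scale Gaussian-pyramid
  mismatch with Laplacian smoothness regularization,
  `sum_s w_s [ MSE(F_s(x), F_s(G(z))) + lambda_grad * mean((lap F_s(G(z)))^2) ]`
  with scale weights `w = [0.6, 0.3, 0.1]` (finest scale first) and
  `lambda_grad = 0.1`, plus an optional neighbour-difference continuity term.
* **PG loss** (structural homeostasis) — a compartment-aware adaptive
  smoothness `sum_{i, j in N(i)} alpha_ij (G(z)_j - G(z)_i)^2` with
  `alpha_ij = exp(-beta ||f_i - f_j||^2) * C_compartment * exp(-t / tau)`
  (`beta = 2`, `tau = 5`; the compartment factor is 1.0 within an organelle,
  0.5 between adjacent organelles, 0.1 otherwise), plus a homeostatic
  penalty `sum_k (mean(O_k) - mu_k)^2` keeping organelle mean intensities at
  their references.

Explicit biological constraints penalize implausible outputs: organelle
volume fractions (nucleus 15–20 %, mitochondria 10–15 %, ER 8–12 %),
minimum-spanning-tree connectivity of organelle components, and cell aspect
ratio (1.2–2.5). The two generator outputs are fused by
temperature-scaled confidence weights
`gamma_SG = e^{C_SG/T} S_secretion / (e^{C_SG/T} S_secretion + e^{C_PG/T} S_structure)`,
and a proportional–integral controller adapts the loss weights
`lambda_SG in [0.3, 1.2]`, `lambda_PG in [0.2, 0.9]` from convergence-rate
EWMAs, with at most 0.15 change per epoch.

The evaluation stack covers FID, Inception Score, SSIM/PSNR, MS-SSIM
diversity, k-NN generative precision/recall, the combined quality–diversity
scoring (weights 0.4/0.35/0.25 and 0.6/0.4, geometric mean, min–max
normalization over the compared architectures), and multi-label
classification metrics with per-class threshold optimization.

## Worked example

```r
library(dualgland)

# simulate a small labelled dataset (4-channel scenes, 19 classes)
scenes <- generate_scene_set(300, 32, 32, seed = 11)
sc <- scenes[[1]]
volume_fractions(sc$organelle_labels, sc$cell_mask)
#>      nucleus mitochondria           er        other
#>        0.174        0.125        0.101        0.029

# train the dual-generator GAN for a few epochs
fit <- dg_train(scenes, net = net_spec(image_size = 32L),
                cfg = train_config(max_epochs = 5, seed = 42))
glance(fit)
#> # A tibble: 1 x 8
#>   epochs best_epoch d_loss loss_sg loss_pg lambda_sg lambda_pg val_loss
#> 1      5          1 0.0195    9.43    9.57      0.75       0.5       20

# fused samples and the evaluation panel
samples <- dg_sample(fit, 48, seed = 1)
report <- evaluate_generators(lapply(scenes[1:100], function(s) s$image),
                              list(dual_gland = samples))
report[, c("architecture", "fid", "is_mean", "msssim_diversity")]
#>   architecture   fid is_mean msssim_diversity
#> 1   dual_gland  55.4    1.00            0.735
```

The training log (`tidy(fit)`) tracks discriminator and generator losses,
the adaptive weights, fusion weights and plausibility metrics per epoch;
`autoplot(fit)` plots the trajectories. A low `d_loss` with high generator
losses, as above, is the expected signature of a small fully-connected GAN
after a handful of epochs — the framework, not sample realism, is the point
at this scale.

The published benchmark summary tables ship with the package and their
derived columns can be recomputed:

```r
tab <- reference_table("quality_diversity")
round(combined_score(tab$quality, tab$diversity), 3)[1:2]
#> [1] 0.903 0.454   # combined scores: dual-gland vs traditional GAN
```

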