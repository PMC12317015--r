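---
title: "Dual-generator augmentation of fluorescence cell images: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-generator augmentation of fluorescence cell images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualgland)
```

## The problem

Protein subcellular localization imaging produces 4-channel fluorescence
images — the protein of interest plus nuclear, microtubule and endoplasmic
reticulum (ER) reference stains — annotated with one or more of 19
localization classes. Two properties make classifier training on such data
hard: severe class imbalance (the most common class is roughly 21 times more
frequent than the rarest) and acquisition artifacts, notably missing pixels
from photobleaching. Generative augmentation can re-balance the classes,
but generic GANs tend to either blur subcellular detail or produce
biologically impossible cells. `dualgland` addresses both failure modes
with two specialized generators and explicit biological plausibility
constraints.

## The dual-generator model

A single discriminator $D$ is trained against two generators through the
value function

$$L_{GAN} = \mathbb{E}[\log D(x)]
  + \mathbb{E}[\log(1 - D(G_{SG}(z)))]
  + \mathbb{E}[\log(1 - D(G_{PG}(z)))],$$

so neither generator can dominate the shared adversarial signal. Generator
updates use the non-saturating form $-\mathbb{E}[\log D(G(z))]$, the
standard choice for stable early training; the discriminator loss follows
the value function exactly. Each generator carries a reconstruction loss
tailored to one aspect of cellular organization.

### Secretory-pattern (SG) loss

Secretory cells organize protein at several spatial scales at once — single
granules, granule clusters, whole-cell polarity. The SG loss compares real
and generated images over a Gaussian pyramid $F_s$ (5×5 kernel,
$\sigma = 1$, reflective padding, decimation by 2):

$$L_{SG} = \sum_s w_s \left[ \mathrm{MSE}(F_s(x), F_s(G_{SG}(z)))
  + \lambda_{grad}\, \overline{(\nabla^2 F_s(G_{SG}(z)))^2} \right]
  + \lambda_{cont} L_{cont}.$$

Defaults: $S = 3$ scales, weights $w = (0.6, 0.3, 0.1)$ finest first,
$\lambda_{grad} = 0.1$, $\lambda_{cont} = 0$. Two candidate weightings
exist in the source configuration — $(0.6, 0.3, 0.1)$ and
$(0.2, 0.3, 0.5)$ — and the ablation grid (`preset_config("scale_grid")`)
identifies the former as optimal, so it is the default. The printed
gradient term is a map, not a scalar; it is reduced to the mean squared
Laplacian of the *generated* pyramid levels, which is nonnegative,
differentiable, and resolution-independent. The per-scale distance is the
per-pixel *mean* squared error (a sum would only rescale
$\lambda_{grad}$ with resolution). The optional continuity term
$L_{cont}$ is the mean squared mismatch of 4-neighbour differences,
invariant to global intensity offsets. The pyramid is a deliberate
analytic default — deterministic and weight-free — and `sg_config(features =)`
accepts any learned feature extractor with the same signature.

### Homeostatic (PG) loss

Endocrine cells maintain structural organization while intensities
fluctuate. The PG loss penalizes intensity differences between neighbouring
pixels with an adaptive weight that respects compartment boundaries:

$$\alpha_{ij} = \exp(-\beta \|f_i - f_j\|^2)\; C_{compartment}(i,j)\;
  e^{-t/\tau},$$

with $\beta = 2$, $\tau = 5$, an 8-pixel Moore neighbourhood, and
$C = 1.0$ within an organelle, $0.5$ between organelles whose masks touch
after 1-pixel dilation, $0.1$ otherwise. Smoothing is therefore strong
inside organelles and weak across boundaries — it never blurs structure
away. Three decisions were genuinely open:

* **Per-pixel features $f_i$.** A global patch embedding cannot provide
  per-pixel vectors, so the default descriptor is analytic: per channel,
  the value, 3×3 local mean, and 3×3 local standard deviation (scaled to
  $[0,1]$). A dense learned feature map can be substituted.
* **The meaning of $t$.** If $t$ were the raw epoch counter, $e^{-t/5}$
  would extinguish the smoothness term by epoch ~25. Here $t$ counts
  epochs since the last constraint-monitor trigger and resets on
  violation, which preserves the intended transient-response behaviour:
  pressure is strong right after a violation and relaxes back to baseline.
* **Homeostatic means.** The homeostatic term
  $H = \sum_k (\mathrm{mean}(O_k) - \mu_k)^2$ needs a scalar mean per
  organelle in a 4-channel image; the mean over all channels within the
  mask is used. The reference intensities $\mu_k$ (nucleus 0.60,
  mitochondria 0.45, ER 0.30) are package defaults, not published values,
  and are user-overridable via `organelle_reference()`;
  $\lambda_{homeostasis}$ defaults to 1.

An organelle-weighted structural variant (`organelle_structural_loss()`)
scores interior texture (mean squared gradient magnitude) plus a hinge on
under-defined boundaries; its per-organelle weights and regularizer default
to the main PG pathway's behaviour.

### Fusion and biological constraints

The fused output is $\gamma_{SG} G_{SG}(z) + \gamma_{PG} G_{PG}(z)$ with a
temperature-scaled softmax over confidence×state products
(`fusion_weights()`, temperature 2.0). The published weighting has no
temperature in its formula but names a fusion-temperature hyperparameter;
placing $C/T$ inside the exponential recovers the plain formula at
$T = 1$. The confidences are mean discriminator realness scores of each
generator's recent batches; the state measures are the mean Sobel gradient
of the protein channel (secretion) and the variance of boundary gradient
magnitudes (structure). When both state measures vanish the weights fall
back to a plain confidence softmax. $\gamma$ is a scalar pair per sample;
spatially varying fusion is out of scope.

The biological loss adds hinge-squared penalties outside physiological
ranges — organelle volume fractions (nucleus 15–20 %, mitochondria
10–15 %, ER 8–12 % of the cell footprint), cell aspect ratio from second
central moments (1.2–2.5) — and a connectivity penalty comparing
minimum-spanning-tree topologies of organelle component graphs between the
generated and reference scene (greedy centroid matching, normalized
symmetric MST edge-set difference, bounded in $[0,1]$). Hinge-squared was
chosen because only the intervals are specified: it is smooth, zero on the
feasible set, and quadratic outside. The three component weights default
to 1 each (no published values).

### The adaptive controller

Convergence rates are tracked per generator as EWMAs of relative loss
change, $r \leftarrow 0.9 r + 0.1 |L_t - L_{t-1}| / L_{t-1}$. When the two
rates diverge by more than 0.3, a proportional–integral update rescales
each weight by $1 + \alpha_p\,e + \alpha_i \sum e$ with
$e = 0.02 - r$ ($\alpha_p = 0.05$, $\alpha_i = 0.01$): slow convergence
yields a positive error and a weight increase. Changes are clipped to 0.15
per epoch and the results clamped to $\lambda_{SG} \in [0.3, 1.2]$,
$\lambda_{PG} \in [0.2, 0.9]$ — in that order (proposal, step clip, bound
clamp). The divergence condition is an absolute-difference reading of the
published trigger description, whose printed inequality is fragmentary.
The integral error is not reset when the trigger deactivates; a simpler
proportional-only mode (`controller_mode = "p"`) implements the
alternative published rule. A constraint monitor evaluates boundary
definition ($x/(1+x)$-mapped mean Sobel magnitude at label boundaries),
coherence (rescaled Moran's I of the protein channel, neutral 0.5 for
constant images) and plausibility ($1-$ clamped volume+morphology penalty)
every 10 epochs, with strict thresholds 0.85 / 0.80 / 0.75.

## The synthetic-scene simulator

`generate_scene()` renders one cell per scene: an elliptical footprint at
the target aspect ratio (default 1.8), an elliptical nucleus, mitochondria
as Gaussian-bump blob clusters, an ER network grown around random walks
from the nuclear envelope, microtubule rays from a centrosome, and a
protein channel painted by class family (nuclear, cytosolic, organellar,
punctate, negative — 19 bespoke painters would add nothing the losses can
distinguish). Organelle pixels are chosen by exact top-$k$ selection on
shape potentials, so achieved volume fractions equal their targets to one
pixel; defaults (nucleus 0.175, mitochondria 0.125, ER 0.10) sit at the
midpoints of the constraint ranges. Class labels are drawn from the
shipped 19-class frequency table (multi-label percentages renormalized to
sampling probabilities); each scene carries a single consistent label —
the weak image-level supervision of real datasets, where not every cell
expresses every image label, is deliberately not modelled. Additive
Gaussian noise (sd 0.02) is clipped to $[0,1]$; missing pixels are zeroed
across all channels (matching the photobleaching description) rather than
set to NA. What the simulator does *not* emulate: real texture and optics
(PSF, shot noise), multiple cells per field, cell-type morphology
variation, and annotation noise — so green tests demonstrate correctness
of the machinery, not realism transfer.

## Training at desk scale

The reference configuration this package documents and tests is
deliberately small: 64-dimensional latents, one 128-unit hidden layer per
network, 32×32 scenes, batch 16, Adam(0.5, 0.999) at learning rates
2e-4/1e-4 with cosine warm restarts every 40 epochs, gradient-norm
clipping at 1.0, dropout 0.3 on the discriminator, L2 1e-5, early stopping
with patience 10 and minimum delta 1e-4, Xavier-uniform initialization.
Networks are fully connected: no published layer-level architecture
exists, the architecture is explicitly not a fidelity target, and dense
stacks keep the hand-written backpropagation exact and fast on one CPU.
The SG/PG reconstruction gradients are analytic — the pyramid and
Laplacian are materialized once per image size as sparse operators and
differentiated by transposition; the PG adaptive weights are treated as
constants of the current iterate (a standard stop-gradient). The
biological penalty is computed on thresholded masks and is therefore
non-differentiable; it enters each generator objective as a value (for
logging and the controller) with zero gradient, estimated on one sample
per batch. The two generators draw independent latent batches per step.
Test and acceptance runs use 300 scenes at 32×32 for 5 epochs — enough to
exercise every component end-to-end in about a minute.

## Evaluation stack

FID uses the Gaussian Fréchet distance with the covariance square root by
symmetric eigendecomposition and a $10^{-6}$ jitter, computed on raw
embedder features (the conventional scale); the k-NN generative
precision/recall (k = 3, radius to the k-th neighbour) uses features
standardized by the real set's statistics with a 0.01 sd floor so no
near-constant feature dominates. The default embedder is analytic (8×8
block means plus 16-bin histograms per channel); a learned embedder plugs
in anywhere. Inception Score uses natural logarithms and a
localization-family posterior by default. The published SSIM formula is
algebraically inverted relative to the standard index — only the standard
form satisfies $\mathrm{SSIM}(x,x)=1$, so that is implemented (population
moments, non-overlapping 8×8 tiles). PSNR uses base-10 logarithms.
MS-SSIM diversity is the mean pairwise 3-scale SSIM geometric mean over up
to 100 samples (seeded subsample beyond). Quality/diversity/combined
scoring uses the published weights (0.4/0.35/0.25; 0.6/0.4; geometric
mean) after cohort min–max normalization — scores are therefore
cohort-relative, and a constant metric column maps to 0.5. The
quality-diversity weights are taken as given; the expert-ranking
correlation that motivated them is not reproducible.

## Numerical choices and degenerate inputs

Reflection is the boundary rule everywhere (blur, Laplacian, patches,
augmentation resampling). Coordinates are 0-based `(row, col)` with
half-open patch windows. Probabilities entering logarithms are clamped to
$[10^{-7}, 1-10^{-7}]$. Degenerate cases are defined, not errors, wherever
a downstream consumer exists: zero-variance Moran's I reports the neutral
coherence 0.5; zero-denominator classification metrics return 0 with an
explicit flag; an all-zero state-measure pair falls back to the confidence
softmax; collinear masks report an infinite aspect ratio (penalized at a
fixed finite value); empty organelle masks contribute nothing. MST
tie-breaks are deterministic by node order (components are numbered by
their topmost-leftmost pixel).

## Tabular results and package shape

Image operations take and return plain numeric arrays; everything tabular
— training logs, evaluation reports, classification summaries, ablation
tables — is a tibble, with `tidy()`, `glance()` and `autoplot()` methods
on fitted GANs and evaluation reports. The published benchmark summary
tables ship as CSV under `inst/extdata` and their derived columns
(combined scores, relative improvements, improvement ratios, robustness
scores) are recomputed by the same exported functions, at the tables'
printed precision. One printed robustness score differs from its
recomputation by 0.001 at three decimals; the recomputed value is reported.

## Known limitations

Sample realism at desk scale is not a goal: after a few epochs the tiny
dense GAN produces blurry composites, the discriminator wins, and k-NN
precision/recall against real scenes is near zero — the tests assert the
machinery (finite losses, bounded weights, normalized fusion, valid
sample ranges), not image quality. The organelle-mask inference for raw
generated images is a simple channel-threshold heuristic. The toy
classification experiment uses embedder features and a small dense
network; its before/after numbers demonstrate the pipeline and are noisy
at n = 150. Real-data ingestion is limited to the package's own
TIFF+JSON scene format; connecting public localization datasets requires
mapping them into `cell_scene` objects first.
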