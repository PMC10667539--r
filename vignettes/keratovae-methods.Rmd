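---
title: "Methods: VAE-augmented deep-learning screening of keratoconus from corneal topography maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VAE-augmented keratoconus screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(keratovae)
```

## The problem

Keratoconus (KCN) is a progressive corneal ectasia that steepens the cornea
and degrades vision; screening candidates for refractive surgery relies
heavily on color-coded corneal topography maps. Normal corneas with regular
astigmatism show a symmetric "bowtie" on the axial curvature map, while
keratoconic corneas show an inferior steep cone, a central cone, or an
asymmetric bowtie with a skewed radial axis (AB/SRAX). Deep convolutional
networks can learn these patterns directly from the color maps, but clinical
image collections are small; one remedy is to train a variational
autoencoder (VAE) on the available maps and expand the training set with
decoded (synthesized) images before fitting the classifiers.

`keratovae` implements that whole pipeline as tested, data-free code: a
parametric simulator of topography maps stands in for the (unavailable)
clinical images, so every stage — preprocessing, VAE training, latent-space
augmentation, classifier training, and clinical evaluation — runs and is
verified end to end on synthetic cohorts.

## The map simulator

Real axial maps are emulated by a minimal parametric curvature field over
the unit disc (pixel coordinates: x rightward, y downward, so "inferior"
means larger y):

$$K(r, \theta) = \bar K + \frac{C}{2}\cos 2(\theta - \alpha)
  + A\, e^{-d^2 / 2w^2},$$

where $\bar K$ is the average keratometry (D), $C$ the cylinder (D) with
axis $\alpha$, and the Gaussian term is a cone of amplitude $A$ (D), width
$w$ (fractions of the disc radius), centered at a point $d$ away from the
cone center. The AB/SRAX pattern adds a second, half-amplitude lobe on the
opposite side rotated by the skew angle. This is not a physical Placido-ring
model; it is the simplest field that reproduces the four named clinical
patterns with controllable indices.

Cohorts draw $\bar K$ and $C$ from per-class truncated Gaussians matching
reference clinical cohorts — keratoconus $\bar K$ 48.68 ± 3.96 D, $C$
4.64 ± 2.53 D; normal $\bar K$ 44.15 ± 1.57 D, $C$ 1.61 ± 1.48 D — so the
class distributions genuinely overlap, as they do clinically. Keratoconic
patterns come from a configurable mixture (default 0.6 inferior cone, 0.2
central cone, 0.2 AB/SRAX; the inferior cone is the most common clinical
presentation). Cone amplitude defaults to a truncated N(6, 2) D on
[1, 15] D and cone width to U(0.15, 0.3) of the radius — values chosen once
to give clearly visible but not caricatured cones.

Rendering maps the field through a discrete dioptric color scale (default
26 bins over 34–52 D, blue to red) onto a landscape canvas (380 x 300 px,
cornea radius 0.45 x min-side). Pseudo-text annotation blocks are scattered
in the margins — outside both a 1.1 x radius ring and the disc's square
crop region, so the ground-truth crop is annotation-free by construction
(a square crop's corners reach 1.41 x radius, so the ring alone cannot
guarantee clean crops; the crop-region exclusion closes that gap).
Structured acquisition noise is modeled as periodic scan lines plus
salt-and-pepper impulses, both removable by the preprocessing chain.

What the simulator does *not* emulate: Placido-ring optics and
reconstruction artifacts, eyelid/eyelash shadowing, device-specific
palettes and layout, elevation/pachymetry maps, and subclinical
keratoconus. Passing tests therefore demonstrate that the pipeline's
mechanics and statistics are correct, not that the clinical accuracies of
any particular device would be reproduced.

## Preprocessing

1. **Denoising**: a 3 x 3 median filter per channel removes impulses and
   thin scan lines; residual periodic artifacts are removed by a spectral
   notch that zeroes isolated spikes on the frequency axes (a spike must
   exceed 8 x the median of its local axis neighborhood — clean maps have
   smoothly decaying axis spectra, so the operation is near-identity on
   them and near-idempotent in general).
2. **Segmentation**: an HSV mask (saturation >= 0.25 and value >= 0.2 by
   default — map colors are saturated, backgrounds and annotations are
   near-gray or near-black) followed by largest-connected-component
   selection and a square crop of its bounding box.
3. **Order-preserving grayscale**: standard luminance conversion scrambles
   the dioptric order of the palette, so each pixel is snapped to its
   nearest scale color (Euclidean RGB) and mapped to `bin / (n_bins - 1)`,
   which is provably monotone in dioptric power. Downsampling uses exact
   area averaging (stable for piecewise-constant band maps); upsampling is
   bilinear.
4. **Model inputs**: the VAE consumes 104 x 104 x 1 grayscale in [0, 1];
   the custom CNN 50 x 50 x 3 color in [0, 1]; transfer backbones get their
   declared side (224 or 160) rescaled to [-1, 1].

## The VAE

Encoder: three 3 x 3 stride-2 "same"-padded convolutions with 64, 32, 16
filters (104 → 52 → 26 → 13, so the flatten width is 13·13·16 = 2704), a
128-unit dense layer, and two linear heads giving the posterior mean and
log standard deviation of $q(z\mid x)$. The latent space is
one-dimensional by default — the two heads emit one scalar each — with
`latent_dim` configurable. Decoder: dense 2704, reshape to 13 x 13 x 16,
three stride-2 transposed convolutions (16, 32, 64 filters), and a 1 x 1
convolution to the single output channel (the output kernel size is not
dictated by the architecture; 1 x 1 is the cheapest choice that closes the
shape chain), with a sigmoid applied in the loss.

The objective is the negated evidence lower bound
$$\mathcal{L} = \underbrace{-\textstyle\sum_{\text{pixels}}
  \big[x \log y + (1-x)\log(1-y)\big]}_{\text{reconstruction NLL}}
  + \underbrace{-\tfrac12\big(1 + \log\sigma^2 - \mu^2 -
  \sigma^2\big)}_{\mathrm{KL}\,[q(z|x)\,\|\,N(0,1)]},$$
with the per-pixel Bernoulli likelihood chosen because inputs live in
[0, 1] (`recon = "mse"` is available). Sampling uses the
reparameterization $z = \mu + \sigma\varepsilon$; the $\sigma$ head is
parameterized as $\log\sigma$ so positivity is structural. The KL closed
form is verified against numerical integration of
$\int q \log(q/p)$ to 1e-6 in the tests.

Training: RMSprop (decay 0.9), learning rate 1e-4, 50 epochs, batch size
32 (the batch size is not specified by the protocol; 32 is the
conventional default), with random horizontal flips and rotations up to
10% of a full turn (±36°). All passes — including the convolutions — are
implemented as BLAS matrix products inside the package (the environment has
no deep-learning runtime, and the model is the package's core contribution);
backpropagation is validated against finite differences to ~1e-10 relative
error in the test suite.

Augmentation proceeds in two ways:

* **Latent-grid decoding** sweeps evenly spaced $(\mu, \sigma)$ values
  (default $\mu \in [-3, 3]$, $\sigma \in [0.1, 2]$ — ranges exist in the
  protocol but their values are unstated; these cover the bulk of the
  aggregated posterior), draws one $\varepsilon$ per cell, and decodes
  $z = \mu + \sigma\varepsilon$; a 30 x 30 grid yields 900 novel images.
* **Class-conditional expansion** (`synthesize_to_target()`) encodes
  randomly chosen class originals, samples from their posteriors, decodes,
  and labels each output with its source's class until every class reaches
  the target (2000 per class at full scale, i.e. 4000 images total from a
  978 + 780 cohort). Posterior-conditioned sampling is the minimal rule
  consistent with training one unconditional VAE on both classes yet
  labelling the expanded set.

## Classifiers

* **Custom CNN**: 50 x 50 x 3 input; three 3 x 3 stride-2 convolutions with
  64, 32, 16 filters (50 → 25 → 13 → 7; flatten 784); two fully connected
  layers (128 and 64 units — widths are a free choice, configurable) with a
  0.25 dropout between them; a single sigmoid output neuron (keratoconus =
  1). Binary cross-entropy, RMSprop at 1e-4, fivefold cross-validation with
  seeded shuffling, 15 epochs per fold.
* **Transfer recipe**: a pluggable backbone (declared input side, spatial
  feature map out) behind an augmentation layer (flip + 20% rotation) and
  the [-1, 1] rescale, topped by global average pooling, dense 512, dropout
  0.2 and the sigmoid neuron. Phase 1 trains the head for 15 epochs with
  Adam at 1e-4 while the backbone stays bit-frozen; phase 2 unfreezes the
  top `finetune_unfrozen_layers` (default 3) backbone layers for 10 more
  epochs. Pretrained ImageNet backbones are external assets; the package
  ships a stub backbone so the recipe's mechanics (freezing, unfreezing,
  shapes) are fully testable offline.

Splits are stratified 80/20 with 10% of the training portion held out for
validation, and the test partition is restricted to original
(non-synthesized) images, so evaluation never sees decoder output.

In the paired originals-vs-augmented comparison (`run_experiment()` /
`augmentation_experiment()`), the originals are split first, the VAE is
trained on the training portion only, and both classifier conditions are
scored on the same original-only test set. Two deliberate choices differ
from the source protocol and are made for internal validity: (a) the VAE
never sees test originals (training it on everything would leak test
structure into the synthesized training images), and (b) both conditions
consume scale-recolored grayscale maps, so the comparison is not
confounded by input representation (decoder outputs are grayscale and are
recolored through the same dioptric palette before classification).

## Evaluation

Confusion counts with keratoconus positive; accuracy, sensitivity,
specificity; predictive values either from raw counts or adjusted to a
stated prevalence by Bayes' rule (the default screening prevalence is 44%):
$$\mathrm{PPV} = \frac{\mathrm{sens}\cdot p}
 {\mathrm{sens}\cdot p + (1-\mathrm{spec})(1-p)},\qquad
 \mathrm{NPV} = \frac{\mathrm{spec}\,(1-p)}
 {\mathrm{spec}\,(1-p) + (1-\mathrm{sens})\,p}.$$
Both modes are kept because the printed predictive values of the source
table cannot be reproduced exactly from its sensitivities/specificities
under the 44% formula; the report records which mode produced its numbers.
A metric with an empty margin (e.g. sensitivity without positives) is
returned as `NA` and named in an `undefined` field rather than aborting the
whole report.

ROC curves sweep the unique scores (positive when score >= threshold) with
infinite sentinels; AUC is the trapezoidal area, which equals pairwise
concordance with ties counted 1/2 (asserted to 1e-9 against brute-force
enumeration on 200 random score sets, and cross-checked against pROC). The
operating point is the threshold minimizing |sensitivity - specificity|,
ties broken by the larger sensitivity + specificity, then by the smaller
threshold.

Grad-CAM: channel weights are spatial means of the positive-logit gradient
at the last convolution layer; the heat is the rectified weighted activation
sum, min-max normalized and bilinearly upsampled. Min-max normalization
makes the map invariant to positive rescaling of downstream weights (a
tested property). Overlays blend `(1 - alpha) * image + alpha *
colorized(heat)` through the same dioptric palette.

## Problem sizes and numerical choices

* Demo scale (the `demo` preset and the test suite) uses 100 + 100
  original maps, a target of 200 per class, 3 VAE epochs and 5 CNN epochs;
  paper scale keeps 978 + 780, 2000 per class, and the full 50/15/10
  epochs. The bookkeeping checks at full scale (4000 images; 800-image
  original-only test split) smoke-fit the VAE with one epoch on a
  stratified 256-image subsample — the quantities under test are counts,
  and this keeps the suite at desk scale.
* At demo scale the VAE performs only a few dozen optimizer steps at the
  protocol's learning rate, so synthesized images carry weak class signal;
  the directional augmented-vs-original comparison is reported with ties
  counting in favour of "no harm", which is what those conditions support.
* Determinism: every stochastic stage derives its seed from the global
  seed via `derive_seed(seed, label)`; fixed (data, config, seed) gives
  bit-identical cohorts, training histories and predictions on one build.
  BLAS builds may differ across platforms; determinism is within-build.
* Degenerate inputs: powers outside the color scale clamp to the end bins
  (counted and attached as an attribute); an empty HSV mask raises
  `no_cornea_found`; a component touching all four borders raises
  `segmentation_ambiguous`; a shape chain that does not close raises
  `architecture_mismatch`; ROC with a single class raises `undefined_roc`.
* Reconstruction probabilities are clamped at 1e-12 inside the Bernoulli
  NLL; training uses the logit form of the loss for stability.

## Known limitations

* The one-dimensional latent space (read literally from the two-parameter
  posterior) limits the diversity of synthesized maps; `latent_dim` is
  configurable but defaults to 1.
* The simulator's class difference is driven by cones and index
  distributions; it has no inter-device or inter-operator variability, so
  absolute accuracies on synthetic cohorts say nothing about clinical
  performance (headline clinical accuracies are explicitly not reproduction
  targets).
* The CPU engine favours clarity and testability: it is fast enough for
  the package's scales (a full demo pipeline in minutes) but not for
  clinical-scale hyperparameter searches.
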