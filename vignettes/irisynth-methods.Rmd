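---
title: "Self-supervised iris segmentation with irisynth: models and methods"
author: "irisynth authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised iris segmentation with irisynth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irisynth)
```

## The problem and the idea

Training a pixel-wise iris segmenter needs eye images with per-pixel labels,
and per-pixel annotation of iris imagery is the expensive step: even the
largest public near-infrared iris collections hold only a few tens of
thousands of images, and masks must be drawn by hand. `irisynth` implements a
self-supervised route around the annotation bottleneck:

1. **A parametric anatomy model** samples plausible eye configurations — a
   pupil circle, an iris circle, and an elliptical eyelid aperture — from
   eleven named parameters, and rasterises each configuration into a binary
   *iris mask* (the annulus of visible iris texture) and a *periocular mask*
   (the open-eye region).
2. **A conditional adversarial network** (U-Net generator + patch
   discriminator, the Pix2Pix family) learns to map the two-channel mask
   condition to a realistic eye image.
3. Because every synthesised image is generated *from* a known mask pair, the
   masks are free labels: the synthetic set trains a **segmentation network**
   with no manual annotation at all. Only the small seed set that trains the
   generator ever needs ground truth.

The package also ships a **procedural eye renderer** so the whole loop runs
hermetically: the renderer plays the role of the "real" camera data at desk
scale, which is what makes every stage testable in minutes on one CPU.

## The mask family

One configuration is held by a `MaskParameters` object: pupil centre/radius
(`pupilX`, `pupilY`, `pupilR`), iris centre/radius (`irisX`, `irisY`,
`irisR`), and the eyelid ellipse expressed relative to the iris — centre
displacement (`xOffset`, `yOffset`), semi-axes as multiples of the iris
radius (`xRatio`, `yRatio`), and rotation (`degree`, counter-clockwise from
the +x axis). Coordinates are 0-based pixels, x = column, y = row, origin
top-left.

Default sampling intervals (for a 640x480 frame): `pupilR` in [20, 60],
`irisR` in [70, 120] pixels, `xRatio` in [1.3, 2.5], `yRatio` in [0.4, 1.1]
(zero ratios would collapse the ellipse), `degree` in [-15, 15], and offsets
bounded by half the corresponding semi-axis, ±`ratio`·`irisR`/2 — larger
displacements push the aperture off the iris entirely. Sampling order
matters and is explicit: radii and ratios first, then the iris centre
(uniform over the middle 60% of the frame, which keeps shapes mostly
in-frame), then the pupil centre as iris centre plus a small isotropic
Gaussian jitter (sd 3 px), rejection-sampled until the pupil circle sits
geometrically inside the iris circle, and finally the offsets, whose bounds
depend on the already-sampled ratios and radius.

Two semantic choices were genuinely open and are fixed as follows:

* **Annulus semantics.** The iris mask is the *annulus* (iris disc minus
  pupil disc), matching overlays where the mask covers visible iris texture;
  an option (`clipToPeriocular`) additionally intersects it with the eyelid
  aperture, and the pipeline uses the clipped form as the segmentation label
  so the label marks exactly the texture a camera would see.
* **Offset reference.** The ellipse centre offset is taken relative to the
  *iris* centre (the iris and pupil centres nearly coincide by
  construction, so the distinction is minor).
* **Pixel-inclusion rule.** A pixel is foreground iff its centre satisfies
  the shape inequality — hard binary masks, no anti-aliasing, because the
  discriminator and the segmentation loss both expect hard labels.

Rasterised areas converge to the analytic areas $\pi(R^2 - r^2)$ and
$\pi a b$; at 640x480 the relative error for in-frame shapes is below 1%,
which the test suite checks against a per-pixel brute-force oracle.

## The networks

Both networks are built from 4x4, stride-2 convolutions, so spatial size
exactly halves (encoder) or doubles (decoder) per layer.

**Generator.** An encoder-decoder U-Net: `depth` encoder convolutions with
instance normalisation and LeakyReLU(0.2); `depth` transposed convolutions
with instance normalisation and ReLU in the decoder; dropout 0.5 on the
first five decoder layers; sigmoid output; skip connections at every level.
At 256x256 the canonical depth is 8, giving a 1x1 bottleneck; at the desk
scale of 64x64 the same construction uses depth 6. Instance normalisation
is skipped on 1x1 maps, where a per-channel spatial variance does not
exist — a numerical necessity, not a modelling choice. Weights are
Gaussian-initialised with sd 0.02 (the Pix2Pix-lineage default; the sd is
otherwise unconstrained).

**Discriminator.** Five stride-2 convolutions on the 3-channel stack (iris
mask, periocular mask, image), instance normalisation + LeakyReLU on the
first four, and a sigmoid *patch* map from the fifth. On a 256x256 input
the feature maps after the fourth convolution are 16x16 and the output
patch map is 8x8; the adversarial objective averages over patches. (The
published architecture description stops at the fourth layer; a stride-2
sigmoid patch head is the consistent completion of "five convolutional
layers with stride 2".)

```{r arch}
d <- discriminatorNetwork(baseWidth = 4, seed = 1)
discriminatorFeatureSizes(d, c(256, 256))
```

**Objectives.** With condition $x$ (the mask pair), reference image $y$ and
generator output $G(x)$:

$$\mathcal{L}_{cGAN}(G, D) = \mathbb{E}\,[\log D(x, y)] +
  \mathbb{E}\,[\log(1 - D(x, G(x)))],$$

ascended by $D$; the generator descends an adversarial term plus an L1
reconstruction term weighted by $\lambda = 100$ (L1 rather than L2 because
it blurs less). Two numerical conventions:

* The L1 term is the **per-pixel mean** $\|y - G(x)\|_1 / (wh)$, not the
  raw sum, so $\lambda = 100$ means the same thing at every resolution.
* The generator's adversarial term defaults to the **non-saturating** form
  $-\log D(x, G(x))$ (the minimax form $\log(1-D)$ has vanishing gradients
  early in training and is available as a config switch,
  `nonSaturating = FALSE`).

Scores are clamped away from 0/1 (at 1e-12) before logs. Training is Adam
with learning rate 1e-4, $\beta_1 = 0.5$, $\beta_2 = 0.99$; the reference
batch size is 64. The generator update reuses the discriminator's fake-pass
activations (i.e. it steps against the pre-update discriminator), one of
the two standard alternating-update orders, chosen because it saves a third
discriminator pass per iteration on a CPU.

**Segmenter.** The generator architecture with the input channel set to one
(grayscale) and the sigmoid head replaced by a channel-wise softmax — an
n-class per-pixel distribution requires normalisation across classes. The
default class set is binary (iris vs everything else); a 3-class mode
(background / periocular / iris) is a config option. Decoder dropout is
disabled for the segmenter: dropout in this lineage is the generator's
noise source, and the segmentation task description prescribes the
architecture, the optimizer, and the loss — not the generation-specific
regulariser (at desk-scale capacity it measurably hurts). The loss is the
FCN form: cross-entropy **summed** over pixel positions,

$$L(P, Q) = -\sum_{i}\sum_{j}\sum_{k} Q_k(i,j)\, \log P_k(i,j),$$

whose pixel mean is the familiar mean cross-entropy (the suite asserts the
identity numerically). Prediction is the per-pixel argmax with ties broken
toward the lower class index.

## The renderer: what it emulates and what it does not

`renderEye` composites four intensity classes — dark pupil (0.05), mid-grey
iris (0.45) with striation texture (angular sinusoid + seeded smoothed
noise, amplitude 0.12), bright sclera (0.9) inside the eyelid ellipse, skin
(0.72) outside — plus optional additive Gaussian noise (sd 0.02) and a
"glasses" mode that adds two specular glare discs and a frame arc,
mirroring the with-/without-glasses capture split. The intensity ordering
(pupil < iris < skin < sclera) matches near-infrared iris captures, and
texture amplitude is bounded so the iris band never overlaps the skin
level; on noiseless renders, plain intensity thresholding recovers the iris
mask with IoU ≥ 0.95, a sanity oracle for the whole pipeline.

What the renderer does **not** emulate: eyelashes, specular reflections on
the cornea, defocus/motion blur, off-axis gaze, or genuine iris texture
statistics. Tests passing on rendered data therefore demonstrate that the
*machinery* (sampling, conditioning, losses, optimisation, metrics) is
correct and that the self-supervised loop closes; they do not certify
performance on real camera data, which needs the full-scale (GPU, gated
dataset) setting.

## Evaluation

All segmentation metrics derive from one k x k confusion matrix of
per-pixel counts ($p_{ij}$ = true class $i$ predicted $j$): pixel accuracy
(trace / total), mean pixel accuracy (per-class recall averaged over
classes present in ground truth — absent classes have an undefined ratio
and are excluded), mean IoU ($p_{ii} / (\sum_j p_{ij} + \sum_j p_{ji} -
p_{ii})$, averaged the same way), and frequency-weighted IoU (IoU weighted
by ground-truth class frequency, compensating the heavy background
imbalance of eye images). All four live in [0, 1] and equal 1 exactly for a
diagonal confusion matrix.

Generated-image quality is scored by the Fréchet distance between Gaussian
fits to embedded image sets:

$$\mathrm{FID} = \|\mu_r - \mu_g\|^2 +
  \mathrm{Tr}\big(\Sigma_r + \Sigma_g - 2(\Sigma_r \Sigma_g)^{1/2}\big).$$

The embedder is pluggable. The canonical choice is a pretrained 2048-d
inception feature; the package default is a deterministic pixel-moment
embedding (8x8 bilinear downsample + global mean and sd), because the
distance formula is embedder-agnostic and desk-scale tests must not
download weights. The matrix square root is computed through the
symmetrised product $\Sigma_r^{1/2} \Sigma_g \Sigma_r^{1/2}$ with an
eigendecomposition; eigenvalues below zero from round-off are clipped, so
the reported distance is never negative. For 1-D Gaussians
$\mathcal{N}(0,1)$ vs $\mathcal{N}(m,1)$ the distance is exactly $m^2$,
one of the closed forms the tests pin.

## Augmentation

The training recipe crops randomly (default window 456x608 from a 480x640
frame — cropping slightly below the native frame enlarges the apparent
iris; 432x576 is the named alternative preset, stored explicitly as
height x width), flips horizontally with probability 0.5 (left and right
eyes augment each other), and resizes to the network input. The identical
transform is applied to the image and both masks; images are resampled
bilinearly, masks by nearest neighbour and re-binarised, because labels
must stay hard. The sampled transform is logged and `applyAugmentation`
re-applies it bit-for-bit, which is the property the suite tests.

## Desk-scale choices (problem sizes, rates, tolerances)

The package's toy experiment (`experimentConfig()`) fixes the hermetic
study conditions: 64x64 frames (mask ranges rescaled by the frame ratio),
200 rendered training pairs, 200 adversarial iterations at batch 16 with
generator width 16 and discriminator width 8, 200 synthesised images, 10
segmentation epochs with one augmented copy per training sample (crop 7/8
of the frame + flip), and a held-out rendered test set. Several settings
are deliberately scale-dependent — the reference recipes assume ~10^4
optimizer steps (thousands of images at batch 64), whereas a desk-scale
run takes ~10^2 steps:

* **Learning rates.** The segmenter's reference 1e-5 cannot move the loss
  appreciably in ~10^2 Adam steps, and the adversarial reference 1e-4
  leaves the generator visibly unconverged; both toy presets use 1e-3,
  chosen by a one-time sweep on rendered (not synthesised) data and kept
  fixed. `segConfig()` and `ganTrainingConfig()` defaults remain the
  reference recipe.
* **Decoder dropout.** At reference scale the generator's dropout 0.5 on
  five decoder layers is a noise source; at width 16 it removes half the
  capacity of an already-minimal decoder and measurably dominates the
  error budget (a dropout-free generator at 200 iterations outperforms a
  dropout generator at 600). The toy presets therefore build the GAN
  generator and the segmenter without decoder dropout
  (`generatorDropout = 0`); full-width networks keep dropout 0.5.
* **Adversarial form.** The toy preset uses the minimax generator term
  (the objective's literal form); at 200 iterations with a λ = 100 L1
  anchor there is no early-training saturation to escape, and the weaker
  adversarial gradient yields smoother, more label-faithful images. The
  non-saturating form remains the full-scale default.
* **Augmentation.** The crop/flip recipe is applied to segmentation
  training sets (one augmented copy per sample); at desk scale it is the
  difference between a segmenter that keys on synthesis artefacts and one
  that transfers to held-out renders.

Numerical edge cases handled explicitly: probability clamping before logs
(1e-12); instance-norm epsilon 1e-5; covariance symmetrisation and
eigenvalue clipping in the Fréchet distance; argmax tie-break toward the
lower class; masks re-binarised at 0.5 after any interpolation; rejection
sampling for the pupil-containment invariant.

## Known limitations

* The networks are CPU implementations intended for desk-scale study of
  the framework; full-scale 256x256 training on tens of thousands of
  images is out of reach without GPU acceleration.
* The renderer's appearance model is deliberately simple (see above); FID
  values on rendered data are not comparable to published values computed
  with inception features on camera imagery.
* The mask family has no eyelash/reflection channels — the anatomy model
  does not parameterise them, so labels on real data that exclude such
  occlusions are outside what the generator can express.
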