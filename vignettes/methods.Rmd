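---
title: "Self-attention fusion of paired-modality images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-attention fusion of paired-modality images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mpfusion)
```

## The problem

Multi-parametric MRI examines the same anatomy under several acquisition
sequences with distinct contrast mechanisms: a T2-weighted sequence depicts
lesion and bladder-wall structure, while a dynamic contrast-enhanced (DCE)
sequence reflects tumour vascularisation. For grading bladder urothelial
carcinoma (high grade vs low grade) the two sequences carry *complementary*
information, and the question this package addresses is how to fuse them:
per-patient 2-D slice pairs go through two independent convolutional
branches, a multiscale attention block enriches each branch's features, and
a self-attention head fuses the two modality representations with a class
token before a two-layer classifier outputs grade probabilities.

## The classification graph

**Branches.** Each modality has its own feature extractor with independent
parameters (no weight sharing). The default is a dense-connectivity network
(blocks of 6/12/24/16 bottlenecked units, growth 32) that maps a
`[B, 224, 224, 3]` batch to a `[B, 7, 7, 1024]` feature map; a residual
bottleneck network and a depthwise-separable stack are registry
alternatives, and a three-stage compact backbone (`[B, 32, 32, 3]` to
`[B, 1, 1, 64]`) exists so the full graph trains in seconds on a CPU.
Before the first convolution, pixel values in $[0,1]$ are shifted by a
constant $-0.5$. The shift is deliberately *not* a per-image
standardisation: overall image brightness is diagnostic information for a
contrast-enhanced sequence, and per-image normalisation would erase it.

**Multiscale attention (MA).** A plug-and-play block configured by channel
counts, not constants:

1. pointwise convolution reducing $C$ channels to $C/2$ (batchnorm +
   ReLU);
2. two parallel *IC paths*, each an inception stage (1x1, 3x3, 5x5
   convolutions plus a 3x3-maxpool + 1x1 branch, one quarter of the
   channels each, 'same' padding) followed by CBAM attention — a channel
   gate (shared two-layer MLP over global-average and global-max pooled
   descriptors, sigmoid) then a spatial gate (7x7 convolution over the
   channel-wise mean and max maps, sigmoid);
3. channel concatenation of the two paths and a second pointwise
   convolution back to $C/2$ (an additive `combine = "add"` variant is
   available);
4. an additive skip connection from the reduced features.

Two points were genuinely open. Whether the second pointwise convolution
precedes or follows the path combination: we place it after, because its
natural role is re-projection of the concatenated paths. Whether the skip
connection adds or concatenates: we add, which is what "mitigating gradient
disappearance without extra parameters" implies; with the IC paths zeroed
the block is then exactly the identity on the reduced features, a property
the test suite asserts.

**SAFF.** Each branch's map is global-average-pooled to a token
$[B, 1, d]$ ($d$ = MA output channels, 512 at full scale), spliced with a
learnable class token (Gaussian init, sd 0.02) into a bundle
$[B, 3, d]$ ordered (A, B, cls). Single-head scaled dot-product attention
with trainable projections $W_q, W_k, W_v$ produces

$$g = \mathrm{softmax}\!\left(\frac{QK^\top}{\sqrt d}\right), \qquad
  f = gV, \qquad h = \theta V + f,$$

where every row of $g$ sums to one (softmax over the key axis) and the
scalar $\theta \ge 0$ (default 1, optionally learnable) preserves the
original features inside the commonality term. The final "splice" of the
specific features $g$ and common features $h$ cannot be an addition —
$g$ is $3\times3$ and $h$ is $3\times d$ — so the fused vector is a
concatenation: the default `readout = "full"` flattens $g$ (column-major,
9 values) and $h$ ($3d$ values) into a length-$3d+9$ vector; the
alternative `readout = "cls"` concatenates the class-token rows of $h$ and
$g$ (length $d+3$). Both readouts ship because it is genuinely ambiguous whether
the specificity features enter the classifier raw or attended; neither is
claimed canonical. A single shared class token is used rather than
per-modality class codes. The classifier is two fully connected layers
(hidden width 256, ReLU) with a softmax over the two grades.

**Fusion baselines.** Input-level fusion pools each modality image as an
independent sample (doubling the sample size) through one shared branch;
feature-level fusion concatenates or adds the two pooled branch features;
decision-level fusion trains the two single-modality models and averages
their output distributions with validation-accuracy-proportional weights
(a majority-vote variant exists). All strategies share the extractors, MA
block and training engine, so a strategy comparison is one configuration
switch.

## Training recipe

`train_config()` defaults mirror the reference recipe: SGD, learning rate
0.01, 50 epochs, batch size 8, cross-entropy loss plus an L1 penalty
(coefficient $10^{-5}$; convolution and dense weights only — biases and
batchnorm parameters are exempt), early stopping on validation loss with
patience 10 and best-weight restore. The optimiser also accepts a
classical-momentum coefficient (default 0, matching the plain recipe).
Metrics are accuracy, F1 with the high-grade class positive, and AUC by
rank-based ROC integration (midranks for ties), reported to 4 decimals
(round half to even). k-fold cross-validation aggregates per-fold metrics
by arithmetic mean and **population** variance (division by $k$): on the
published 10-fold accuracies only the population variance reproduces the
printed 0.0001 (the sample variance gives 0.0002), which settles the
convention.

Splits are always at patient level. The 8:1:1 rule is: per class,
validation and test each get $\mathrm{round}(n/10)$ patients and training
the remainder — the only simple rounding rule consistent with the published
60/8/8 and 50/6/6. The k-fold splitter stratifies fold assignment by class
(sizes within one per class); in fold $i$ subset $i$ is the test set, the
next subset the validation set, the remaining $k-2$ train.

Augmentation draws, per image, a vertical flip (p = 0.5), a horizontal
flip (p = 0.5), a brightness factor uniform on ±20 % (clipped to $[0,1]$)
and a shear uniform on ±10°; only the four operations themselves are
prescribed, so the ranges are package defaults, all configurable. The
published augmented slice counts imply non-uniform per-class expansion
(155 to 743 is 4.8x, 99 to 665 is 6.7x) without stating whether
augmentation balanced the classes; `augment_cohort()` therefore accepts
per-class multiplicities and infers nothing. The reference manifest
(`reference_split_manifest()`) copies the published counts verbatim rather
than deriving them.

## The synthetic cohort generator

The clinical cohort (138 patients, T2WI + DCE) is private, so the package
ships a generator that emulates its *shape*: two classes with the observed
55/45 imbalance, 1–5 paired slices per patient, grayscale slices replicated
to three channels. Each slice shows a deterministic scene (a centred lesion
disk on a mild intensity gradient) plus i.i.d. Gaussian pixel noise
(`noise_sigma`, default 0.05), and high-grade slices additionally carry two
class cues split complementarily across the modalities:

* **modality A** — an oriented sinusoidal texture (45°, wavelength
  size/8) inside the lesion disk, emulating structural heterogeneity in a
  T2-weighted sequence;
* **modality B** — a diffuse intensity enhancement over the field,
  emulating contrast uptake in a DCE sequence.

Both cue templates are L2-normalised and mutually orthogonal, so the
matched-filter (Bayes-optimal) statistic of modality $m$ is Gaussian with
unit variance and class separation
$d_m = \mathrm{effect}_m \cdot \mathrm{cue\_scale}_m / \sigma$, the cues
are conditionally independent given the class, and the joint deflection is
$\sqrt{d_a^2 + d_b^2}$ — strictly larger than either marginal whenever both
effects are positive. `bayes_oracle()` computes the Bayes accuracy under
the configured class prior by numeric integration of
$\max\{\pi_1\varphi(t - D), \pi_0\varphi(t)\}$ and the AUC of the optimal
score by integrating the rank statistic; the test suite cross-checks both
against the closed-form Gaussian answers. These oracle values upper-bound
any classifier trained on the images.

Two design iterations are worth recording because they shaped the cue
model. First, every backbone here (full-size and compact) ends in global
average pooling, so the statistics a trained network can realise are
position-free: the global mean, and rectified-filter energies. A cue that
requires a *spatial mask* to detect (a thin rim annulus, say) has a high
matched-filter deflection that no pooled network can approach — early
versions of the generator produced exactly that pathology, with networks
learning only the faint global-mean shadow of a localised cue. The final
cues are therefore position-free statistics by construction. Second, after
pooling, a linear readout of any zero-mean spatial pattern vanishes, so
the texture cue is only detectable *quadratically* (energy of rectified
filter responses), which requires per-pixel contrast on the order of the
noise. That is why the default texture cue norm (`cue_scale[1] = 1.2`) is
an order of magnitude larger than the enhancement cue norm
(`cue_scale[2] = 0.125`): at image size 32 the texture's per-pixel
amplitude is then about 1.7 times the pixel noise while the enhancement
shifts each pixel by only about 1/40 of the noise, and the two trained
single-modality arms land in a comparable accuracy range. The price is
that the matched-filter bound for modality A is loose for pooling
networks; the bound direction is unaffected.

What the generator does **not** emulate: MRI physics and acquisition
artefacts, 3-D anatomy and inter-slice correlation (slices of a patient are
conditionally independent given the label), ROI outlining, scanner and
site effects, and any label noise. Passing the synthetic benchmark
therefore demonstrates that the implementation can discover and fuse
complementary modality-specific signal under controlled conditions — not
that it reproduces clinical performance.

## The fusion-benefit benchmark

`fusion_benchmark()` fixes the study conditions: per replicate, a training
cohort of 32 + 28 patients (about 170 slices) at 32 px with unit effects on
both cues, split 8:1:1 by patient; a fresh evaluation cohort of 30 + 26
patients scored in full (about 170 slices, so the Monte-Carlo s.e. of an
accuracy is below 0.04 per replicate); three replicates; and the compact
backbone with MA and the norm-free configuration. Training uses SGD with
momentum 0.9 and learning rate 0.005 for 60 epochs without early stopping.
Two small-data engineering facts shaped that recipe. First, the two-branch
fusion graph starts in a saddle whose escape time on ~10² noisy slices is
seed-dependent (tens of epochs); before the escape the loss is flat at
log 2 while a tiny ripple of the logits already ranks the classes, so AUC
can look good while the probabilities sit uncalibrated near 0.5 — training
must therefore run long enough to *converge*, not merely to rank, and
early stopping on the wobbling pre-escape validation loss would quit too
soon. Second, a batch of 8 on cohorts this small makes batchnorm's
train/eval statistics mismatch dominate weak cues, which is why the
compact configuration is norm-free end to end (the full-size backbones
keep batchnorm). The
acceptance checks are that the fused head's mean AUC over replicates is at
least each single-modality arm's, and that every arm's accuracy stays below
its Bayes bound plus three Monte-Carlo standard errors. Problem sizes were
chosen so the whole benchmark runs in minutes on one CPU core while the
evaluation sets are large enough for the comparisons to be meaningful.

## Numerical choices

* Convolution is im2col + BLAS matrix multiplication, 'same' zero padding
  throughout; every backward pass in the package is verified against
  central finite differences in the test suite (tolerances $10^{-6}$ to
  $10^{-4}$).
* Batchnorm uses population batch statistics in training and running
  moments (momentum 0.1) at evaluation; $\varepsilon = 10^{-5}$.
* Softmax and cross-entropy are computed with max-subtraction and a
  $10^{-12}$ floor inside the logarithm.
* Max-pool ties break to the first (column-major) position; rank AUC uses
  midranks, equivalent to half-credit for ties.
* Early stopping treats "no improvement" as a non-decrease of the
  monitored score beyond $10^{-12}$; on ties the earlier epoch's weights
  are kept.
* CBAM's channel-MLP hidden width is $\max(1, C/\mathrm{ratio})$ so the
  block remains valid at small channel counts.
* Weight initialisation is He-normal for convolutions and hidden dense
  layers, $1/\sqrt{d}$ scaling for attention projections and final
  classifier layers; all initialisation is seeded and bit-reproducible.
* t-SNE (visual validation only) is the exact $O(n^2)$ algorithm with
  bisection-matched perplexity, early exaggeration 4 for 50 iterations,
  and momentum gradient descent under a fixed seed.

## Limitations

The numerical core is plain R with BLAS; it trains compact models in
seconds but full-size backbones, while functional forward and backward,
are not practical to train at 224 px on a CPU — transfer-learning
initialisations can be supplied as weight files instead
(`extractor_save_weights()` / `extractor_load_weights()`, `pretrained =`).
The SAFF head is written for exactly two modalities plus one class token;
generalising the token axis is future work. Slice-level evaluation is the
default (the published slice counts are the evaluation units); patient-
level aggregation by mean probability is available via
`evaluate_fit(aggregate = "patient")`. The synthetic benchmark's scope is
stated above; no claim about clinical data follows from it.
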