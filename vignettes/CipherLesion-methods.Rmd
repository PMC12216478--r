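---
title: "CipherLesion: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CipherLesion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CipherLesion)
```

CipherLesion is a toolkit for privacy-preserving classification of
dermoscopy-like images. It chains four components: a block-scrambling
image cipher for confidential storage and transport, fused convolutional
feature extraction, a conditional variational autoencoder (CVAE)
classifier, and the hippopotamus optimization (HO) metaheuristic for
hyperparameter tuning. This vignette explains each model, the parameters
that matter, the numerical choices, and what the synthetic benchmarks do
and do not demonstrate.

## The block-scrambling cipher

An image of `X x Y` pixels (8 bits per channel) is divided into
non-overlapping square blocks, `Bx = By = 16` by default. Four key
streams, one entry per block, drive four scrambling steps:

1. **Block scrambling (K1).** A secret permutation of block positions.
2. **Rotation/flip (K2).** Each block undergoes one of the 8 symmetries
   of the square (4 rotations x optional horizontal flip). "Invert and
   rotate" is read as the full dihedral group, the standard reading in
   block-scrambling schemes.
3. **Negative–positive transform (K3).** Where the key bit is 1, every
   pixel becomes `p XOR (2^L - 1)` — for `L = 8`, `255 - p`. The key
   bits are Bernoulli(0.5), so on average half the blocks are inverted.
   The transform is an involution.
4. **Channel shuffling (K4).** The three colour components of the block
   are permuted by one of the `3! = 6` permutations in a fixed
   enumeration.

K1–K3 are shared across colour components; K4 permutes whole channels.
Decryption applies the exact inverses in reverse order, so
`decrypt(encrypt(x)) == x` bit for bit — the package asserts this
per-image inside `runPipeline()`. Because the scrambling acts on whole
blocks and pixel values (not on a transform domain), the ciphertext
remains an ordinary raster image that standard codecs can store; PNG
round trips are lossless and decrypt exactly, while JPEG storage is
lossy and only suitable as a smoke test.

**Key derivation.** The four streams derive from a single integer master
seed through R's Mersenne-Twister generator in a fixed order (K1 via
`sample.int`, then K2, K3, K4). The generator and stream order are part
of the cipher's contract: two parties sharing the seed derive identical
keys. This derivation is a package design choice; only the four-stream
structure itself is fixed by the scheme.

**Non-divisible images.** The default is a hard error naming the
offending axis. With `pad = TRUE` the image is reflect-padded on the
bottom/right, the original size is recorded, and decryption crops back.

The cipher offers scrambling-based confidentiality, not provable
cryptographic security; no resistance analysis is claimed.

## Fused convolutional features

Three reduced-scale extractor families mirror well-known architectures:

* **MobileNetV2-style** — inverted residual blocks: 1x1 expansion,
  depthwise 3x3 convolution, linear 1x1 projection, with an identity
  shortcut when the stride is 1 and channel counts match.
* **Inception-style** — blocks with parallel 1x1 / 3x3 / 5x5 branches
  (1x1 reductions) plus an average-pool projection branch, concatenated
  along channels.
* **AlexNet-style** — a wide 7x7 first receptive field, then 5x5 and 3x3
  kernels with max-pooling. The canonical design is five convolutional
  stages feeding fully connected layers; the textual description of
  "eight fully connected layers and five convolutional layers" sometimes
  seen for this family conflicts with the canonical counts, and the
  canonical convolutional design is what is implemented.

All use ReLU. The feature vector is the global average pool of the last
convolutional stage, and fusion is plain concatenation in declared
backbone order (88 features at width 1), optionally followed by
per-feature z-scoring with statistics fitted on training data only.
Concatenation is the simplest faithful reading of "fusion": it preserves
every backbone's information and leaves the weighting to the classifier.

**Why fixed random weights?** The package runs download-free on a single
CPU, so ImageNet-pretrained weights are out of scope. The extractors are
architecture-faithful but He-initialized from a seed and then *fixed* —
random convolutional features, a standard and surprisingly strong
baseline — and the interface accepts externally supplied weights.
Backbone training is deliberately not implemented: the trained component
of the pipeline is the classifier, and on the synthetic data the fixed
features already support far-above-chance classification (a
nearest-centroid probe on the fused features reaches roughly 60%
accuracy on the 9-class synthetic benchmark, against an 11% baseline).
Images are bilinearly resized to the extractor input (default 64 px) and
scaled to `[0, 1]`; extraction is a pure function of (weights, image).

## The conditional VAE classifier

The classifier is a conditional VAE on (standardized) fused feature
vectors `x` with class labels `c` one-hot concatenated to both the
encoder and decoder inputs. The encoder (two ReLU hidden layers, default
64/32) outputs the mean and log-variance of a diagonal Gaussian
posterior `q(z | x, c)`; the reparameterized sample `z = mu + sigma *
eps` feeds the mirrored decoder, whose output parameterizes a
unit-variance Gaussian likelihood, so the reconstruction term is
`||x - xhat||^2 / 2`. Training minimizes

  reconstruction + KL( q(z | x, c) || N(0, I) ),

with the closed-form KL `0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)`
and a single Monte-Carlo sample per step. Defaults follow the study
settings: learning rate 0.01, 50 epochs, batch size 5, dropout 0.5.

**Decision rule.** A generative CVAE does not define a classifier by
itself. The package evaluates the training objective under every
candidate class with the latent noise pinned to 0 and takes the argmin —
conditional-likelihood classification using exactly the trained
objective, deterministic at inference, with exact ties resolved to the
lowest class index.

**Numerical choices.** Log-variances are clamped to `[-15, 15]` against
overflow; gradients (hand-written backpropagation, verified against
finite differences in the test suite) are clipped in global norm at
`max(5, 0.25 * inputDim)` — the reconstruction term sums over feature
dimensions, so gradient magnitudes grow with the input width and a fixed
small threshold would silently shrink the effective learning rate on
wide feature vectors. The latent dimension must be strictly smaller than
the input dimension.

**Benchmark design.** The correctness benchmark trains on 3-class
Gaussian mixtures (n = 300, 10 dimensions, unit noise) and requires
held-out accuracy of at least 0.95. With class means exactly 4 standard
deviations apart, the Bayes error is already about 3.5%, and on 60
held-out points even the Bayes rule falls below 0.95 on roughly one draw
in six — a bound that tight cannot separate implementation errors from
sampling luck. The benchmark therefore uses clearly separated mixtures
(6 sigma between means) and a 100-epoch training budget, where the
implementation passes with margin across every probe seed; the pipeline
defaults are unaffected.

## Hippopotamus optimization

`hippoOptimize()` is a bound-constrained population minimizer with three
phases per iteration over a herd of `M` candidates in `N` dimensions:

1. **Social phase** (first half of the herd, exploration): a male update
   toward the current leader, `x + rand * (leader - C1 * x)`, and a
   female/calf update relative to the mean of a random subgroup, with a
   branch keyed on the decay scalar `T` and a secondary coin flip. Five
   interchangeable random-coefficient scenarios supply the step vector.
2. **Defense phase** (second half): a predator is placed uniformly in
   the box; the candidate jumps with a Levy-flight factor applied to the
   predator position plus a term scaled by the inverse distance (the
   denominator switches to `2*Dist + rand` when the predator is not
   fitter). Coincident positions are guarded by a 1e-10 floor.
3. **Escape phase** (everyone, exploitation): a step inside local bounds
   `L/t, U/t` that shrink with the iteration counter `t`, with the step
   scale drawn from three scenarios (uniform, signed uniform, normal).

Every proposal is clamped to the box and accepted only on *strict*
fitness improvement, so the best-so-far trajectory is monotone
non-increasing by construction; ties reject. The decay scalar is
implemented as `T = exp(-t / maxIter)` — keeping `T` in `(e^-1, 1]` so
the early-phase branch (`T > 0.6`) is active at the start — rather than
the typographically ambiguous alternative `exp(-t)/maxIter`, which would
be vanishingly small from the first iteration. The defense-phase
constants `b, c, d, g` have no canonical values; they are drawn per
update from documented default ranges (`[2,4]`, `[1,1.5]`, `[2,3]`,
`[-1,1]`), all configurable. The Levy step uses Mantegna's stable-ratio
construction with exponent 1.5. Everything is reproducible from one
seed.

On the 2-D sphere with `M = 20` and 50 iterations the optimizer reaches
fitness below 1e-2 (typically far below), and it beats uniform random
search with an identical evaluation budget on shifted convex quadratics
on 20 of 20 paired seeds in the acceptance run.

**Tuning interface.** `tuneHyperparameters()` searches a mixed box over
(log10 learning rate, latent dimension, batch size, dropout); integer
dimensions are rounded at evaluation. The objective is the negative
validation macro precision on a stratified 80/20 carve-out of the
training features. The default configuration is seeded into the initial
population, so the tuned settings can never score worse than the
defaults on the tuning objective.

## Metrics

All metrics derive from the K x K confusion matrix (rows true, columns
predicted) by one-vs-rest binarization: per class, accuracy
`(TP+TN)/total`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F-measure
`2PR/(P+R)` and the Matthews correlation coefficient. Per-class
"accuracy" is the binarized binary accuracy — the only reading
consistent with per-class accuracies near 99% in a 9-class problem — and
the multiclass MCC is the per-class one-vs-rest binary MCC, not the
multiclass R_K statistic. Macro averages are unweighted means over
classes. Any metric with a zero denominator is 0 by convention. Report
tables round half-up to 2 decimals for display; full precision is kept
internally. A note on reading published per-class tables: when the
per-class cells are themselves rounded to 2 decimals, their recomputed
mean can differ from a printed average (computed from unrounded values)
by up to about 0.01.

## Synthetic data

`generateLesionDataset()` renders class-labelled lesion-like images: an
elliptical blob with a soft, sinusoidally-perturbed border on a noisy
skin-tone background. Each class has a parametric appearance — hue,
eccentricity, border irregularity frequency/amplitude, texture noise,
size — and a `separability` knob in `[0, 1]` scales how far the class
appearances sit from a shared base appearance: at 0 the classes are
exchangeable (any classifier's expected accuracy is 1/K), at 1 they are
maximally distinct. Default per-class counts mirror a 9-class dermoscopy
archive's imbalance (114, 376, 95, 438, 357, 462, 77, 181, 139; 2239
total), scaled by 0.1 by default for desk-scale runs; the imbalance
deliberately exercises imbalance-sensitive metrics such as MCC. Default
image size is 64 px and default separability 0.8 — strong but not
trivial class structure. Splits are stratified per class (the package's
choice; 80:20 and 70:30 are the evaluated ratios).

What the synthetic data does *not* emulate: dermoscopy resolution and
optics, realistic lesion morphology, hair/ruler artefacts, inter-device
colour variation. Passing the synthetic benchmarks demonstrates that the
cipher, features, classifier and optimizer are implemented correctly and
interact as specified — not that the pipeline reaches any particular
accuracy on real dermoscopy archives, which would require the real data
and pretrained backbones.

## Problem sizes and reproducibility

The packaged benchmarks use desk-scale sizes chosen for tight iteration:
the synthetic dataset at scale 0.1 (about 224 images, 64 px), backbone
width 1 (88 fused features), the CVAE at the study defaults, HO
benchmarks at `M = 20` x 50 iterations (sphere) and `M = 10` x 20
iterations (paired comparisons). Every stochastic stage takes an
explicit seed derived arithmetically from one global seed, and the
end-to-end pipeline is bit-reproducible: two runs with the same
configuration produce identical reports.

## Known limitations

* The cipher is a scrambling scheme; no formal security model is
  claimed, and JPEG (lossy) storage of ciphertexts breaks exact
  decryption by design.
* Backbones are fixed random-feature extractors; supplying trained
  weights is supported but no training loop for them is provided.
* The CVAE decision rule evaluates an ELBO, a bound rather than the
  exact class-conditional likelihood; on hard, overlapping classes it
  can sit measurably below the Bayes rule.
* The defense-phase constants of the optimizer are conventions, not
  canonical values; results on other objectives may be sensitive to
  them.
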