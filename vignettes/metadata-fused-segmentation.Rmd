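---
title: "Metadata-fused U-Net segmentation with Monte Carlo Dropout uncertainty"
author: "LesionSegUQ authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metadata-fused U-Net segmentation with Monte Carlo Dropout uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LesionSegUQ)
```

## The problem

Dermoscopic skin-lesion segmentation asks for a pixel-wise binary mask
separating a lesion from surrounding skin. Two practical difficulties
motivate this package. First, lesion boundaries are often ambiguous —
low contrast, hairline gradients, regression areas — so purely image-driven
models are uncertain exactly where clinical decisions are hardest. Second,
each lesion usually comes with structured clinical context: a histological
diagnosis and the standard dermoscopic criteria (pigment network,
dots/globules, streaks, regression, blue-whitish veil, colours, asymmetry,
border irregularity). `LesionSegUQ` implements a U-Net whose bottleneck is
fused with a 29-feature encoding of that context, together with a Bayesian
(Monte Carlo Dropout) treatment that quantifies how much the metadata
reduces predictive uncertainty.

## The model

The backbone is a standard U-Net. Each encoder block applies two 3×3
zero-padded convolutions with ReLU,

$$\mathbf{F}_l = \mathrm{ReLU}(\mathbf{W}_l * \mathbf{F}_{l-1} + \mathbf{b}_l),$$

followed by 2×2 max pooling; channel widths double per block
(64 → 128 → 256 → 512) up to a 1024-channel bottleneck. The decoder mirrors
the encoder with 2×2 transposed convolutions, skip concatenation and two
3×3 convolutions per stage, ending in a 1×1 convolution with a sigmoid that
yields a 224×224×1 lesion-probability map.

One architectural point needed reconciling: a 224-input U-Net with four
pools bottoms out at 14×14, yet the latent representation here is 7×7×1024
and the whole network counts about 31 M parameters. We satisfy both by
inserting a fifth, width-preserving (hence parameter-free) max-pool before
the bottleneck convolutions, mirrored in the decoder by a parameter-free
nearest-neighbour 2× upsample after the first transposed convolution. The
resulting counts are exact integers the test suite audits: 18,843,200
parameters for encoder + bottleneck and 31,037,798 for the full
embedding-fused model — "31 M". Because all convolutions are zero-padded,
the crop-and-copy of classic U-Nets degenerates to a plain copy and the
output stays at the input resolution.

### The metadata branch and fusion strategies

The metadata vector has width 29 under the default schema: eight one-hot
groups (diagnosis, asymmetry, pigment network, dots/globules, streaks,
regression, blue-whitish veil, border irregularity; 23 columns) plus six
independent binary colour flags. The composition of the 29 columns is a
package choice — the attribute families are the standard dermoscopic
criteria — and any user schema of matching width can replace it via YAML.

For embedding-based fusion, each one-hot group (and each binary flag, via a
2-row table) is embedded into a 4-dimensional vector; embedding dimension 4
is our choice, small enough that the branch stays ~4 k parameters. The
concatenated embeddings pass through dense layers of 36 and $s^2$ units
(ReLU), where $s$ is the bottleneck size — 49 units for the reference 7×7 —
and are reshaped to $s \times s \times 1$. Four fusion strategies are
implemented at the bottleneck:

* `none` — image-only U-Net (the baseline);
* `onehot_dense` — the raw 29-vector through the two dense layers, then
  concatenated as a 1025th channel;
* `weighted` — $w_{img}\,\mathbf{F}_{latent} + w_{meta}\,\mathbf{M}_{embed}$
  with the metadata map broadcast across channels and $w_{img}+w_{meta}=1$
  (70–30 by default);
* `embedding_concat` — $\mathrm{Concat}(\mathbf{F}_{latent},
  \mathbf{M}_{embed})$, the reference configuration.

## Bayesian inference and uncertainty

With `bayesian = TRUE` a dropout layer (default rate 0.5; the rate is a
package choice) follows each two-convolution block. Monte Carlo Dropout
approximates the posterior predictive by keeping dropout active at
inference and averaging $T = 10$ stochastic passes. The binary sigmoid
output $p$ is materialized as a two-class distribution $(p, 1-p)$ so all
estimators share one code path. Per pixel, with $\bar p$ the mean over
passes:

* confidence $C = \max_c \bar p(c)$;
* predictive entropy $H = -\sum_c \bar p(c)\log_2 \bar p(c)$ (total
  uncertainty);
* mutual information $MI = H(\bar p) - \frac1T\sum_t H(p_t)$ (epistemic
  disagreement);
* expected pairwise KL divergence
  $EPKL = \frac{1}{T(T-1)}\sum_{i \ne j} KL(p_i \,\|\, p_j)$.

We use log base 2 throughout (bounded, interpretable bits; the base cancels
under the min–max normalization anyway) and clip probabilities at $10^{-12}$
inside logarithms. `EPKL` is defined over ordered pairs — the literal
"pairwise" reading; a variant averaging $KL(p_t \| \bar p)$ against the
ensemble mean is selectable via `epklMap(..., variant = "mean")`.

Per image, the four means are min–max normalized across the evaluation
cohort (a degenerate cohort maps to 0) and combined into

$$U_{tot} = \alpha C - \beta H + \gamma\,MI - \delta\,EPKL,
\qquad (\alpha,\beta,\gamma,\delta) = (0.4, 0.2, 0.2, 0.2).$$

The sign pattern is kept exactly as printed. Note its quirk: higher
confidence *raises* the score while higher entropy lowers it, so under
these signs a well-calibrated confident model scores high. We deliberately
do not "fix" the signs; `rankByUncertainty()` makes the ranking direction
explicit (`decreasing = TRUE` by default) and refuses to rank reports
normalized on different cohorts, which the cohort fingerprint in every
report enforces. Whether normalization statistics should come from the test
cohort alone was an open choice; we normalize over the cohort being
reported, and record it.

## Training

Losses: pixel-mean binary cross-entropy (probabilities clipped at $10^{-7}$)
and the soft-Jaccard surrogate
$1 - (\sum py + \varepsilon)/(\sum p + \sum y - \sum py + \varepsilon)$ with
$\varepsilon = 1$ — the loss is only *named* in the literature this follows,
so the standard differentiable form is a design decision. Metrics: IoU and
Dice on masks binarized at 0.5, with the both-empty convention of 1.0 and
the exact identity $\mathrm{Dice} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$ used
as a test invariant. Optimization is Adam (default learning rate $10^{-4}$,
batch 16, up to 200 epochs) with checkpointing on minimum validation loss
and early stopping at patience 20. Augmentation applies one geometric
transform — flips, right-angle rotations, or scaling in [0.9, 1.1] with
centre crop/pad (magnitudes are our choices) — identically to image and
mask; since all 29 schema attributes are geometry-invariant, "augmenting
the metadata consistently" means keeping the vector paired and unchanged.

The whole engine (convolution, pooling, transposed convolution, forward and
backward passes, Adam) is implemented in the package via Rcpp/Armadillo and
validated against central finite differences in the test suite.

## The synthetic generator

No external dermoscopy data ship with the package; a seeded generator
produces structurally faithful stand-ins. A lesion is a deformed ellipse
(low-frequency radial harmonics; asymmetry and border-irregularity
attributes deform the outline itself) on a smoothly textured skin-like
background. Each remaining active attribute renders one local, additive
texture overlay — reticular grid, dark dots, radial spokes crossing the
boundary, pale regression patches, blue veil tint, colour blotches — so
the metadata one-hot encodes exactly what is rendered, and toggling one
attribute perturbs only its own support (a tested invariant). The mask is
the exact region indicator *before* edge blurring; contrast, boundary blur
and pixel noise are tunable. One master seed derives an independent stream
per sample and per renderer, so datasets regenerate bit-for-bit from their
manifest regardless of generation order.

`makeAmbiguousTask()` builds the regime where metadata should matter most:
contrast 0.12, boundary blur ≥ 1.5 px, noise sd 0.08 (on the order of the
contrast, so pixel intensity alone is weakly informative), overlays off,
and the contrast *polarity* tied to the diagnosis — darker than background
iff melanoma (prevalence 0.5), lighter otherwise. A pixel classifier
without the diagnosis faces a two-sided mixture; with it, a one-sided
discriminant. These values were fixed once on those design grounds.

What the generator does **not** emulate: hair and ruler artifacts,
multi-lesion images, specular highlights, camera vignetting, or realistic
colour statistics. Passing tests on this data therefore demonstrate the
mechanics of fusion and uncertainty — not clinical performance on real
dermoscopy.

## Desk-scale experiments

Two properties are exercised end-to-end at sizes chosen to keep the full
suite comfortably runnable on a laptop CPU (problem sizes are package
choices):

* *learnability*: a reduced U-Net (32×32 inputs, widths 16/32, bottleneck
  64) trained with the soft-IoU loss at learning rate $10^{-3}$ on 60 easy
  synthetic samples reaches validation IoU ≥ 0.80 within 30 epochs for at
  least 2 of 3 fixed seeds;
* *metadata benefit*: on the ambiguous task (100 samples, 70:10:20 split),
  the embedding-fused model beats the image-only model on mean test IoU
  and shows higher mean confidence and lower mean entropy, mutual
  information and EPKL, averaged over 3 seeds, with Monte Carlo Dropout at
  rate 0.25 and $T = 10$.

The learning rate ($10^{-3}$ rather than the reference $10^{-4}$) and the
reduced dropout rate reflect the much smaller networks in these
experiments.

## Numerical choices and degenerate inputs

* Probability clipping: $10^{-7}$ in BCE, $10^{-12}$ inside uncertainty
  logarithms.
* Mask binarization threshold 0.5 after normalizing by the file maximum, so
  0/1 and 0/255 mask encodings behave identically; metric binarization also
  at 0.5.
* Split sizes use largest-remainder rounding (ties to the earlier
  partition), so they always sum to the cohort size; 200 ids at 70:10:20
  give exactly 140/20/40.
* Degenerate lesions (area < 9 px) are resampled up to 10 times, then
  error.
* Min–max normalization of a constant cohort maps to 0 for all images.
* Ranking ties break lexicographically by id.
* He-uniform initialization for convolutional/dense weights,
  uniform(−0.05, 0.05) for embeddings, zero biases, all seeded.

## Known limitations

* The engine is CPU-only and unoptimized relative to GPU frameworks; the
  reference 224 configuration is practical for parameter audits and single
  forward passes, not for full-scale training.
* Binary segmentation only (`outChannels = 1`); the estimators generalize
  to more classes but the head does not.
* The schema ships with one plausible 29-column composition; real datasets
  will need their own schema files.
* Uncertainty aggregation weights are taken as given, not re-derived.

## A worked example

```{r example, eval = FALSE}
library(LesionSegUQ)

gen <- generatorConfig(imageSize = 32, nSamples = 90, seed = 11)
samples <- generateDataset(gen)
ids <- vapply(samples, function(s) s@id, character(1))
split <- splitDataset(ids, seed = 11)
byId <- setNames(samples, ids)

cfg <- modelConfig(inputSize = 32, encoderWidths = c(16, 32),
                   bottleneckWidth = 64, nPool = 2,
                   fusionStrategy = "embedding_concat",
                   bayesian = TRUE, dropoutRate = 0.25)
fit <- trainModel(buildModel(cfg, seed = 1),
                  byId[split@train], byId[split@val],
                  trainConfig(learningRate = 1e-3, maxEpochs = 30,
                              loss = "iou", seed = 1))

ev <- evaluateModel(fit$model, byId[split@test])
reports <- normalizeMeasures(lapply(byId[split@test], function(s)
  uncertaintyReport(mcdPredict(fit$model, s, T = 10, seed = 1))))
rankByUncertainty(reports, k = 5)
```
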