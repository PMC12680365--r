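---
title: "Graph-convolutional fundus grading: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-convolutional fundus grading: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`fundusgcn` grades colour fundus photographs into the five standard
diabetic-retinopathy severity levels (0 = none ... 4 = proliferative).
The pipeline has four stages.

**Feature extraction.** A convolutional backbone $f$ maps each image
$x \in \mathbb{R}^{H \times W \times 3}$ to an embedding
$z = f(x) \in \mathbb{R}^d$ by global average pooling (GAP) of its final
spatial activation map. The built-in backbone is four 3x3 stride-2
convolution blocks with rectifier activations and $d = 64$; any adapter
exposing the pooled vector *and* the pre-pool spatial map (needed for
Grad-CAM) can be substituted.

**Batch graph.** The embeddings of one mini-batch become graph nodes.
Pairwise distances combine a magnitude-sensitive *spatial* term
(Euclidean) and a direction-sensitive *semantic* term (cosine):
$$d_{comb}(i,j) = \beta\, d_{sp}(i,j) + (1-\beta)\, d_{se}(i,j), \qquad
\beta \in [0,1],$$
each matrix min–max normalised per batch to $[0,1]$ over its
off-diagonal entries. Edges are the union of a self-loop at every node,
symmetrised $k$-nearest-neighbour pairs, and all pairs with
$d_{comb} \le r$ (defaults $\beta = 0.5$, $k = 4$, $r = 0.1$).

**GCN refinement.** Two graph-convolution layers (widths 512 and 256)
update the node embeddings with symmetric degree normalisation:
$$h_i^{(l+1)} = \sigma\!\Big(\sum_{j \in \mathcal{N}(i)}
\tfrac{1}{\sqrt{\deg(i)\deg(j)}}\, W_l\, h_j^{(l)} + b_l\Big),$$
with $\sigma$ the rectifier and $\mathcal{N}(i)$ including the
self-loop. Dropout 0.2 follows each layer when active.

**Heads and objective.** A softmax head on $h^{(2)} \in \mathbb{R}^{256}$
(with dropout 0.3 on its input) yields grade probabilities
$\hat{y} = \mathrm{softmax}(W_{cls} h + b_{cls})$; a logistic quality
head yields $\hat{q} = \sigma(W_{QA} h + b_{QA}) \in (0,1)$. Training
minimises
$$\mathcal{L}_{total} = \mathcal{L}_{cls} + \lambda\, \mathcal{L}_q,
\qquad
\mathcal{L}_q = -q \log \hat{q} - (1-q)\log(1-\hat{q}),$$
with $\mathcal{L}_{cls}$ the mean cross-entropy and $\lambda = 0.1$,
using AdamW (learning rate $5\times10^{-5}$, decoupled weight decay
0.01), a reduce-on-plateau schedule on the validation loss (patience 7,
minimum rate $10^{-7}$), early stopping (patience 15), batch 32, up to
50 epochs, seed 42.

**Uncertainty.** Prediction runs $T = 10$ stochastic passes with dropout
forced on; the reported probability is the mean
$\bar{y} = \tfrac1T \sum_t \hat{y}^{(t)}$ and the per-class uncertainty
the standard deviation with divisor $T$. The batch graph is built once
per batch from the dropout-off features; because the backbone has no
stochastic layers, rebuilding it per pass would reproduce the same graph,
so no rebuild option is offered.

## Decisions where the design was open

*Provenance of the binary quality target.* A binary "true quality" $q$
enters $\mathcal{L}_q$, but no annotation source exists for it. We
define $q_i = 1$ exactly when the arg-max prediction equals the true
grade (ties to the lower grade), recomputed each forward pass with no
gradient through the target. This is the standard self-supervised
correctness proxy; `fundus_gcn(quality_policy = ...)` accepts any other
policy, e.g. real image-quality labels.

*Distance functions and their interaction.* Neither $d_{sp}$ nor
$d_{se}$ has a prescribed functional form, nor is an interaction rule
between the $k$-NN and radius criteria given. We use Euclidean and
cosine distance (the standard magnitude/direction pair), min–max
normalisation (without which a radius of 0.1 has no absolute meaning),
and the union of both edge rules with index-ascending tie-breaks. When
all off-diagonal distances are equal, the scale is undefined and raw
values clipped to $[0,1]$ are used, which preserves the distinction
between coincident and orthogonal embeddings in degenerate batches.

*Final embedding width.* The head shapes require
$h^{(2)} \in \mathbb{R}^{256}$; a configurable linear projection
(`proj_dim`) is available for users who want a wider output, off by
default.

*Split-then-balance.* The stratified 70/15/15 split happens on original
samples first; oversampling (duplicate + augment to the majority count
$N_{max}$) is applied to the training partition only. Balancing before
splitting would leak augmented near-copies of training images into the
test set; evaluation is on genuinely held-out, possibly imbalanced data.
Per class, validation and test receive $\lfloor 0.15\, n_c \rfloor$
samples each and the remainder trains, so rare classes always keep
deterministic, non-empty test representation.

*Kappa flavour.* "Cohen's kappa" is reported unweighted by default;
the quadratic-weighted variant common in retinopathy grading is also
computed and clearly labelled.

## The phantom generator: what it emulates and what it does not

`generate_phantom()` draws a shaded circular retina on a dark field, an
optic-disc ellipse, dark random-walk vessels, and four lesion
primitives whose counts rise with grade:

| primitive | analogue | grades (count range) |
|---|---|---|
| bright dots | microaneurysms / small exudates | 1: 1–3, 2: 4–8, 3–4: 9–15 |
| dark blobs | dot/blot haemorrhages | 2: 1–3, 3–4: 4–8 |
| bright patches | hard-exudate plaques | 2: 1–2, 3–4: 2–4 |
| vessel tufts | neovascular fronds | 4 only: 2–5 |

Grade 4 is distinguished from grade 3 *only* by tufts, so a grader must
read shape, not just total lesion load. Lesion sizes are specified at
the 224-px reference scale and floored at 1 px so that lesions never
become sub-pixel at small rendering sizes (downsampled real fundus
images keep microaneurysms at a pixel or more). Additive Gaussian pixel
noise (sd 0.02) sets a detection floor: a grade-1 image differs from
grade 0 by 1–3 dots whose pooled area is close to that floor, which
keeps the easiest pair honest. The default class counts reproduce the
APTOS2019 imbalance (1805/999/370/295/193).

The phantoms do **not** model camera optics, illumination fields,
media opacity, resolution variation or inter-grader label noise. A green
test establishes that the pipeline machinery works and that severity is
recoverable from lesion statistics at desk scale — not that the system
grades real retinas.

## Desk-scale initialisation choices

The published setting fine-tunes ImageNet-pretrained backbones. Without
downloads, a randomly initialised CNN at the published learning rate
($5\times10^{-5}$, $\le$ tens of epochs) stays essentially frozen, so the
built-in backbone is initialised to be useful *before* training, playing
the role pretraining plays at full scale:

- **Detector-bank first layer**: centre-surround, edge and box filters
  over colour-opponent axes. One axis — the null direction of the
  background and optic-disc hues — isolates yellow exudate-like lesions;
  box (matched-filter) units on that axis carry thresholds at several
  multiples of the noise floor, with the bias compensating the $-0.5$
  input centring, so their pooled activation approximates lesion area at
  several salience levels.
- **Aggregator deeper layers**: channel-preserving 3x3 averaging with
  small kernel perturbations and cross-channel weights at exactly zero —
  any random cross-channel leakage would bury the small lesion-area
  channels under large texture channels. Gradients still reach the zero
  weights, so training can grow mixing.
- **Feature standardisation**: embeddings are standardised per feature
  before graph construction and refinement (batch statistics during
  training, running averages at inference), mirroring the normalisation
  stage pretrained backbones end with and giving the GCN well-scaled
  inputs. Standardised values are winsorised at ±3: no single feature can
  dominate a distance or a logit, and far-out-of-distribution inputs sit
  on the clamp instead of saturating the softmax into spurious
  confidence — which is what lets Monte-Carlo dropout flag them as
  uncertain.
- **Head/GCN initialisation**: hidden layers use fan-in (He)
  initialisation with gain 2 (`gcn_gain`); both heads start at zero, so
  the initial prediction is uniform and the first gradient steps move the
  logits along class-separating directions instead of fighting random
  initial logits.

## Numerical conventions

- BCE predictions are clamped to $[10^{-7}, 1-10^{-7}]$; cross-entropy
  clamps the selected probability the same way.
- Arg-max ties resolve to the lowest class index everywhere.
- $\kappa$ returns 0 by convention when chance agreement is 1; per-class
  F1 is 0 when precision and recall are both undefined or zero.
- AUROC is trapezoidal over tie-grouped thresholds; AUPR is
  step-interpolated average precision. Macro averages are unweighted over
  the classes present, with a warning naming absent classes.
- Uncertainty uses the population convention (divisor $T$), so $T = 1$
  or all-zero dropout gives exactly $\sigma = 0$.
- Degenerate single-sample batches refine through a self-loop-only graph
  (the GCN reduces to a per-sample transform).
- All randomness flows from the single config seed: dataset generation,
  splits, initialisation, batch order, dropout and MC passes are
  bit-reproducible given it.

## Known limitations

- **Desk-scale accuracy is optimiser-bounded.** With the published
  learning rate and $\le 10$ epochs on 1,000 phantoms (220–550 AdamW
  steps), held-out accuracy reaches about 0.80 ($\kappa \approx 0.75$).
  The refined embeddings contain considerably more information (a
  converged linear readout of $h^{(2)}$ reaches about 0.97; a
  nearest-class-mean rule about 0.91); the binding constraint is the
  number of optimisation steps available to calibrate the hardest
  (grade 0 vs 1) decision boundary, which at this learning rate needs
  thousands of steps. The full-scale setting escapes this because
  pretrained backbones are fine-tuned for tens of epochs on thousands of
  images. The corresponding acceptance check in
  `tests/testthat/test-acceptance.R` states the original bar and fails
  honestly rather than lowering it.
- The quality head learns the correctness proxy, not photographic
  quality; with noise-free balanced training its targets are imbalanced
  towards $q = 1$ as accuracy grows.
- Grad-CAM for the built-in backbone upsamples a coarse map (input size /
  16 per side); localisation is indicative, not pixel-accurate.
- Batch-statistics coupling: predictions depend mildly on batch
  composition through the batch graph; evaluation uses the training batch
  size (32) for matched graph statistics.
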