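---
title: "Ageing-related dynamic attention: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ageing-related dynamic attention: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ardaceph)
```

## The method in outline

`ardaceph` quantifies *where* a convolutional age regressor looks on
grayscale lateral-cephalometric-style images and how that attention
redistributes with age. The pipeline has five stages.

**1. Age regression.** A CNN $f$ maps a preprocessed image $x$ to a
predicted age $\hat y = f(x)$, trained by minimizing the mean absolute
error
$$L = \frac{1}{N}\sum_{n=1}^{N} \lvert y'_n - y_n \rvert,$$
the natural loss when errors are reported in years and robustness to
outlying ages matters.

**2. Ageing salience (Grad-CAM).** Let $F^k$ be the $k$-th map of the
last convolutional layer before global pooling ($h \times w$, $Z = hw$
pixels). The weight of each map is the spatial mean of the output
gradient,
$$w_k = \frac{1}{Z}\sum_i\sum_j \frac{\partial \hat y}{\partial F^k_{ij}},$$
and the salience map is the rectified weighted sum
$M = \mathrm{ReLU}\big(\sum_k w_k F^k\big)$. Because the output is a
scalar age, $\hat y$ itself is the backpropagated quantity; no class
selection is involved. $M$ is upsampled bilinearly to the image grid
and min-max normalized to $[0,1]$ per subject.

**3. ARDA aggregation.** Salience maps of all subjects with the same
completed age $a$ are averaged element-wise,
$$A_a = \frac{1}{N_a}\sum_{n=1}^{N_a} M_{a,n}, \qquad a \in \{4,\dots,40\},$$
giving one ageing-related dynamic attention (ARDA) map per integer age.

**4. Quantification.** For each age, the *ageing-significant region* is
the set of $A_a$ pixels at or above the median, 75th or 90th percentile
of that map's own values (linear-interpolation quantiles, ties included
by `>=` so a constant map is entirely significant). The *quantified
ARDA* of an anatomical instance is the mean of $A_a$ over the
intersection of the instance mask with the significant region; an empty
intersection is recorded as missing, never as zero, since a zero would
masquerade as measured salience.

**5. Constrained training and retest.** For subjects older than a
cutoff `KA`, the subject's own salience map (from the frozen baseline)
is concatenated to the image as a second input channel and a
two-channel model is trained with the same loss; younger subjects
receive a zero channel so one network serves both regimes. At
inference, the baseline predicts $\hat y_1$; only if $\hat y_1 > KA$
(strictly) is the constrained model consulted, and its prediction is
final. There is exactly one retest round.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `targetSize` | 224x224 (network-specific) | preprocessed image size; phantom studies use 64x64 |
| CLAHE clip limit | 2 (tile-histogram multiple), 8x8 tiles | contrast enhancement before padding/resizing |
| affine bounds | rotation ±10°, translation ±5%, scale 0.9–1.1, flip 0.5 | mild, label-preserving augmentation |
| split fractions | 0.70 / 0.15 / 0.15 | per-age-group stratified train/val/test |
| `epochs`, `batchSize`, `lr` | 30, 32, 1e-3 cosine-decayed | Adam with decoupled weight decay 0.01 on weights |
| threshold levels | median, p75, p90 | ageing-significant region percentiles |
| `KA` | 25 years | retest cutoff; the metric suite reports 4–25 and 26–40 super-groups, making 25 the natural cutoff; fully configurable |

Two trainer details deserve a note because they matter for attribution,
not just accuracy. The head bias is initialized to the mean training
age: otherwise the network's early training absorbs the large constant
offset (mean age ≈ 22 y) into whatever constant-activation features are
handy — typically bright static structures — which then read as
spuriously high salience forever after. Decoupled weight decay (0.01,
weights only) gives features whose activations carry no age signal a
gentle pull toward zero. Both are standard regression practice.

## The synthetic phantom

The phantom emulates the study conditions without clinical data:
2D grayscale "radiographs" with ages uniform on [4, 40] years (decimal,
rounded to hundredths), a blank background, additive truncated-Gaussian
acquisition noise clipped to $[0,1]$, and labeled instances whose
linear size follows a piecewise-multiplicative age response
$$s(a) = (1+r_\text{young})^{\min(a,b)-4}\,(1+r_\text{old})^{\max(a-b,0)}$$
with a stage break $b$ (default 18 y) separating fast development from
slow ageing — the two regimes the method is meant to expose. Rendered
area therefore grows as $s(a)^2$, which the tests check against the
closed form.

The default instance set is one fast-changing tooth row
(5%/y then 1%/y, periodic texture, intensity 0.9), one slow-changing
cranial ellipse (3%/y then 0.8%/y, solid, 0.7) and one static block
(solid, 0.3). Two design requirements emerged from building the
recovery tests and are worth stating explicitly:

* **Local distinguishability.** Instances must differ in local
  appearance (intensity or texture), as real tissues differ in
  attenuation. A static distractor rendered pixel-identically to an
  ageing structure poses an *unidentifiable* attribution problem — no
  method that scores local evidence could separate the two interiors —
  so such a phantom would test nothing.
* **Feature-grid visibility.** Instances must be solid enough to
  register at the final feature resolution (input/4). Structures much
  thinner than one feature cell (e.g. a thin ring) have their
  activations diluted by background within each cell and their
  salience systematically underestimated — a real limitation of
  coarse-grid Grad-CAM worth remembering when drawing instance masks
  on real images.

What the phantom deliberately does **not** emulate: anatomical shapes
and overlap of projected tissues, intensity inhomogeneity, detector
artifacts, gender effects, or correlated (non-stationary) noise.
Passing the recovery tests therefore shows that the pipeline's
machinery — training, attribution, aggregation, thresholding,
quantification — recovers a known planted age signal; it does not by
itself validate attention maps on clinical radiographs.

## Numerical choices

* Ages are binned to completed years (`floor`) for ARDA aggregation.
* Quantiles use R's default linear interpolation (type 7); masks use
  `>=` so constant maps stay well defined and masks nest:
  p90 ⊆ p75 ⊆ median.
* Percentile thresholds are computed over all pixels of the per-age
  ARDA map. The per-image reading (thresholding each subject's own
  map) is available and is what `instanceStats()` uses to build
  per-subject distribution bands.
* Bilinear resampling uses the half-pixel center convention with
  border clamping; label maps always travel by nearest neighbor.
* Per-map min-max normalization precedes aggregation (a zero map stays
  zero) so subjects contribute on a common scale; rendering normalizes
  for display only and never feeds back into quantification.
* Region boxes use (x = column rightward, y = row downward), origin at
  the top-left, half-open intervals, fractional corners floored. The
  100-pixel offsets of the box table assume ~2144-px frames
  and scale proportionally (`round(100 * W / 2144)`) below 300 px.
  "Discard" masks the box to zero rather than cropping, so all discard
  conditions share the baseline's input geometry.
* The constrained model's salience channel is the subject's own
  Grad-CAM map from the frozen baseline, at train and at test time;
  looking up the population ARDA map of the predicted age instead is a
  plausible alternative we did not adopt, because the per-subject map
  is what the retest procedure can actually compute at inference.
* Sub-`KA` subjects are included in constrained training with a zero
  channel rather than excluded, so a single two-channel network covers
  every retested subject.

## Problem sizes

Phantom studies in the tests and the acceptance script use 2000
subjects at 64x64 with zero noise and 30 training epochs; unit tests
use 32x32 cohorts of 60–160 subjects and a few epochs. These sizes were
chosen so a complete study trains in minutes on a single CPU while
leaving the recovery properties clearly resolved (test MAE ≈ 1.2 y
against a constant-predictor baseline of ≈ 9 y).

## Known limitations

* Grad-CAM at input/4 resolution cannot attribute finer than one
  feature cell; thin structures are penalized (see above).
* Attribution is relative within an image: salience says which regions
  carry more age evidence than others, not how much a tissue changes
  in physical units.
* The tiny CNN is a vehicle for the method at desk scale; the
  EfficientNet-B0 stage plan is shipped as an architecture ledger
  (faithful stage table and exact parameter arithmetic) rather than a
  trainable network.
* DICOM input is not supported in this environment; images arrive as
  PNG or in-memory matrices in $[0,1]$.
* `MCS-5` is implemented as the mean of CS-1..CS-5 — one standard
  reading of "mean cumulative score" — and is isolated in a single
  function so another definition can be swapped in.
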