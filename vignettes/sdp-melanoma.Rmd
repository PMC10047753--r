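---
title: "Sobel Directional Patterns and stacked RBMs for dermoscopy lesion classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sobel Directional Patterns and stacked RBMs for dermoscopy lesion classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sdpskin)
```

This vignette is the package's account of its science: the model behind each
stage, the tunable parameters and why their defaults are what they are, what
the synthetic data generator does and does not emulate, and the numerical
choices that make the pipeline deterministic.

## The problem

Melanoma is distinguished from benign pigmented lesions by cues a
dermatologist reads visually: asymmetry, border irregularity, multiple hues,
uneven texture, diameter. A descriptor for automated triage should therefore
respond jointly to *edges* (borders), *texture* (pigment networks) and
*colour* (hue multiplicity), and should be robust to the illumination
differences between capture devices. The package implements such a
descriptor — the Sobel Directional Pattern (SDP) — together with the
preprocessing, segmentation, classification and evaluation stages needed to
use it end to end.

## Hair removal

Dark hairs are a dominant artifact in dermoscopy. Detection follows the
DullRazor recipe: grayscale morphological closing with linear structuring
elements at 0°, 45°, 90° and 135° (default length 9 px) raises dark thin
structures on each colour channel; the maximum closing residual over
orientations and channels is thresholded (default 10 on the 8-bit scale).
Candidate components are kept only when *thin and extended*: mean width at
most 5 px and skeleton-length/width at least 5. Width is estimated as
`2 * area / perimeter` — the ribbon model — because a moment-based major
axis underestimates the length of curved hairs and misclassifies them as
thick. Flagged pixels are repaired by linear interpolation between the
nearest unflagged pixels on either side along the component's minor axis
(across, not along, the hair), followed by an adaptive median filter
(window growing 3 → 7) confined to the 1-px-dilated mask, so no pixel
outside the mask neighbourhood is ever altered.

All structuring-element lengths and thresholds are package choices — the
DullRazor family of methods names the operations but fixes no parameter
values — and are exposed in `hair_config()`.

## Segmentation

Semantic-segmentation networks are one route to lesion masks but require
training data the package deliberately does not assume. The package
implements the classical route — Otsu's threshold on BT.601 luminance with the lesion on
the darker side, opening and closing with a disc of radius 5, rejection of
components touching two or more image borders (vignette artifacts),
retention of the largest remaining component, region growing from its
darkest-decile seeds with tolerance 0.08 in normalized luminance, and hole
filling — and accepts externally supplied masks through `lesion_mask()`, so
any other mask source (including a trained network) can be plugged in
without touching the rest of the pipeline. Segmentation is invariant to
constant intensity offsets because both the Otsu threshold and the
region-growing criterion shift with the histogram.

## The SDP descriptor

### Opponent channel pairs

A channel triple (HSV by default; RGB and YCbCr are supported and can be
pooled) yields six pairs: the centre pixel of each 3×3 block comes from
channel $X$, the eight neighbours from channel $Y$, for
$(X,Y) \in \{HH, SS, VV, HS, HV, SV\}$. The hue channel is rescaled linearly
from its angle and treated as an ordinary channel; its circular topology is
*not* folded, which keeps the construction identical across channels at the
cost of a wrap discontinuity for reds — an accepted simplification.

### Fractional Sobel compass masks

The Grünwald–Letnikov fractional difference has weights
$w_j = (-1)^j\binom{\alpha}{j}$; three terms fit a 3×3 kernel, and the unit
pixel step absorbs the $1/m^\alpha$ prefactor. The base (horizontal) kernel
is the outer product of the Sobel smoothing weights $(1,2,1)$ across rows
with a derivative stencil across columns. The three GL weights are assigned
leading-to-trailing along the derivative axis — $w_0 = 1$ on the leading
sample, $w_1 = -\alpha$ on the trailing sample, and the residual weight
$w_2 = \alpha(\alpha-1)/2$ at the centre — so that $\alpha = 1$ reproduces
the classical central-difference Sobel kernel *exactly*, which is the
anchoring property of the construction. The natural one-sided placement
(weights on offsets $+1, 0, -1$) cannot satisfy that anchor, so the package
treats Sobel degeneracy as the binding constraint; the left mask leads to
the right and the right mask is its mirror, preserving the forward/backward
asymmetry for $\alpha < 1$.

Eight orientations are generated by rotating the eight outer kernel cells
one ring position per 45° step (compass convention). Every kernel is then
made **DC-free by subtracting its mean**. This is the single most
consequential implementation decision: the truncated GL stencil does not sum
to zero for $\alpha < 1$, and a non-zero DC component would couple the
response to absolute intensity, destroying the illumination-offset
invariance that motivates the descriptor. With DC removal the invariance is
exact and is asserted in the test suite.

The gain $\lambda$ (default 3.5, with {3.5, 7, 14, 28, 56} as the
conventional ladder) enters as a pure multiplicative factor. The package
supports max-pooling code images across a
$\lambda$ set, but because each code image is max-normalized, a pure gain
cancels — multi-scale pooling is therefore off by default and documented as
a structural hook rather than an active mechanism.

### Code images, DoG and grid histograms

Each pixel receives 16 responses (8 orientations × left/right). The
maximum forms the code image; ties break to the lowest orientation index,
left before right; negative maxima are clamped to zero and the image is
rescaled by its maximum (a maximum below $10^{-12}$ — pure rounding noise of
the DC-free kernels on constant inputs — maps to an all-zero image). The
winning index is retained internally only for the rotation-covariance test:
rotating the input a quarter turn advances the winning compass orientation
by two 45° steps at interior pixels.

The code image is convolved with a Difference of Gaussians
$D = G(\sigma_1) - G(\sigma_2)$, $\sigma_1 = 2 > \sigma_2 = 1$, truncated at
radius $\lceil 3\sigma_1 \rceil$ with each Gaussian normalized to unit sum
(so $D$ has near-zero DC), then min–max rescaled. Finally the image is
partitioned into a $4 \times 4$ grid (remainder pixels join the last
row/column of cells) and each cell is histogrammed into 16 uniform bins on
$[0,1]$ (final bin right-closed), normalized to unit mass, and concatenated
row-major: spaces → pairs (11, 22, 33, 12, 13, 23) → cells → bins, giving
$6 \cdot 16 \cdot 16 = 1536$ features for HSV alone.

All convolutions use reflect padding with edge duplication; every
convolution, coding and binning operation is checked against brute-force
nested-loop oracles on random small images in the test suite.

The default order $\alpha = 0.5$ sits mid-range of the admissible $(0, 1]$;
the package ships `sweep_alpha()`, a cross-validated k-nearest-neighbour
(k = 3) harness over an $\alpha$ grid, which is the procedure by which an
order would be selected for a new image domain.

## The stacked RBM classifier

Features are min–max normalized per column using training statistics only
(constant columns map to 0.5; application values are clipped), then passed
through a stack of Bernoulli RBMs trained greedily: each layer learns on the
previous layer's hidden activation *probabilities*. Training uses persistent
contrastive divergence — one persistent fantasy chain per batch slot,
advanced one Gibbs step per update — with momentum-smoothed gradients.
Defaults: learning rate 0.1, momentum 0.7, batch size 25, at most 300
epochs, early stopping after 3 consecutive epochs without improvement of
the mean one-step reconstruction error, hidden widths (256, 64). The width
schedule is a package choice; the scalar settings are standard stacked-RBM
practice and the momentum is a single constant coefficient (no delay
schedule). Automated hyperparameter search is out of scope; `sweep_alpha()`
plus the exposed `rbm_hyperparams()` fill the tuning role at desk scale.

The supervised top layer is multinomial logistic regression fitted by
maximum likelihood (`nnet::multinom`) on the final hidden probabilities; its
coefficients are stored explicitly and inference is a deterministic
mean-field forward pass with a softmax — no sampling — so identical
data, hyperparameters and seed give bit-identical models and predictions.
There is no backpropagation through the stack; training is purely
layer-wise. An empty width schedule degenerates
to plain multinomial logistic regression, which is also the honest baseline
against which the stack should be compared on new data.

## Metrics and cross-validation

Per class, one-vs-rest: accuracy, specificity TN/(TN+FP), sensitivity
TP/(TP+FN), positive predictive rate TP/(TP+FP), F-score, and the
sensitivity–specificity harmonic mean. Ratios with zero
denominators are reported as missing, never silently as zero. Multi-class
summaries are unweighted (macro) averages; the overall fraction correct is
reported alongside. Cross-validation uses seeded stratified folds (default
10) with the fold counter running across classes so fold sizes stay
balanced; `k = n` is accepted as exact leave-one-out. All preprocessing
statistics (feature min/max) are fitted inside each fold's training data
only.

## The synthetic study set

The generator emulates the statistical structure the descriptor assumes,
not the appearance of any real dataset: a skin-toned background with a
smooth illumination gradient and Gaussian noise (sd 3 intensity levels); a
star-convex lesion whose boundary radius perturbs an ellipse by low-order
sinusoids with class-dependent amplitude (border irregularity); a fill
mixing a class-dependent number of tones selected by smooth random fields
and modulated by a sinusoidal texture at class-dependent frequency; and
optionally 3–8 dark hair strokes of width 1–3 px along random smooth
curves. The three presets order the cues monotonically — common-nevus-like
(irregularity 0.05, 1 hue), atypical-like (0.18, 2 hues), melanoma-like
(0.38, 4 hues, darker and blue-grey tones) — mirroring the clinical triad
and giving the descriptor a real signal to detect. Masks are exact by
construction, so segmentation Dice scores are well defined, and every
sample is a pure function of its seed.

What the generator does **not** emulate: specular reflections, ruler and
gel artifacts, vignetting, camera colour profiles, pigment-network
micro-structure, or the intra-class diversity of real lesions. Passing the
synthetic study therefore demonstrates that the implementation is correct
and that the descriptor separates the cues it claims to encode — not that
the reported real-dataset accuracies transfer.

The default study size is 150 images (50 per class) at 128 × 128 pixels
with 10-fold cross-validation — large enough for stable fold estimates
while keeping a full run of the pipeline in the low minutes on a single
CPU; the 760 × 570 working-size convention is exercised separately by the
resize stage.

## Numerical choices and degenerate inputs

* Reflect padding (edge-duplicating) everywhere; borders are excluded only
  in the rotation-covariance test.
* Ties in the maximum response break to the lowest orientation index, left
  mask before right; prediction ties break to the first class label.
* Constant images: hair detection returns an empty mask (closing is the
  identity); segmentation raises a "no lesion found" error; code images map
  to all zeros.
* Chroma channels of the full-range BT.601 transform can reach 255.5 at
  saturated corners and are clamped to [0, 255] before normalization.
* All RNG use is confined with a save/restore wrapper, so library calls
  never perturb the caller's RNG state; every stochastic routine takes an
  explicit seed.

## Known limitations

* Hair recall degrades where hairs cross dark, highly textured lesions —
  the closing residual vanishes when hair and background intensities
  coincide. The repair error still decreases monotonically in practice, and
  the composition never touches pixels outside the detected mask.
* The descriptor treats hue as linear; deeply red lesions spanning the hue
  wrap will split one hue mode into two.
* Multi-scale $\lambda$ pooling is structurally supported but inert under
  max-normalization (see above).
* The stacked RBM is trained unsupervised; on small studies a plain
  multinomial logistic layer on raw SDP features can match or exceed it.
  The stack's value is expected at larger sample sizes.
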