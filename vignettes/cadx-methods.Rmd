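---
title: "Methods: SDAE-based CADx and its conventional baselines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SDAE-based CADx and its conventional baselines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`sdaecadx` implements a computer-aided diagnosis (CADx) framework for the
benign/malignant differentiation of lesions in 2-D ultrasound (US) regions
of interest and nodules in multi-slice CT stacks. Its centerpiece is a
stacked denoising autoencoder (SDAE) classifier; around it sit two
conventional texture pipelines (RANK and CURVE), a clinical morphology
baseline (MORPH), slice-selection strategies with majority voting, and a
repeated cross-validation harness. Because clinical image collections
cannot be redistributed, the package ships a seeded synthetic-image
generator that reproduces the statistical structure the classifiers rely
on; every empirical statement in the test suite is made on that synthetic
material.

# The SDAE classifier

## Model

Each ROI is cropped around its lesion mask, bilinearly resized to a
28×28 patch and min–max normalized to $[0,1]$. A single denoising
autoencoder (DAE) with input $x \in [0,1]^d$ corrupts the input by
*masking noise* — exactly $\lfloor \nu d \rfloor$ coordinates, drawn
uniformly without replacement, are set to 0 — and reconstructs

$$h = \sigma(W\tilde{x} + b_{enc}), \qquad
  z = \sigma(W^{\top}h + b_{dec}),$$

with tied weights and the mean cross-entropy reconstruction loss

$$L(x, z) = -\tfrac{1}{d}\sum_i \big[x_i \log z_i + (1-x_i)\log(1-z_i)\big],$$

$z$ clipped to $[10^{-7}, 1-10^{-7}]$ so the loss is always finite.
Gradients are analytic (the decoder pre-activation gradient is the scaled
residual $(z-x)/d$) and optimized by mini-batch SGD.

The stack is built greedily: layer 1 (784 → 200) is trained on patch
vectors, layer 2 (200 → 100) on the *clean* layer-1 codes. Whether
corrupted or clean codes feed the second layer was a genuinely open
design point; clean codes were chosen because each layer's own corruption
already provides the denoising pressure, and the convention keeps the
layer-2 training distribution identical to the codes used at prediction
time.

For supervised fine-tuning the network gains (i) three auxiliary input
neurons carrying the resize scale factors of both dimensions and the
aspect ratio (width/height) of the original crop, z-scored with
training-fold statistics, and (ii) a 2-class softmax head. The auxiliary
inputs are wired only into hidden layer 1 through a matrix initialized to
zero, so the first fine-tuning forward pass is exactly the pretrained
encoding; the softmax head starts with small seeded uniform noise. The
whole network is then trained by back-propagation on the softmax
cross-entropy. An exact probability tie of 0.5 is resolved to *benign*
(favoring specificity); malignant is the positive class everywhere.

## Defaults and why

| parameter | default | rationale |
|---|---|---|
| hidden sizes | 200, 100 | two-layer architecture used throughout |
| corruption level $\nu$ | 0.3 | canonical masking fraction for SDAEs |
| pretraining | lr 0.1, batch 20, 15 epochs | stable for sigmoid + cross-entropy on [0,1] pixels |
| fine-tuning | lr 0.05, batch 20, 100 epochs | smaller steps once the head is attached |
| weight init | $U(\pm 4\sqrt{6/(d_{in}+d_{out})})$, zero biases | standard sigmoid scheme |

All are `train_spec()` arguments. Sigmoid activations with cross-entropy
reconstruction are an assumption of this implementation (the activation
family is not dictated by the architecture itself); they match the
$[0,1]$ patch normalization.

# Conventional baselines

**RANK** (ultrasound texture): the ranklet transform computes, at every
window position, the rescaled Mann–Whitney statistic
$2U/(n_T n_C) - 1 \in [-1,1]$ between Haar-like treatment and control
half-windows (vertical, horizontal, diagonal splits; ties credited ½ via
midranks). Being a rank statistic it is *exactly* invariant to monotone
intensity transforms — the property that makes it robust to speckle.
Responses are requantized and summarized by gray-level co-occurrence
matrix (GLCM) statistics: a 12-feature Haralick subset per angle,
averaged over the four angles. Feature selection uses the bootstrap: in
each of $B$ resamples features are ranked by two-sided single-feature AUC,
$\max(\mathrm{AUC}, 1-\mathrm{AUC})$, and features appearing in at least
$\tau B$ of the top-$k$ lists are kept. The two-sided criterion is a
deliberate choice: a feature that separates the classes in the reverse
direction is exactly as useful to the downstream SVM, and a literal
one-sided AUC ranking would place a perfect reverse separator last.

**CURVE** (CT texture): a pluggable sub-band decomposition — by default a
2-level separable orthonormal Haar wavelet giving 7 bands, written
in-package with a perfect-reconstruction test — followed by the full
14-feature Haralick set per band, averaged over angles. The decomposition
is a stand-in front-end: the pipeline structure (decompose → GLCM →
angle-average → SVM) is what is reproduced here, and any band-producing
function can be plugged in.

**MORPH** (clinical morphology): from masks only. 2-D lesions: area and
the major-axis length of the moment-matched ellipse
($4\sqrt{\lambda_{\max}}$ of the coordinate covariance — exact for a
filled continuous ellipse). Nodule stacks: volume $\sum_j A_j \cdot t$
(slice areas times thickness — an approximation that inherits the slice
discretization), the maximum per-slice major diameter, and the maximum
slice area. "Major diameter" is interpreted slice-wise (the maximum over
member slices of the in-plane ellipse major axis), not as a 3-D diameter.

All three baselines share one SVM stage (`e1071`/libsvm; RBF kernel,
$C = 1$, $\gamma$ = 1/(d·var), training-fold standardization). The shared
configuration is intentional: the comparison contract is that all
methods see identical folds and an identically configured classifier.

# Slice strategies and voting

`SINGLE` represents a nodule by its middle slice, index
$\lfloor (n-1)/2 \rfloor$ (the lower middle for even $n$ — the tie-break
is a documented convention). `ALL` pools every member slice of the
training cases in seeded random order; at test time a nodule is called
malignant iff *strictly more than half* of its slice predictions are
malignant, so an exact half resolves to benign. Voting uses hard labels
(a count rule), but the case-level *score* under `ALL` — needed for AUC —
is the mean slice malignancy probability/score, since a hard-label vote
carries no ranking information.

# Evaluation protocol

`make_folds()` draws 10 repetitions of stratified 10-fold partitions at
the *case* level: all slices of a case stay on one side of every split,
which the harness re-asserts at run time. Stratification by class is a
design choice (plain random partitions would occasionally starve a fold
of one class at the small sample sizes used here); repetition
distinctness is enforced by rejection on a canonical partition signature.
Six metrics are reported per fold: AUC (tie-corrected rank statistic,
identical to Mann–Whitney $U/(n_1 n_0)$), ACC, SENS, SPEC, PPV, NPV.
Ratios with zero denominators are `NA`, never 0, and NA folds are
excluded from (not imputed into) that metric's mean. Method agreement is
summarized by Bland–Altman statistics (mean difference ± 1.96 sample SD
limits) and a pooled-variance two-sample t-test on per-fold values, with
the zero-variance/equal-means case defined as $t=0, p=1$.

# The synthetic generator

**What it emulates.** US mode: a hypoechoic star-convex lesion
($r(\theta) = r_0(1 + a \sum_k c_k \sin(k\theta + \phi_k))$, harmonics
$k = 2..7$ standardized to unit RMS so the amplitude $a$ is directly the
RMS radial modulation) on an echogenic background with mild depth gain,
degraded by multiplicative mean-one Rayleigh speckle of configurable
strength, optionally with posterior shadowing, then log-compressed and
quantized to 8 bits. CT mode: an ellipsoidal nodule sliced at configurable
thickness; the middle slice cuts the equator, per-slice masks are the
exact analytic cross-sections, lobulation reuses the same harmonic
machinery coherently across slices. Masks always come from the analytic
boundary — they stand in for manual outlines, and no segmentation is
simulated.

**Class signal.** In US mode the class enters *only* through the
configured effect parameters — boundary irregularity (default benign
0.05, malignant 0.30) and texture contrast (0.05 vs 0.25); size and
orientation are drawn identically for both classes. This makes the
null-calibration property testable: with effect parameters set equal the
mask statistics of the two classes are exchangeable by construction. In
CT mode malignant nodules are additionally larger (in-plane semi-axes
5–10 mm vs 3–7 mm), matching the clinical fact that size itself is
diagnostic for pulmonary nodules and giving the morphology baseline a
real signal to find. Default speckle 0.6, shadowing probability 0.25,
US pixel spacing 0.15 mm, CT 0.7 mm, all configurable.

**What it does not emulate** — and hence what passing tests do and do not
show: speckle is spatially uncorrelated (real speckle has a correlation
cell set by the point-spread function); there are no acoustic artifacts
beyond a simple shadow band, no anatomy, no scanner or annotation
variability; CT background is homogeneous parenchyma without vessels; and
the class-conditional distributions are far cleaner than clinical data.
Success on this material validates the *machinery* (gradients, pipelines,
protocol), not clinical performance; the headline clinical numbers of a
real deployment are out of reach of any synthetic phantom of this kind.

# Numerical choices

- Bilinear resize with half-pixel center alignment; the 28×28→28×28
  mapping is exactly the identity, making patch production idempotent on
  the 8-bit grid. The kernel is written in-package so its semantics are
  pinned by tests rather than inherited from an external image stack.
- Min–max patch normalization maps constant crops to all-zeros rather
  than NaN.
- Masking corruption uses an exact count, not Bernoulli draws: the
  corrupted fraction is deterministic, which both matches the stated
  fraction exactly and makes tests sharp.
- `plogis` is used as the sigmoid: it saturates without overflow at
  logits of ±500 and beyond.
- All randomness is seed-scoped (`withr::with_seed`), so every seeded
  run — generation, pretraining, fine-tuning, folds — is bit-reproducible;
  per-fold seeds are derived arithmetically from the plan seed.
- GLCM quantization is uniform binning of $[0,1]$ into `levels` bins
  (default 16; 8 for the compact ranklet response images).
- Bounding-box margins expand each side by `ceiling(margin × extent)`
  before clipping.

# Problem sizes used in the shipped checks

The test-suite and acceptance-script runs use deliberately scaled
problem sizes chosen to exercise every code path at desk scale: the
end-to-end US experiment uses 500 cases per class (400 train / 100 test)
across 10 seeds; the CT voting harness uses 30 cases per class with 2–4
slices each under the full 10×10-fold grid; texture-stack checks use a
300-case US subset. Oracle checks (finite differences, pair enumeration,
closed forms) run on small random instances where brute force is exact.

# Known limitations

- The curvelet-style decomposition is represented by its pluggable
  stand-in; directional selectivity beyond the three separable wavelet
  orientations is not provided in-package.
- The published feature subsets of the original RANK/CURVE systems are
  not reproduced; the bootstrap selector regenerates a subset on the data
  at hand.
- `run_experiment` with the SDAE over the full 10×10 grid is
  computationally heavy in pure R; the shipped experiments demonstrate it
  with the fast baselines and validate the SDAE end-to-end on split
  designs.
- MORPH is case-level by construction and ignores the slice strategy.
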