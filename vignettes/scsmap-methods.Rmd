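---
title: "Sharpened cosine similarity classification of hyperspectral tissue scenes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sharpened cosine similarity classification of hyperspectral tissue scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scsmap)
```

## The problem

Intraoperative hyperspectral imaging records, for every pixel of a tissue
surface, a full reflectance spectrum across hundreds of narrow bands. Tissue
types — normal tissue, tumor, blood vessels, and surgical background — have
distinct spectral signatures, so a labeled cube (a raster $X \in
\mathbb{R}^{(M \times N) \times B}$ plus a per-pixel class mask $Y$) supports
training a classifier that maps every pixel of a scene to a tissue class.
Annotations in this setting are sparse and expensive, so the pipeline must
work with limited training data; that motivates the similarity-based layer
at the core of this package.

`scsmap` implements the complete workflow: cube and mask I/O, spectral
dimension reduction, spectral–spatial patch extraction, a Sharpened Cosine
Similarity classifier with convolutional baselines, the standard evaluation
suite for hyperspectral classification, and a synthetic scene generator so
that every stage is testable without access-restricted clinical data.

## The Sharpened Cosine Similarity operator

A convolution computes the sliding dot product $w \cdot x_{ij}$ between a
filter $w$ and an image window $x_{ij}$. The dot product confounds *pattern
match* with *magnitude*: a bright window scores high against any filter.
Normalizing both vectors turns the operation into a cosine similarity, which
responds to direction only. The SCS operator stabilizes and sharpens this:

$$
c = \frac{w \cdot x_{ij}}{(\lVert w \rVert + q)\,(\lVert x_{ij} \rVert + q)},
\qquad
\mathrm{SCS}(w, x_{ij}) = \operatorname{sign}(c)\,\lvert c \rvert^{p},
$$

with a stabilizer $q \ge 0$ and a sign-preserving exponent $p \ge 1$. At
$q = 0$, $p = 1$ this is exactly classical cosine similarity, bounded in
$[-1, 1]$. The stabilizer damps the response of small-magnitude (noisy)
windows: as $q$ grows, $|c|$ shrinks, and for fixed directions the score is
non-increasing in $q$. The exponent sharpens the contrast between strong and
weak matches while preserving the sign of anti-matches.

Two readings of the stabilized denominator are possible; `scsmap` adds $q$
to the *norms* (the default), because that keeps the $q \to 0$ limit exactly
cosine similarity and directly serves the stabilizer's purpose. The
alternative — adding $q$ to every vector component before taking norms — is
available via `q_mode = "component"` in `scs_score()` for comparison.

Because SCS responses are signed, pooling uses **absolute max-pooling**: each
window keeps the value of largest magnitude irrespective of sign, since a
strong anti-match is as informative as a strong match. Ties in magnitude are
broken by first occurrence in row-major window order, making the operator
deterministic; during training the gradient flows only to the selected
element.

```{r scs-demo}
scs_score(c(1, 2, 2), c(1, 2, 2))          # parallel vectors
scs_score(c(3, 4), c(3, 4), q = 5)         # damped: 25 / (10 * 10)
scs_score(c(3, 4), c(3, 4), q = 5, p = 2)  # damped and sharpened
abs_max_pool(matrix(c(-5, 3, 2, -1), 2, 2), 2)  # keeps the -5
```

## The classifier and its training regime

The SCS classifier is the minimal composition that uses the operator as a
feature extractor: one SCS layer (32 units by default, kernel
$\min(3, s)$, stride 1), absolute max-pooling (window 2 when the SCS output
is spatially at least $2 \times 2$; with the default $3 \times 3$ patches
the SCS output is $1 \times 1$ and the pooling stage is an identity kept in
the graph), a flatten, and a softmax head. There are no activation
functions, bias terms, or normalization layers around the SCS stage — the
similarity map itself is the feature.

Training minimizes softmax cross-entropy with minibatch Adam under a fixed
regime: **50 epochs, batch size 256, learning rate 0.001**, weights randomly
initialized. These defaults are wired into `training_config()` and used by
every model so comparisons are like for like. Two convolutional baselines
are provided by `build_baseline()`: a compact 2-D CNN (3×3 convolution +
ReLU, max-pool, dense 100 with batch normalization and ReLU, softmax) and a
LeNet variant (two 5×5 convolution/ReLU/average-pool stages, dense 120 and
84, softmax). On inputs smaller than a kernel the baselines switch to
same-padding, and pooling stages degrade to identities at $1 \times 1$,
each with a logged note.

Parameter choices that are design decisions of this package, with their
rationale:

* **Kernel directions** are initialized uniformly on the unit sphere — SCS
  is scale-invariant in $w$ at $q = 0$, so only direction matters. An
  alternative `init = "prototype"` draws unit-normalized training windows
  (class-stratified) as initial kernels, making each unit a matched filter
  against a class exemplar; measured on the synthetic study it did not
  improve recovery under the fixed epoch budget, so it is an option, not
  the default.
* **The sharpening exponent is trainable and starts at $p = 2$** (per
  kernel), the conventional starting point for sharpened-cosine layers:
  beginning beyond the plain-cosine special case widens the gap between
  strong and weak matches from the first epoch, which matters under a fixed
  50-epoch budget. `scs_score()` itself defaults to $p = 1$, the printed
  operator. The exponent is floored at 1 during optimization.
* **The stabilizer is trainable, scalar per kernel, starts at $q = 0.1$**,
  and is floored at $10^{-6}$ during optimization so the denominator can
  never collapse. Per-channel stabilizers were considered and rejected as
  unidentifiable at these kernel sizes.
* **Softmax-head weights** use fan-in-scaled Gaussian initialization. A
  zero-initialized head was measured and degraded recovery, so it was not
  adopted.

The training engine (SCS layer with exact analytic gradients, im2col-based
convolution, batch normalization, pooling, Adam) is written in vectorized
base R. At the geometries this package targets — $3 \times 3 \times 3$
patches, a few thousand samples — every forward/backward pass reduces to
small dense matrix products, and a full 50-epoch run takes well under a
second on one CPU core; a deep-learning framework would add nothing but
dependencies. All gradients are verified against central finite differences
in the test suite (relative error below $10^{-5}$).

## Band reduction by factor analysis

The spectral dimension is reduced before patch extraction: the
$(M \cdot N) \times B$ matrix of band-standardized spectra is fit with a
factor-analysis model and each pixel is replaced by its `n_factors = 3`
factor scores, rescaled to zero mean and unit variance over the scene.
Zero-variance bands are excluded from standardization with a warning.

Numerical choices:

* Maximum-likelihood estimation (`stats::factanal`) is attempted first.
  Scenes whose band covariance is nearly low-rank — exactly what smooth
  spectra plus correlated noise produce — drive uniquenesses to the
  boundary and make the MLE fail; the implementation then falls back to a
  deterministic principal-axis fit (squared-multiple-correlation priors,
  iterated communalities) and says so via a message.
* Scores use the *model-implied* regression form
  $\Psi^{-1} L (I + L^{\top} \Psi^{-1} L)^{-1}$ with uniquenesses floored at
  0.005. Computing regression scores against the empirical correlation
  matrix (`solve(cor(Z), L)`) is numerically catastrophic when that matrix
  is near-singular; the Woodbury form degrades gracefully to a
  least-squares projection onto the loading subspace as uniquenesses
  shrink.
* The phrase "most informative bands identified through factor analysis"
  admits a second reading — selecting original wavelengths rather than
  projecting onto factors. `mode = "select"` implements it (the original
  band with maximal absolute loading per factor, distinct across factors);
  the default is factor scores, which is what dimension reduction means in
  the factor-analysis literature.
* Whether spectra should be standardized before the fit is genuinely open;
  this package standardizes, which makes the reduction invariant to
  band-wise affine rescaling (verified as a property test via factor-score
  correlations $\ge 0.999$).

## Patches, splits, and protocol fidelity

Spatial context enters through patch extraction: each labeled pixel
becomes one sample, an $s \times s \times D$ window centered on it
($s = 3$ by default, $s$ odd so the focal pixel is centered), labeled by
the focal pixel alone. Out-of-grid positions are zero-padded by default
(declared in the config; mirror reflection is the alternative), and
coordinates are 0-based row-major throughout so patch extraction and map
rendering agree. A full-scene mode extracts a patch at *every* pixel for
whole-scene map prediction.

Samples are split per class into train/validation/test at 15/15/70.
Rounding within each class uses largest remainders, so per-class counts are
within one sample of the exact fractions (a 7-sample class splits 1/1/5);
remainder ties go to train, then validation, then test, and classes are
processed in increasing code order, making the split a deterministic
function of the seed. A class with fewer than 3 samples cannot appear in
all three splits; it is assigned entirely to train with a warning (or
rejected in strict mode). When several models are compared,
`compare_models()` runs them on the byte-identical split and records its
MD5 fingerprint in every result row.

## Evaluation metrics

From the test-split confusion matrix $C$ (rows true, columns predicted,
total $n$) the package computes:

* **Overall accuracy** $\mathrm{OA} = \operatorname{tr}(C) / n$.
* **Average accuracy**: the unweighted mean of per-class recalls
  $C_{cc} / \sum_j C_{cj}$ — the standard definition in hyperspectral
  classification.
* **Cohen's kappa** $\kappa = (A_o - A_e)/(1 - A_e)$ with observed
  agreement $A_o = \operatorname{tr}(C)/n$ and expected agreement
  $A_e = \sum_c (r_c\, k_c) / n^2$ from the row/column marginals. If
  $A_e = 1$ (all mass in one cell) the convention $\kappa = 0$ applies,
  with a warning.
* **F1**: one-vs-rest precision and recall per class,
  $F_1 = 2PR/(P+R)$ with $F_1 = 0$ when $P + R = 0$; both the macro
  (unweighted) and support-weighted means are reported, since published
  aggregate F1 values use either convention.

Two printed variants of these formulas circulate in which the expected
agreement is a two-term sum that does not reduce to the marginal-product
form, and "average accuracy" appears as $(TP+TN)/(TP+TN+FN)$. Neither is
self-consistent for multi-class problems; `scsmap` implements the standard
forms above and exposes the literal variants behind flags
(`cohens_kappa(..., literal_binary = TRUE)` for $2 \times 2$ matrices,
`average_accuracy(..., literal = TRUE)`) so the discrepancy is inspectable
rather than silently corrected. All metrics are verified in the tests
against from-scratch recounts on raw label pairs, never via the matrix.

## The synthetic scene generator

Clinical hyperspectral databases are access-restricted, so the package
ships a generator whose scenes exercise every pipeline stage with the same
structure real scenes have:

* **Spectra**: each of the four classes gets a smooth non-negative mean
  spectrum (baseline plus 1–3 Gaussian bumps with class-specific centers
  and widths over band index). Within-class variation is band-correlated
  Gaussian noise — independent draws smoothed along the band axis by a
  Gaussian kernel (length scale about $B/15$ bands) normalized so the
  marginal per-band standard deviation is exactly $\sigma$ (default 0.02).
* **Layout** (mimicking a surgical scene): a background frame around the
  scene, a normal-tissue interior, a rotated elliptical tumor blob, and a
  sinusoidal blood-vessel track about 2 px wide. Scenes smaller than
  $16 \times 16$ are rejected; every class is guaranteed at least one
  pixel.
* **Partial labeling**: a per-class random subset of pixels
  (`labeled_fraction`, default 0.5) carries labels; the rest are marked
  unlabeled, as in partially annotated clinical ground truth. The default
  of one half is a deliberately optimistic but realistic stand-in for the
  sparse annotation of surgical scenes.
* **Determinism**: a library and a scene are bit-identical functions of
  their seeds.

**How separation is measured.** The difficulty knob is the minimum pairwise
separation between class means in noise units. Because the noise is
band-correlated, it carries far more variance along smooth directions —
exactly where class contrasts live — than the marginal $\sigma$ suggests,
so Euclidean distance over $\sigma$ would overstate the effective
separation several-fold. The generator therefore measures separation along
the discriminating direction: for classes $i, j$ with contrast
$d = \mu_i - \mu_j$ and noise covariance $\Sigma$,

$$
\mathrm{sep}(i, j) = \frac{\lVert d \rVert^2}{\sqrt{d^{\top} \Sigma\, d}},
$$

the Mahalanobis-like ratio that governs the pairwise Bayes error of a
projection classifier ($\approx \Phi(-\mathrm{sep}/2)$). Class-mean
contrasts are rescaled so the minimum pairwise value equals the requested
separation exactly (the default 10 puts the hardest class pair at a Bayes
error around $\Phi(-5) \approx 3 \times 10^{-7}$ per pixel — cleanly
separable, but only for a pipeline that actually preserves the contrasts
through reduction, patching, and training).

**What the generator does not model**, and hence what passing tests cannot
show: real tissue optics (absorption and scattering spectra, angiogenesis
signatures), specular highlights and shading, spatially varying
illumination, label noise at region boundaries, and inter-patient spectral
variability. Results on synthetic scenes demonstrate that the pipeline's
machinery is correct and recovers well-posed scenes; they say nothing about
clinical accuracy.

## Problem sizes and runtime

The standard synthetic study used by the tests and the acceptance script is
a $64 \times 64 \times 30$ scene: 30 bands rather than several hundred
because the pipeline reduces to 3 factors either way and its behavior is
band-count-invariant by design (large-band generation remains available).
With half the pixels labeled and 15% used for training, a full run — scene,
factor analysis, patches, split, 50 training epochs, evaluation, full-scene
map — takes roughly half a second on one CPU core; the ten-seed recovery
study in the acceptance tests completes in a few seconds. Unit tests use
$24 \times 24 \times 12$ scenes.

## Known limitations

* The training engine targets desk-scale problems; there is no GPU path
  and no minibatch parallelism. Scenes of several hundred thousand labeled
  pixels would train, but slowly.
* Rare classes (the vessel track and small tumor blobs yield only tens of
  training samples at desk scale) learn slowest under the fixed 50-epoch
  regime; their recall is the first casualty on hard seeds. More epochs
  resolve this but would depart from the fixed training protocol.
* ENVI support covers the common core (BSQ/BIL/BIP interleaves, float32/64
  payloads, little/big endian, wavelength lists); exotic header features
  (band-dependent gains, bad-band lists) are ignored.
* `factanal`'s MLE rarely converges on near-low-rank scene covariances;
  the principal-axis fallback is deterministic and well-behaved but does
  not provide likelihood-based factor-count diagnostics.
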