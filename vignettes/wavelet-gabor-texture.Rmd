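---
title: "Wavelet-Gabor texture features for normal/abnormal image screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-Gabor texture features for normal/abnormal image screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwtgabor)
```

## The model

Many screening problems reduce to a single question: does this image
contain *abrupt, frequent, high-contrast* texture variation that the
normal anatomy does not produce? Microcalcifications in mammograms,
exudates in retinal photographs and many MR-visible lesions share this
signature even though the underlying physics differ entirely. The
pipeline implemented here makes that premise operational in three stages.

**Stage 1 — isolate high-frequency structure.** A separable 2D discrete
wavelet transform (Daubechies-4, 8 taps) filters rows and then columns
with a quadrature low/high-pass pair and decimates by two, producing four
half-resolution subbands. The diagonal detail band HH is high-pass in
both directions, so smooth anatomy is (to machine precision) annihilated
while edges, specks and streaks survive. Level 2 repeats the analysis on
the level-1 approximation (LL), the standard pyramid recursion; it probes
coarser anomalies at the cost of resolution.

**Stage 2 — probe orientation and frequency content.** The HH band is
convolved with the real part of twelve Gabor kernels, a cosine carrier of
central frequency $f$ at orientation $\theta$ under an elliptical
Gaussian envelope: four orientations ($0, \pi/4, \pi/2, 3\pi/4$ — both
axes and both diagonals) by three frequencies ($f = 2, 2.5, 3$
cycles/pixel). Directional anomalies (vessels, streaks, linear clusters)
excite some bank members much more than others, which a single isotropic
statistic would average away.

**Stage 3 — summarise and classify.** Each response is reduced to the
entropy $E = -\sum_z p(z)\log_2 p(z)$ and uniformity $U = \sum_z p(z)^2$
of its coefficient histogram. These two statistics describe the *shape*
of the coefficient distribution while discarding all spatial layout —
appropriate because the diagnostic signal is "how much disordered
high-frequency content", not "where". The resulting vectors
($[E, U]$ for the wavelet-only mode, $[E_1..E_{12}, U_1..U_{12}]$ for the
Gabor modes) feed a soft-margin SVM with the degree-2 polynomial kernel
$K(x, x_i) = (\langle x_i, x\rangle + 1)^2$, evaluated by stratified
tenfold or leave-one-out cross-validation.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| wavelet | Daubechies-4, 8 taps | — | the common choice for subband texture coding; "4" is read as 4 vanishing moments (8 taps), the more frequent convention, and any quadrature pair can be substituted via `wavelet_spec()` |
| decomposition level | 1 or 2 | — | the two levels the method is validated at; deeper levels need `allow_deep = TRUE` |
| boundary mode | symmetric (half-sample) | — | medical images have no natural periodicity; periodization would fabricate wrap-around edges |
| $\theta$ | $0, \pi/4, \pi/2, 3\pi/4$ | rad | covers axes and diagonals; the real kernel is even under $\theta \mapsto \theta + \pi$ |
| $f$ | 2, 2.5, 3 | cycles/pixel | taken literally on the integer grid, hence deliberately aliased (see below) |
| $\sigma_x, \sigma_y$ | 1, 1 | pixels | the unity default used for retina/MR-like imagery; `gabor_bank(fwhm = τ)` switches to the mammographic scheme $\sigma_x = \tau/2.35$, $\sigma_y = 8\sigma_x$ |
| kernel support | half-width $\max(3, \lceil 3\max(\sigma_x,\sigma_y)\rceil)$ | pixels | 3-sigma truncation keeps >99% of envelope mass |
| histogram bins | 256 | — | the 8-bit gray-level convention of the texture literature |
| SVM | $C = 1$, degree 2 | — | degree 2 is the method's kernel; $C$ is not prescribed anywhere, so the common default is used and recorded in every report |

**The aliased frequencies.** With $f \ge 2$ cycles/pixel the carrier is
far above Nyquist: at $\theta = 0$ every integer offset satisfies
$\cos(2\pi f x) = 1$ (for integer $f$), so those kernels degenerate to
pure Gaussians, while the diagonal orientations sample the cosine at
irrational multiples and stay oscillatory. This literal reading is kept
because it is the configuration the method is defined with; a
`freq_scale` knob on `gabor_bank()` lets users move the carrier below
Nyquist without touching the bank layout. The tests pin the literal form.

**Histogram domain.** Bins span the min–max range of each image's own
coefficients. This makes $E$ and $U$ exactly invariant to positive
rescaling (and to pixel permutation), so heterogeneous image sizes and
bit depths need no resizing or normalisation — at the price that a
histogram never distinguishes two images differing only by an affine
intensity map. Whether one should instead quantise to a fixed global
gray-level grid is genuinely open; the per-image choice is the documented
one here and is what the invariance tests assert.

**Convention choices.** Entropy uses $\log_2$ (bits); any fixed base only
rescales one feature axis, which the kernel machine absorbs. $0\log 0$ is
0. Decision values of exactly 0 classify as abnormal — the conservative
direction for screening. Fold assignment is stratified and seeded;
per-fold sensitivity/specificity that is undefined because a fold lacks a
class (always, under leave-one-out) is excluded from the mean ± sd with a
message, and pooled whole-protocol metrics are reported alongside.
libsvm (via e1071) solves the dual with KKT tolerance $10^{-6}$; the
package evaluates its own decision function from the stored support
vectors, dual coefficients and bias, which a test checks against libsvm's
predictions point for point.

## The synthetic testbed

`synth_config()` defines the study conditions used throughout the tests
and the acceptance script: 128×128 images, 40 per class. A *normal* image
is Gaussian white noise blurred at scale 4 px and rescaled to $[0,1]$ — a
smooth, spatially correlated field whose HH band is essentially empty. An
*abnormal* image adds five hard-edged bright discs of radius 2 px at
amplitude 0.25 plus one diagonal streak of the same amplitude. The spots
are two blur-scales smaller than the background correlation length, so
they are genuinely high-frequency; the amplitude is an order of magnitude
above the local post-blur contrast yet leaves the two classes' global
histograms largely overlapping. These values were fixed once, from that
reasoning, as the generator's definition of the task.

What passing the end-to-end tests shows: the pipeline detects exactly the
kind of structure it claims to detect, under controlled conditions, with
the hybrid features at least as good as the wavelet-only baseline on
identical folds. What it does not show: performance on clinical data,
whose anomalies are not ideal discs, whose backgrounds contain legitimate
high-frequency anatomy, and whose acquisition introduces noise this
generator deliberately omits.

The suite also pins a *failure* regime, mirroring the known weakness of
Gabor-on-raw-image features: with a single radius-1 spot at amplitude
0.003 the anomaly is invisible against the raw-intensity variation, and
the Gabor-only machine drops to chance with strongly imbalanced
sensitivity/specificity, while the hybrid features — which see the spot
against a silent HH background — stay at 100%. The exact imbalance is
data-dependent, so the test asserts the qualitative collapse at a fixed
seed rather than any specific split.

## Numerical and degenerate cases

* Constant images: every detail band is zero to $10^{-10}$ (high-pass
  taps sum to zero); their histogram is a single degenerate bin, giving
  the feature pair $E = 0$, $U = 1$ rather than an error.
* Odd image dimensions decompose with ceil-halving under symmetric
  extension; the validated sizes are even.
* Images must be at least the filter length (8) per side for one level,
  16 for two.
* Convolution is true convolution (kernel flipped); for the
  point-symmetric Gabor kernels this coincides with correlation, but the
  contract is stated for arbitrary kernels and tested with an asymmetric
  one.
* Ties, duplicated samples and single-class folds are all exercised in
  the test suite; training on a single class is a validation error.

## Problem sizes

The default test and acceptance runs use 40+40 images of 128×128 (and
64×64 for unit-level checks), tenfold cross-validation, and the 12-kernel
bank — a few tens of seconds end to end. The implementation is plain
vectorised R (shift-and-add convolution, slice-decimated filtering); it
scales linearly in pixel count and kernel area, and nothing prevents
running it on full-resolution clinical imagery, only time.

## Known limitations

* Only the real part of the Gabor response is used; magnitude/phase
  features are an extension point.
* No feature selection or kernel/parameter search is performed — the bank
  and SVM settings are fixed by design, not optimised.
* Binary classification only; the multi-pathology case is out of scope.
* The histogram estimator ignores spatial structure entirely; two images
  with identical coefficient distributions but different layouts are
  indistinguishable by construction.
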