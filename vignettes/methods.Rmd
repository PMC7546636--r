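---
title: "Screening for diabetic neuropathy from facial video: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for diabetic neuropathy from facial video: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rubeoscan)
```

## The screening problem

Rubeosis faciei diabeticorum — chronic facial erythema caused by
microangiopathy — accompanies diabetic neuropathy but routinely goes
unnoticed in clinical practice because the reddening is subtle and
confounded by skin tone. `rubeoscan` implements a contactless screening
pipeline that works from an ordinary face video: pulse-driven color
variation that is invisible to the naked eye is amplified, summarised as
a spatio-temporal "tensor profile", and characterised through the
statistics of largest eigenvalues of windowed covariance matrices. The
right tail of the eigenvalue distribution separates two dynamical
regimes — scale-free (healthy-control-like) versus unstructured random
(neuropathy-like) — and a supervised ensemble plus majority voting turns
per-segment evidence into a per-subject decision.

This vignette records the models, the tunable parameters, the places
where the design was genuinely open and what we chose, and what the
synthetic-data validation does and does not demonstrate.

## Eulerian video magnification

Each video segment is decomposed per channel into a full Laplacian
pyramid; every spatial band is temporally filtered with the difference
of two zero-phase Butterworth low-pass filters (cutoffs 0.4 and 4.0 Hz,
bracketing the human pulse band), scaled by the magnification factor
`alpha = 50`, added back, and collapsed.

Design choices worth recording:

* **Filter order.** Only the two cutoff frequencies are fixed by the
  method; the order and phase behaviour are free. We use order 3 per
  low-pass, applied with zero phase. At 50 fps this gives a band gain of
  0.996 at 1 Hz (so a pulse component of amplitude $a$ comes out at
  $(1 + \alpha g)a \approx 50a$) while content at 10 Hz or above is
  amplified by at most 1.1x under `alpha = 50`. Order 1 would leak the
  0.4 Hz edge into the pass band (gain only ~0.80 at 1 Hz) and order 2
  would amplify 10 Hz content 1.8x, so order 3 is the lowest order that
  meets both contracts. `band_gain()` exposes the designed response so
  expected amplification can always be computed analytically.
* **Zero-phase realisation.** The forward-backward (squared-magnitude)
  response is applied in the frequency domain on odd-reflection-padded
  series, with FFT lengths rounded up to 5-smooth numbers. This is the
  exact amplitude response of a forward-backward Butterworth pass and is
  several times faster than a time-domain recursion over every pixel.
  Like any zero-phase filter it has edge transients; measurements in the
  tests are taken away from segment boundaries.
* **Pyramid depth.** "Full pyramid" needs a termination rule: `"auto"`
  uses `floor(log2(min(H, W))) - 2` levels, i.e. it stops when the
  coarsest band is a few pixels across.
* **Uniform amplification and the pyramid identity.** With one `alpha`
  for all levels and pixels, every operation involved is linear and the
  decomposition commutes with the temporal filter, so
  pyramid-filter-collapse is mathematically identical to filtering each
  pixel directly. `magnify(use_pyramid = FALSE)` exploits this; the
  tests assert both paths agree to ~1e-13. The explicit pyramid path
  remains the default and the place where level-dependent processing
  would be added.
* **Color constancy.** Recording without controlled illumination needs a
  color-constancy step; the method is not pinned down, so we use the
  gray-world per-channel gain, applied before magnification. It is
  scale-invariant, preserving the linearity of the whole magnifier.
* Processing is float throughout; intensities are clipped to `[0, 1]`
  only on PNG export (which also quantises to 8 bits — the sidecar CSV
  formats exist precisely so that downstream stages can be re-run
  losslessly).

## The tensor profile

Eight 31x31-pixel facial patches (two cheek patches, where erythema
expresses; six background patches on forehead, nose and philtrum) are
taken from every frame via a static patch manifest — landmark tracking
is out of scope and delegated to whatever produced the manifest. From
the Red channel we form the pixelwise difference between the patch with
the highest and the patch with the lowest mean intensity, then z-score
every pixel row.

Open points we fixed:

* The extreme patches are chosen **once per segment** by time-averaged
  mean, not per frame, so the identity of the "reddest" patch cannot
  switch mid-segment and inject artificial jumps.
* "Normalized" is read as per-pixel-row standardisation (zero mean, unit
  variance); rows with zero variance are flagged, imputed to zero and
  counted in a warning rather than dropped, so the pixel grid stays
  rectangular.
* Whether the method's "tensor" is the pixelwise difference matrix or
  the scalar difference of patch means is ambiguous; we implement the
  matrix (it is what a covariance analysis needs) and expose the scalar
  series as `mean_series` for comparison.

Using a *difference* of facial regions makes the pipeline insensitive to
global, homogeneous color factors (skin tone, sun exposure, absolute
haemoglobin level): adding a constant to every pixel of every frame
leaves the profile unchanged, and this invariance is tested.

## Largest-eigenvalue spectra

For each segment the profile is cut into sliding windows (defaults: 250
frames = 5 s, stride 50 frames = 1 s at 50 fps). In each window the
sample covariance of the pixel rows is formed and its largest eigenvalue
extracted by power iteration (tolerance 1e-12, at most 1e4 iterations,
fixed-seed start vector; the iteration works through the data matrix so
the N x N covariance is never materialised). The collection of
$\lambda_{max}$ values — one per window — is the sample whose empirical
spectral density (ESD) the tail analysis characterises; this windowing
construction is the central reconstruction choice of the package, since
the source method never states how a distribution of largest eigenvalues
is populated from a single segment. Every tail report carries the
window geometry used.

The Tracy-Widom normalization
$\xi = \sqrt{2} N^{1/6} (\lambda_{max} - \sqrt{2N})$ is provided
(`tw_normalize()`); the exact Tracy-Widom CDF via the Painlevé-II/Airy
route is out of scope because the method itself substitutes a Gamma
approximation (below). Whether $N$ should be the pixel dimension or the
window length is ambiguous in the source; we use the covariance
dimension (pixels), which is what the normalization's derivation refers
to.

At desk scale the eigen-analysis may subsample pixel rows
(`n_pixels`); this thins the covariance dimension without changing the
tail class of the window eigenvalues.

## Tail models and the sgn(k) verdict

The right tail of the $\lambda_{max}$ ESD is fitted with a generalized
Pareto distribution (GPD), whose shape $k$ is the tail index:

* $k > 0$: polynomial (power-law) tail — the self-organized-criticality
  signature associated with healthy controls, whose decay exponent is
  then estimated by the Hill-type MLE
  $|\hat\gamma| = 1 + N\left[\sum_i \ln(x_i/x_{min})\right]^{-1}$;
* $k < 0$: finite tail — compatible with Tracy-Widom (random-matrix)
  behaviour, then summarised by a Gamma$(\beta, \theta)$ fit (shape,
  rate) as the Tracy-Widom surrogate;
* $k = 0$ goes to the power-law side by convention (the boundary is
  stated nowhere in the source, so we state it here).

Numerical and design choices:

* **GP fitting.** Maximum likelihood over $(k, \log\sigma)$ with a
  multi-start Nelder-Mead search honouring the $k<0$ support bound
  ($\max x \le \mu - \sigma/k$). No CRAN extreme-value package is part
  of this package's dependency footprint; the fitter is self-contained
  and its parameter recovery is tested against simulated draws at
  3 Monte-Carlo standard errors.
* **Threshold.** For eigenvalue samples produced by the video pipeline
  the GP is fitted to peaks over the 90th-percentile threshold (the
  default), with at least 30 exceedances required. For feature-level
  synthetic samples — which are drawn from the tail families directly
  and are therefore already exceedances — the location is pinned at 0
  and the whole sample is used (`threshold_quantile = 0`); a
  peaks-over-threshold split there would only discard information and
  noticeably destabilises the sign of $\hat k$ at segment sample sizes.
* **Power-law MLE.** The estimator is implemented in its standard
  reciprocal (Hill) form; the reported $\hat\gamma$ carries a negative
  sign (a decay rate) while the MLE operates on the magnitude under the
  assumption $\gamma > 1$. With `x_min = "auto"` the cutoff minimises
  the Kolmogorov-Smirnov distance between the fitted Pareto tail and the
  empirical tail over a quantile grid, requiring at least 10 tail
  points.
* **Gamma parametrization.** Rate (the density carries $e^{-\theta x}$);
  samplers and fitters are self-consistent under it. The ML fit runs on
  a unit-mean rescaled sample for numerical stability.

## Classification

Each segment contributes the feature vector $(k, \sigma)$ of its GP tail
fit (a 12-feature subject-level mode and extra features
$\hat\gamma, \beta, \theta$ sit behind configuration flags). Class
convention: C = 0, DM = 1; a score of exactly 0.5 classifies as DM
(another boundary the source leaves unstated).

* **Base learners.** Gradient-boosted shallow trees are the reference
  configuration — 10 learners, learning rate 0.469, at most 38 splits
  per tree, pinned so runs are reproducible rather than re-tuned per
  run; a "52 learners / learning rate 0.107" alternative is exposed as a
  named variant. Class imbalance (twice as many DM as C subjects) can be
  handled RUSBoost-style by seeded random undersampling of the majority
  class with at most 39 splits. LDA and logistic regression complete the
  base-learner set.
* **COWE.** The cross-validated optimal weighted ensemble places the
  learners' class-1 probability scores on a simplex and minimises the
  cross-validated mean squared prediction error of the weighted score.
  Out-of-fold scores come from seeded stratified 5-fold internal
  cross-validation. With up to three learners the simplex is searched
  exhaustively on a 0.01 grid; beyond that, projected-gradient descent
  with multistart. Near-ties are broken toward uniform weights, so
  duplicated learners share weight equally. By feasibility of the
  simplex vertices, the optimal cross-validated MSE is never worse than
  any single learner's — this is asserted in the tests.
* **Subject fusion.** Per-subject decisions use equal-weight majority
  voting: with six segments the winner needs at least 4 votes; with
  fewer segments a strict majority; an exact tie is "undecided".
  Undecided subjects count against sensitivity and specificity and are
  reported separately.
* **Evaluation.** Leave-one-out cross-validation at subject level: all
  six segments of the held-out subject leave the training set together,
  and an internal assertion fails the run if a held-out subject's
  segments are ever seen in training. An unsupervised baseline
  classifies each segment by $\mathrm{sgn}(k)$ alone and fuses with the
  same voting rule.

## The synthetic-data generator

The study's patient videos are not publicly deposited, so validation
rests on two synthetic levels.

**Feature level.** `cohort_spec()` / `generate_cohort_features()` draw
per-segment eigenvalue samples from the two reference parameter
families bundled with the package (`reference_tail_params()`): Gamma
(shape, rate) pairs for the diabetic group and positive-shape GP pairs
for controls, nine printed pairs per group. Defaults: 18 DM and 9 C
subjects, 6 segments each, 500 eigenvalues per segment sample, and a
per-group "atypical" fraction (3/18 DM, 2/9 C) of subjects whose
segments are drawn from the *opposite* family — matching the reported
share of subjects whose tail type contradicts their clinical group.
With these defaults the unsupervised sgn(k) classifier lands exactly at
15/18 DM and 7/9 C correct; with the atypical fraction at 0 the full
supervised pipeline reaches 100% sensitivity and specificity. That is a
statement about the generator's separability, not about clinical
performance.

**Video level.** `render_video()` produces frame stacks in which eight
disjoint patches sit on a uniform skin-colored background; cheek patches
carry a constant redness offset plus a Red-channel pulse modulation, and
per-pixel Gaussian sensor noise is added everywhere. The source does not
state a generative mechanism for the group difference in eigenvalue
tails, so the contrast is a modelling choice of this package, selected
because each mechanism provably induces the intended tail class:

* **C (control):** every heart beat draws its amplitude from a
  continuous Pareto (density exponent 3, rescaled to unit mean) — the
  avalanche-size analogy of self-organized criticality. Window
  eigenvalues then inherit a polynomial tail (index ~1), and the GP fit
  recovers $k > 0$.
* **DM:** a constant-amplitude pulse, 18x larger, plus unstructured
  white Gaussian fluctuation. Window eigenvalues concentrate around the
  pulse energy with light-tailed fluctuation, and the GP fit recovers
  $k < 0$.

Amplitudes are sub-visible before magnification (below one 8-bit step)
and calibrated once so that the magnified DM/C ratio of mean absolute
patch difference is about 22-fold (measured 22.0, median over 8
segments); the pulse defaults to 50/19 Hz, i.e. a 19-frame beat period
(0.38 s) at 50 fps. Sensor noise (sd 5e-5) is set an order of magnitude
below the control group's magnified signal so that the eigenvalue
statistics reflect physiology rather than the noise floor; this is
idealised relative to an 8-bit camera, which is one reason video-level
results here validate the machinery, not the clinical claim.

**What the synthetic validation does not show.** No head motion, no
illumination drift beyond a global gain, no landmark-tracking error, no
photo-realistic skin texture, and a hand-chosen generative mechanism for
the group contrast. Passing tests demonstrate that each stage implements
its contract and that the chain separates the two regimes it was built
to separate — not that real patient videos would yield the published
clinical numbers.

## Problem sizes used in the checks

The test-suite and acceptance problem sizes are chosen to make every
check sharp at desk scale: parameter-recovery fits use 1e4 draws (1e5
for the power-law exponent example); cohort-level checks use the full
27-subject layout with 500 eigenvalues per segment; video-level checks
render 68x136-pixel frames at 25 fps with 1000-frame segments,
analysing windows of 15 frames with stride 3 at a 0.6 tail threshold
(about 1.6 beats per window, so scale-free beat-to-beat variability
remains visible in the window eigenvalues), with verdict agreement
required on at least 90% of 20 segments. The full-size recording layout
(1280x720 at 50 fps, 5-second windows) remains the default
configuration of the exported functions.

## Known limitations

* The windowing construction of the $\lambda_{max}$ ESD is a
  reconstruction; other poolings (across repetitions or pixels) would
  give different effective sample sizes for the tail fits.
* GP shape estimates from a few dozen exceedances are noisy
  (SE $\approx (1+k)/\sqrt{n_{tail}}$); near-zero true shapes can flip
  sign per segment, which is exactly why subject-level majority voting
  exists.
* The frequency-domain zero-phase filter has boundary transients over
  roughly one low-cutoff period at each segment end.
* PNG interchange quantises to 8 bits; sub-step modulation written to
  PNG before magnification is lost, so magnification should run on the
  float frames (or magnified stacks should be exported instead).
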