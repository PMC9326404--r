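---
title: "Estimating leaf potassium from hyperspectral imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating leaf potassium from hyperspectral imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Potassium is highly mobile in plants: leaf potassium content (LKC, % of dry
mass) can change quickly as the plant redistributes K toward developing
organs, and classical wet chemistry (digestion + flame photometry,
`lab_k_percent()`: K% = rho V t_s 1e-4 / m) is destructive and slow.
Visible/near-infrared hyperspectral imaging offers a non-destructive
alternative: K status changes both the leaf spectrum (chlorophyll absorption
features, red edge, NIR plateau height) and the spatial appearance of the
leaf surface (texture, brightness). `leafspec` implements a complete
chemometric pipeline for this estimation problem, together with a synthetic
scene generator that provides ground truth for validating every stage.

The pipeline is: scene acquisition (or simulation) -> reflectance
calibration against a gray reference panel -> single-band threshold
segmentation -> whole-leaf mean spectra -> continuous wavelet transform
(CWT) at dyadic scales -> characteristic-wavelength selection (CARS, random
frog) -> grayscale-image texture and color features at the selected
wavelengths -> partial least squares regression (PLSR) with feature fusion.

# The synthetic scene generator

No public dataset accompanies this class of leaf-imaging campaign, so the
generator is a first-class module rather than a test fixture. Its defaults
encode the study conditions the analysis assumes:

* a 128-band sensor grid starting at 376 nm. The nominal range 376--1044 nm
  with "about 5 nm" resolution is honored with a spacing of 5.2 nm: a
  literal 128-point linspace over 376--1044 leaves 105 bands inside the
  400--950 nm working window, whereas 5.2 nm spacing yields exactly the 106
  retained bands the analysis expects (last center 1036.4 nm);
* three growth stages (budding, flowering, boll setting) with 60 leaves
  each, K drawn from truncated normal distributions reproducing the
  published per-stage min/max/mean/sd (budding 0.51--3.56, mean 1.63, sd
  0.81; flowering 0.57--2.80, 1.18, 0.44; boll 0.40--2.30, 1.25, 0.56);
* a dark background plate (reflectance 0.05, well below the 0.25
  segmentation threshold) and a gray reference panel (0.60, well above it);
* a linear sensor: DN = reflectance x gain (4000 DN) + dark current
  (100 DN) + Gaussian noise (sd 8 DN).

Because mean and sd of a naively truncated N(mean, sd) differ from the
nominal values, the parent parameters are moment-matched with a small
optimizer so the *truncated* distribution reproduces the published moments.
The boll-stage sd (0.56 over [0.40, 2.30]) slightly exceeds what any
truncated normal on that interval can reach (the uniform limit is about
0.548); the matcher gets within sampling error of it at n = 600. Sampling
is by rejection, with the parent sigma capped at twice the range width so
the rejection rate stays bounded.

Potassium is coupled to the scene through three *linear* links with known
ground truth (`ground_truth_params()`):

* spectral: the NIR plateau height falls by `nir_slope` (0.06 reflectance
  per % K) as K rises, so K-deficient leaves are brighter at 760--950 nm;
* texture: multiplicative per-pixel speckle whose amplitude falls linearly
  with K (`texture_effect`, max 5% at the low end of the K range);
* color: whole-leaf brightness gain falling with K (`color_effect`, 2% per
  % K around the range midpoint).

Linear links are a deliberate simplification: the true K-reflectance
functional form in cotton is unknown, and linearity is the weakest
assumption that still supports exact parameter-recovery tests (a noiseless
campaign must be recoverable with validation R^2 of 1). They are a
stand-in, not an inference about plant physiology.

On top of the K links, each leaf carries K-*independent* biological
variability: NIR plateau jitter (sd 0.03 reflectance), whole-leaf gain
jitter (sd 3%), green-peak amplitude jitter (sd 10%) and a red-edge
inflection shift (sd 3 nm). These were chosen once so that spectra-only
models on default campaigns reach validation R^2 around 0.5--0.8 — the
regime reported for real cotton campaigns — instead of the 0.9999 a
noise-free linear link would give. Without this, fusion comparisons are
vacuous because the spectra alone are already perfect. The smooth spatial
field (amplitude 0.05) emulates venation/illumination structure so that
masked texture statistics see realistic within-leaf correlation.

What the generator does *not* emulate: radiative transfer (no PROSPECT-type
leaf optics), instrument line-spread functions, specular effects,
illumination geometry, or disease/damage patterns. Passing tests therefore
demonstrate that the *analysis machinery* is correct and that the designed
couplings are recoverable — not that the pipeline would reach any
particular accuracy on real leaves.

The default desk-scale scene is 192 x 192 pixels (the full 692 x 520
acquisition frame is available by config); tests and the acceptance script
use 64 x 64 scenes with 60 leaves per stage, which keeps a full two-arm,
ten-seed fusion experiment inside a few minutes on one CPU while leaving
about 1,200 pixels per leaf for texture statistics.

# Preprocessing

Reflectance calibration divides each band by the mean panel DN and
multiplies by the nominal panel reflectance, which cancels any global
illumination gain exactly (a doubling of all DN leaves reflectance
unchanged to 1e-12). A dark-current offset can be subtracted first; with
the generator's sensor model this recovers ground-truth reflectance to
machine precision on noiseless scenes.

Segmentation thresholds the band nearest 800 nm at reflectance 0.25:
vegetation is bright on the NIR plateau while the background plate stays
dark, making 800 nm the natural single-band choice. The published
description of the threshold interval ("0.25--0.3098") is read as a lower
cut at 0.25 with 0.3098 being the observed leaf maximum, not an upper cut —
an upper cut would delete the brightest leaf pixels. The declared panel
region is excluded, and only the largest 4-connected component is kept,
which removes noise speckle. Named wavelengths always resolve to the
nearest band center, ties toward the lower center.

# Continuous wavelet transform

Spectra are decomposed with the sym2 mother wavelet at dyadic scales
a = 2^i, i = 1..10 ("CWT-i"). The transform is the discretized integral
W(a, b) = sum_lambda f(lambda) psi_ab(lambda) with normalization 1/sqrt(a),
computed along the *band index* (unit spacing): on a uniform grid this is
equivalent to integrating in nm up to a relabeling of scales, and it keeps
coefficient columns aligned with bands. Boundary handling is half-sample
symmetric (mirror with edge duplication); symmetric extension avoids the
edge ramps a zero-pad would create, which would masquerade as red-edge
features at coarse scales.

sym2 is sampled by cascade refinement of its reconstruction filters at
2^12 points over the support [0, 3] (well above the 2^10 floor at which the
cascade is visually converged), then linearly interpolated per scale; the
mother is centered at its support midpoint so coefficient b aligns with
band b. The implementation computes each scale as one matrix product
against a kernel-placement matrix; an independent brute-force summation of
the discretized integral agrees to better than 1e-8 relative error at all
ten scales, which is the package's oracle-equivalence test. sym2 is mildly
asymmetric, so the |coefficient| maximum of a narrow spectral bump can sit
one band off its center — tests allow exactly that slack.

Scale-by-wavelength maps of |Pearson r| between coefficients and K
(`correlation_map()`) reproduce the shape of published correlation
analyses; on default synthetic campaigns the per-scale maxima land around
0.7--0.8. Wavelet-coefficient grayscale images (`coefficient_image()`)
min-max scale the per-pixel coefficient at one scale and wavelength to
0..255 *per image* (not globally): each leaf then uses the full dynamic
range, and a global illumination gain cancels exactly. Raw-band images are
available behind a flag.

# Variable selection

**CARS** runs 50 Monte Carlo iterations with 5-fold cross-validation. Each
run fits PLSR on a random 80% row subset (the subsample fraction is
standard practice; the source description does not fix it), ranks variables
by |regression coefficient|, enforces the exponential reduction schedule
r_i = a e^(-k i) with r_1 = 1 and r_N = 2/p, and then applies adaptive
reweighted sampling. ARS is implemented as the cited algorithm's weighted
draw *with replacement* with duplicates collapsed: a literal
without-replacement draw of K_i items from K_i candidates would be a no-op.
Each run's subset is scored by 5-fold RMSECV on the full calibration data
with one fixed fold partition (paired comparisons across subsets), and the
minimum-RMSECV subset wins.

**Random frog** is reconstructed from its published outline: a working
subset of nominal size Q = 5 proposes candidates by resizing
(round(|N(Q, 0.3 Q)|), clipped to [1, p]) and swapping members; candidates
replace the current subset when their RMSECV is no worse, and otherwise
with probability eta (0.1) times the RMSECV ratio. Selection probability is
the exact inclusion frequency over 10,000 iterations; variables at or above
the stage threshold (defaults 0.40 / 0.21 / 0.23 — how those stage values
were chosen is not documented, so they are plain configuration here) are
returned in descending probability order. Q, the proposal spread and eta
are reconstruction choices, all configurable. Repeated subsets are memoized
within one call, which cuts the 10,000-iteration run to a couple of
seconds.

Both selectors cap their output at 10 variables (CARS by |coefficient| in
the winning subset, RF by probability; ties resolve toward the lower
index). Within selection, the PLSR latent count is capped at
min(10, |subset|, n - ceil(n/folds) - 1).

The selection-recovery standard is synthetic: on y = 2 x40 + x70 + noise
(sigma = 0.1 sd(signal), p = 106, n = 60), both selectors must contain both
informative variables in at least 90% of 20 seeded repetitions; in this
build both recover them in 20/20.

# Image features

Texture uses the gray-level co-occurrence matrix at 256 levels, step 1,
directions 0/45/90/135 degrees, counting only pixel pairs with *both*
pixels inside the leaf mask, symmetrized and normalized. Statistics are
energy, entropy (natural log), contrast and correlation. Two printed
formulas required interpretation: the contrast kernel appears as "(i,j)^2"
and is implemented as the standard (i - j)^2 — the only reading for which a
constant image has zero contrast, consistent with contrast as furrow depth;
and the correlation denominator appears as "VAR_i * VAR_j" and is
implemented as sqrt(VAR_i VAR_j) so that correlation lies in [-1, 1].
Whether the published matrices were symmetrized is not stated; symmetric is
the common convention and is configurable in the oracle tests. Each
characteristic-wavelength image yields 24 features: 4 statistics x 4
directions plus the mean and (population) variance of each statistic across
directions, named like `641 nm-CON-135°` and `641 nm-MEA (CON)`.

Color moments are the gray-level mean, the root-mean-square deviation and
the signed cube root of the third central moment over masked pixels (the
printed second/third-moment equations are typographically garbled; the
standard color-moment definitions are used). One gray channel gives 3
features per image, named like `532 nm-VAR`.

Image features are screened in two stages: keep features whose correlation
with K is significant at p < 0.05, then run CARS on the survivors. With no
survivors the selection is empty and fusion degrades to spectra-only, with
the report row flagged.

# Modeling and comparison

The calibration/validation split is a concentration gradient: sort by K,
send the middle sample of each consecutive block of three to validation
(2:1, so 60 leaves give 40/20), and force the global minimum and maximum
into calibration so the validation K range is always covered. The cited
method is not algorithmically specified; this rule reproduces both of its
stated outcomes.

PLSR is SIMPLS on mean-centered data, implemented in compiled code because
CARS and random frog together evaluate tens of thousands of small fits per
selection call; a pure-R NIPALS implementation serves as the independent
cross-check in the tests. The latent count minimizes 5-fold RMSECV, capped
at min(10, p, n - ceil(n/folds) - 1). Models report R^2 and RMSE in the
population forms, on calibration and validation sets separately.

Within the comparison harness, features are scaled to unit variance before
fitting. This deviates from a mean-centering-only default (kept, and
switchable, in `fit_plsr()`): GLCM contrast lives on a gray-level-squared
scale of order 10^3 while spectral features are of order 10^-2, and an
unscaled fusion collapses the PLS directions onto the texture block
(observed validation R^2 of 0.24 against 0.9999 for spectra alone on an
early noise-free build). Scaling restores the fusion comparison to a
comparison of information rather than of units.

The harness fits the R-spectrum baseline and all configured CWT scales per
selector, picks the best scale by validation R^2 (ties: lower RMSE, then
fewer features), and then fits the four fusion combinations spectra /
+color / +texture / +color+texture at that scale. Per-stage best scales are
always recomputed from the data, never hard-coded, since they are data
outcomes. On campaigns where K drives texture, the +texture fusion improves
validation R^2 over spectra-only in 8 of 10 seeded repetitions (mean gain
about +0.2); with the texture and color links switched off the improvement
rate drops below one half and the mean gain shrinks — the qualitative
pattern that motivates fusion in the first place.

# Numerical choices and degenerate inputs

* Zero-variance coefficient columns in correlation maps give |r| = 0 and a
  degenerate flag rather than NA.
* A constant coefficient field over the mask yields an all-zero grayscale
  image with a warning.
* GLCM correlation of a degenerate (constant) region is reported as 0 with
  a flag; 0 ln 0 is taken as 0 in the entropy.
* Empty image-feature selections degrade fusion to spectra-only, flagged in
  the report row.
* Ties everywhere resolve toward the lower variable/band index; fold
  partitions are seeded and shared across subset comparisons.
* Sub-seeds derive from the master seed by one documented affine scheme
  (`seed * 7919 + stream, mod 2^31 - 1`), so each stage is independently
  reproducible.

# Known limitations

* The K links and biological variability are linear and Gaussian; real
  leaf optics are neither. Absolute accuracies on synthetic campaigns do
  not transfer to field data.
* sym2 is the only validated mother wavelet (others are pluggable but
  untested). The discrete wavelet transform is out of scope.
* The generator renders one leaf per scene; multi-leaf scenes in
  leaf-position order are not modeled.
* SWIR wavelengths, alternative regressors (SVM, ensembles, deep models)
  and selectors (SPA, UVE, GA) are out of scope.
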