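---
title: "Quantifying nest camouflage through predator vision: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nest camouflage through predator vision: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camonest)
```

## The problem

Ground-nesting birds such as plovers, coursers and nightjars lay their eggs
on bare substrate and rely on background matching to escape detection.
Which component of their appearance — luminance, contrast, pattern or colour —
actually predicts whether a clutch survives to hatching? Answering this
requires (i) calibrated imagery that includes the ultraviolet band many
predators see, (ii) translation of camera measurements into the cone catches
of the relevant predator visual systems, (iii) metrics of how well a target
region (the clutch, or the incubating adult) matches its surrounds, and
(iv) survival models linking those metrics to predation hazard while
handling censored nests. `camonest` implements that pipeline, together with
a synthetic-data module that generates scenes and nest fates with known
ground truth so every stage can be validated end to end.

## Image calibration

Cameras respond non-linearly to radiance. `fit_linearization()` fits, per
channel, the monotone family

$$ \text{reflectance} = a\,(c / c_\max)^{g} + b, \qquad a > 0,\; g > 0, $$

to a ladder of diffuse reflectance standards (by default eight, 99% down to
2%), profiling the exponent numerically and solving the rest by least
squares. This family contains the identity and every power-law (gamma)
response, so noise-free gamma-encoded counts are fitted exactly; with
measured standards the per-channel $R^2$ is reported.

`normalize_to_reflectance()` rescales each linearized channel so that the
mean over a grey-standard region equals the standard's known reflectance
(sequential calibration with a 40% standard photographed in the scene).
Reflectance above 100% is legitimate (specular facets, bright substrate), so
`rescale_saturation()` never clips: when the global maximum is $M > 1$ the
stored 16-bit image is divided by $M$ and the factor $1/M$ recorded, and
processing reconstructs the true values in floating point.

UV and visible exposures are taken sequentially through different filters,
with a refocus in between, so `align_uv_visible()` estimates a uniform scale
plus translation by exhaustively maximizing the normalized cross-correlation
between the visible green and UV blue channels (the most correlated pair).
Rotation is excluded: a tripod-mounted refocus changes magnification, not
orientation. If the correlation peak stays below a floor (default 0.5) the
alignment fails loudly and a manual transform can be supplied.

## Mapping camera channels to predator cone catches

The quantum catch of receptor $i$ viewing reflectance $R(\lambda)$ under
illuminant $I(\lambda)$ is

$$ q_i = \frac{\int R(\lambda)\, S_i(\lambda)\, I(\lambda)\, d\lambda}
              {\int S_i(\lambda)\, I(\lambda)\, d\lambda}, $$

normalized so a perfect diffuse reflector scores 1 (`quantum_catch()`,
trapezoidal rule). Because camera passbands differ from animal receptors, a
degree-2 polynomial (intercept, linear, squares and pairwise interactions
over the five camera catches) is fitted per receptor across a library of
reflectance spectra (`fit_cone_catch_mapping()`); `apply_mapping()`
evaluates it per pixel. Three predator classes are built in: a dichromat
mammal (ferret: S, L at cone ratio 1:14), a trichromat primate (human:
S, M, L at 1:5.49:10.99) and a tetrachromat bird (peafowl: VS, S, M, L at
1:1.9:2.2:2.1 plus a double cone for luminance).

Choices left open by the problem and decided here:

* **Illuminant.** Flat (equal energy) by default; any measured spectrum can
  be supplied. A flat illuminant keeps synthetic validation self-contained.
* **Polynomial degree.** 2 with interactions (21 terms over 5 channels);
  configurable. Degree 2 already reaches training $R^2 \ge 0.998$ per
  receptor on the synthetic library; the residual is polynomial bias, which
  is largest for the violet receptor whose band sits between the camera's UV
  and blue passbands (held-out predictions are typically within 2% but
  individual violet catches can err by ~5%).
* **Mapping input.** Calibrated channel reflectances are treated as the
  camera's own quantum catches: a channel normalized against the grey
  standard *is* the camera-sensitivity-weighted catch of the pixel spectrum.
* **Negative predictions** (polynomial extrapolation) are clamped at
  $10^{-6}$ so log-ratio colour distances stay defined.
* **Synthetic sensitivities.** The built-in camera and receptor curves are
  Gaussians. The camera's five channels (600, 535, 455, 372, 342 nm; SDs
  55, 50, 55, 30, 28 nm) overlap and cover 320–680 nm without gaps, as a
  full-spectrum-converted SLR does; an early design with narrow,
  non-overlapping UV channels left a 390–440 nm coverage hole no real camera
  has and degraded the violet-receptor fit. Measured curves can be loaded
  from CSV.

## Achromatic metrics

All pattern, luminance and contrast metrics run on a luminance image
(`luminance_image()`): the L cone for the ferret, pixelwise $(L+M)/2$ for
the human, the double cone for the peafowl — pattern is thought to be
processed largely achromatically.

* **Mean luminance** and **contrast** are the mean and population SD of
  square-root transformed luminance in the region; the transform
  normalizes skewed natural luminance distributions. Contrast therefore
  scales as $\sqrt{c}$ when luminance scales by $c$.
* **Luminance difference** is the $L^1$ distance between the target's and
  background's 32-bin luminance histograms (equal-width bins spanning
  0–100%; values above 100% enter the top bin). Counts are normalized to
  proportions first — target and surround always differ in area, and raw
  counts would conflate area with appearance. Range $[0, 2]$.
* **Pattern difference** uses a granularity spectrum: the region (cropped to
  its mask bounding box, masked-out pixels replaced by the region mean) is
  passed through 17 FFT annular bandpass filters at scales 2 px to 512 px in
  $\sqrt 2$ steps, and the "energy" at each scale is the SD of the filtered
  pixels within the mask. `pattern_diff()` sums absolute energy differences
  across scales: sensitive to mismatches of marking size, spacing and
  contrast, blind to phase — it tests background matching, not template
  matching.

Numerical choices worth knowing:

* Scales are generated as $2^{1+k/2}$ so the power-of-two scales are exact
  in floating point, and every FFT bin is assigned to exactly one half-open
  octave band $[s, s\sqrt 2)$ via $\lfloor 2\log_2 p - 2 \rfloor$ of its
  period $p$ — a naive per-band radius test double-counts bins that land on
  band edges (e.g. a pure period-8 sinusoid).
* Mean padding (not windowing) suppresses spurious edge energy from the
  mask boundary; bands larger than the crop are retained with energy 0 so
  all spectra share the 17-scale bank.
* The square-root transform applies to mean luminance and contrast only;
  pattern energies are computed on untransformed luminance.

## Colour metrics

Colour discrimination follows the receptor-noise-limited model. Weber
fractions derive from cone ratios by noise pooling,
$\omega_i = \nu \sqrt{\eta_{\max}/\eta_i}$ with $\nu = 0.05$ for the most
abundant class, and the distance between catches $a, b$ uses log ratios
$\Delta f_i = \ln(a_i/b_i)$ in the standard quadratic forms for 2–4
receptors (`jnd_distance()`); ~1 JND is the discrimination threshold. The
distance is intensity-invariant and a metric on log-catch space.

`cluster_colours()` reduces a region to its dominant colours in two passes:
a local pass grows 4-connected clusters, admitting a pixel when it is
within 0.05 JND of the *adjacent pixel* it touches, so smooth gradients
chain into one colour; a global pass, largest cluster first, absorbs any
cluster within 1 JND of the (running) mean. Reporting stops at 99% coverage
or 32 colours. Comparing against the adjoining pixel rather than the cluster
running mean is deliberate: a gradient in sub-threshold steps must clump
regardless of its total span, which a running-mean criterion cannot satisfy
(the frontier drifts arbitrarily far from the mean); `local_compare =
"mean"` selects the stricter alternative. Scan order is row-major from the
top-left; coverage ties break by discovery order.

`colour_match_metrics()` then reports, for the single most abundant target
colour: `best_jnd`, its distance to the closest background colour, and
`mean_jnd`, its coverage-weighted mean distance to all reported background
colours (weights renormalized over the reported set, so truncation at the
stopping rule does not deflate the mean).

## Survival analysis

Nest fates are time-to-event data: predation is the event; hatching,
desertion, trampling, season end and unknown fates are censoring at the
last known date. `kaplan_meier()` produces product-limit curves with
Greenwood variance and log-transformed 95% CIs (clipped to $[0,1]$),
typically under `median_split()` of a metric (ties go to "low").
`cox_ph()` fits a fixed-effects Cox proportional-hazards model (Efron
approximation for ties) on internally standardized covariates, optionally
stratified by species so each species keeps its own baseline hazard. Both
are backed by the `survival` package; the test suite checks the Cox
estimates against an independently enumerated partial-likelihood oracle.
A mixed-effects (frailty) Cox and mixed-model interaction analyses are out
of scope; `fate_interaction_glm()` provides a fixed-effects logistic
approximation for the target-versus-background contrast interaction and is
labelled as such. `pooled_group_stats()` combines per-species summary rows
into sample-size-weighted pooled means and SDs.

## The synthetic-data module

`generate_scene()` renders a calibrated five-channel scene: an isotropic
$1/f^{\beta}$ Gaussian texture (default $\beta = 2$, the slope of natural
images) around an earth-toned base colour with low UV reflectance, and an
elliptical target composited in. Four knobs control the mismatch between
target and surround — relative luminance offset, texture-scale factor,
texture-amplitude factor, and a chromatic offset expressed in JND of a
reference equal-abundance dichromat reading the visible-green and UV-blue
channels (chosen because that offset is analytically invertible: the
requested JND maps exactly to a log-catch shift split between the two
channels). With all knobs at zero the target reuses the background's own
texture realization and is a perfect match by construction.

Generator defaults are fixed study conditions, not tuning dials:

* 96 px scenes at 2 px/mm; target ellipse semi-axes size/3 × size/4.5
  (an incubating bird or clutch fills much of a close-range frame);
* texture amplitude 0.06 reflectance units; largest texture period capped
  at 8 px through a smooth Butterworth-style rolloff. The cap keeps the
  substrate grain finer than the target so both regions sample many
  independent texture patches — without it, frame-scale $1/f^2$ structure
  makes even a "matched" target measurably different from its surround; the
  smooth rolloff avoids spectral leakage across bandpass-band edges that a
  hard cutoff causes once regions are cropped.
* `generate_study()` draws predation times from an exponential hazard
  $\lambda_0 \exp(\beta z)$ on the standardized mismatch covariate, with
  $\lambda_0 = 0.015$/day over a 28-day incubation (roughly a third of
  unmatched nests depredated before hatching) and independent censoring
  causes — desertion 0.19, trampling 0.03, season end 0.02 — scaled from
  the census of a single field season of about 160 nests.

What the generator does **not** emulate: specular highlights and cast
shadows, three-dimensional relief, anisotropic vegetation texture, measured
(non-Gaussian) sensitivities, inter-nest habitat heterogeneity, or
predator behaviour. Passing end-to-end tests therefore demonstrates that
the pipeline recovers known effects under its own assumptions — not that
those assumptions exhaust real nest scenes.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles: analytic
inversions (known gamma curves, known JND offsets), direct integration
versus the polynomial mapping, hand product-limit calculations, an
enumerated Cox partial likelihood, and metric axioms (symmetry, identity,
triangle inequality) for the $L^1$ and JND distances. The end-to-end check
generates 150 scenes per replicate along a pattern-scale gradient, measures
`pattern_diff` through the full imaging path, simulates fates with a true
log hazard ratio of 1 per SD, and requires the Cox fit to recover a
positive, significant effect in at least 80% of 20 seeded replicates —
96 px scenes and 150 nests give that experiment comfortable power while
keeping a full validation run quick on a laptop.

## Known limitations

* Alignment is scale-plus-integer-translation; sub-pixel shifts and
  rotation are not modelled.
* The polynomial mapping is only as good as the spectral library it is
  fitted on; violet-band receptors carry the largest extrapolation bias.
* Colour clustering is greedy and order-dependent by design (documented tie
  rules), as in the field's standard tools; it is not a global optimum.
* Fixed-effects Cox replaces the random-effects (frailty) formulation;
  species enter as strata, repeated measures per nest across visual systems
  must be analysed per system.
* Histogram and granularity metrics compare distributions, not spatial
  arrangement: two targets with identical spectra but different layouts are
  equivalent to these metrics — intentionally, as a background-matching
  (not template-matching) hypothesis.
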