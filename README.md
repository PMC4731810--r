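# camonest

Camouflage metrics through predator eyes, and their link to nest survival.

Ground-nesting plovers, coursers and nightjars rely on background matching
to keep their clutches alive. `camonest` is for researchers who have (or
simulate) calibrated multispectral photographs of nests and want to ask:
*how well does this clutch — or this incubating adult — match its surround,
as seen by its actual predators, and does that matching predict survival?*
The package covers the whole chain: camera calibration, cone-catch
modelling of dichromat/trichromat/tetrachromat predators, achromatic and
chromatic background-matching metrics, survival analysis of predation, and
a synthetic-scene generator for end-to-end validation.

## The metrics

Working on a luminance image defined per visual system (L cone for a
ferret, (L+M)/2 for a human, double cone for a peafowl):

- **mean luminance / contrast** — mean and SD of √luminance in a region;
- **Luminance_diff** — L1 distance between the 32-bin luminance histograms
  of target and background, `Σ_b |p_t(b) − p_b(b)|` ∈ [0, 2];
- **Pattern_diff** — L1 distance between granularity spectra,
  `Σ_s |E_t(s) − E_b(s)|`, where `E(s)` is the SD of the region after an
  FFT bandpass at scale `s` (17 scales, 2 px to 512 px in √2 steps);
- **colour match** — receptor-noise-limited (Vorobyev–Osorio) JND distances,
  with Weber fractions `ω_i = 0.05·√(η_max/η_i)` from cone ratios
  (ferret 1:14, human 1:5.49:10.99, peafowl 1:1.9:2.2:2.1), between the most
  abundant target colour and the background colours found by 0.05-JND local
  / 1-JND global clustering: `best_jnd` (closest background colour) and
  `mean_jnd` (coverage-weighted mean).

Associations with survival use Kaplan–Meier curves under median splits and
fixed-effects Cox proportional hazards (Efron ties, optional species
strata), with censoring for hatched, deserted and lost nests.

## Worked example

Fit a ferret (dichromat) predator model on a synthetic spectral library,
render a matched and a mismatched nest scene, and measure both:

```r
library(camonest)

lib    <- generate_spectra(200, seed = 1)
ferret <- fit_predator_model(vs_ferret(), lib, camera_gaussian())
round(ferret$mapping$r_squared, 4)
#>    sws    lws
#> 0.9991 0.9998

matched <- generate_scene(scene_spec(seed = 8))
poor    <- generate_scene(scene_spec(seed = 8, pattern_scale = 3, colour_jnd = 2))
rec <- rbind(
  run_nest(matched$image, matched$regions, ferret, nest_id = "matched"),
  run_nest(poor$image,    poor$regions,    ferret, nest_id = "mismatched"))
rec[, c("nest_id", "contrast_target", "luminance_diff", "pattern_diff",
        "best_jnd", "mean_jnd")]
#>      nest_id contrast_target luminance_diff pattern_diff best_jnd mean_jnd
#> 1    matched          0.0583         0.0702      0.00986  0.00246    0.172
#> 2 mismatched          0.0520         0.2037      0.14442  0.49068    0.566
```

The matched target (which reuses the background's own texture) sits near
zero on every relative metric; enlarging its texture grain 3× and shifting
its colour raises `Pattern_diff` ~15-fold and moves the best colour match
away from zero. An end-to-end replicate — 150 scenes along a pattern
mismatch gradient, nest fates simulated with a true log hazard ratio of 1
per SD of measured `Pattern_diff`, Cox fit on the result:

```r
recovery_replicate(1, predator = ferret, n_nests = 150)
#>   beta_hat    se     z n_events
#> 1    1.486 0.255 5.838       50
```

A thin command-line wrapper with subcommands `calibrate`, `simulate-scene`,
`simulate-study`, `metrics` and `survive` is installed at
`inst/cli/camonest`.

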