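#' Generate a synthetic library of smooth reflectance spectra
#'
#' Natural reflectance spectra are smooth, positive and bounded. The generator
#' draws each spectrum from a low-order random Fourier basis with amplitudes
#' decaying as `1 / k^smoothness`, then squashes it into (0.01, 0.99) through
#' a logistic link. Used to fit camera-to-cone-catch mappings without a
#' measured spectral database.
#'
#' @param n number of spectra (>= 20).
#' @param wl wavelength grid, nm.
#' @param smoothness amplitude decay exponent of the Fourier components
#'   (larger = smoother spectra).
#' @param n_terms number of Fourier components.
#' @param seed RNG seed (reproducible library).
#' @return matrix `n x length(wl)` of reflectances in (0.01, 0.99) with
#'   attribute `wavelength_nm`.
#' @export
generate_spectra <- function(n, wl = default_wl(), smoothness = 2.5,
                             n_terms = 5L, seed = 1L) {
  if (n < 20) stop("a spectral library needs at least 20 spectra")
  set.seed(seed)
  t <- (wl - min(wl)) / diff(range(wl))
  out <- matrix(0, n, length(wl))
  for (i in seq_len(n)) {
    z <- rnorm(1, 0, 0.8)
    for (k in seq_len(n_terms)) {
      amp <- 1.6 / k^smoothness
      z <- z + rnorm(1, 0, amp) * cos(2 * pi * k * t) +
               rnorm(1, 0, amp) * sin(2 * pi * k * t)
    }
    out[i, ] <- 0.01 + 0.98 * plogis(z)
  }
  attr(out, "wavelength_nm") <- wl
  out
}

#' Simulate raw camera counts for reflectance standards
#'
#' Emulates a camera with a power-law (gamma-style) response:
#' `count = full_scale * (gain * reflectance)^(1 / exponent)`, noise-free.
#' Used to exercise and validate [fit_linearization()].
#'
#' @param reflectances standard reflectances in (0, 1].
#' @param exponent power-law exponent of the sensor response (2.2).
#' @param gains named per-channel gains (default 5 camera channels).
#' @param full_scale full-scale count (65535).
#' @return data.frame with columns `channel`, `reflectance`, `mean_count`.
#' @export
simulate_camera_counts <- function(reflectances, exponent = 2.2,
                                   gains = c(visR = 1, visG = 0.95, visB = 0.9,
                                             uvR = 0.5, uvB = 0.45),
                                   full_scale = 65535) {
  do.call(rbind, lapply(names(gains), function(ch) {
    data.frame(channel = ch, reflectance = reflectances,
               mean_count = full_scale *
                 pmin(gains[[ch]] * reflectances, 1)^(1 / exponent))
  }))
}

# isotropic 1/f^beta Gaussian random field, standardized to mean 0, sd 1.
# beta is the power-spectrum exponent (power ~ f^-beta); max_period caps the
# largest spatial period (smooth Butterworth-style rolloff -- a hard spectral
# cutoff would leak across bandpass boundaries when regions are cropped) so
# the texture grain stays finer than the frame
field_1f <- function(size, beta = 2, max_period = Inf) {
  wn <- matrix(rnorm(size * size), size, size)
  ft <- fft(wn)
  f <- c(0:floor(size / 2), -((ceiling(size / 2) - 1):1)) / size
  r <- sqrt(outer(f^2, f^2, `+`))
  hp <- if (is.finite(max_period))
    1 / (1 + ((1 / max_period) / pmax(r, 1e-12))^6) else 1
  amp <- ifelse(r > 0, r^(-beta / 2) * hp, 0)
  x <- Re(fft(ft * amp, inverse = TRUE)) / length(wn)
  (x - mean(x)) / sd_pop(x)
}

#' Scene specification for the synthetic nest-scene generator
#'
#' Describes one synthetic calibrated nest scene: an isotropic 1/f^beta
#' textured background with an elliptical target (clutch or incubating adult)
#' composited into it, with controllable luminance, pattern-scale, contrast
#' and colour mismatch between target and background.
#'
#' Defaults emulate a close-range nest photograph: a 96 px scene at 2 px/mm,
#' natural-image-like background texture (power exponent 2), texture amplitude
#' 0.06 reflectance units around an earth-toned 5-channel base colour with low
#' UV reflectance, and a target ellipse covering roughly an eighth of the
#' frame. With all mismatch knobs at 0 the target reuses the background's own
#' texture field, so it is a perfect background match by construction.
#'
#' @param size image side, px (>= 64).
#' @param px_per_mm spatial scale.
#' @param bg_beta background texture power-spectrum exponent.
#' @param bg_max_period largest texture period, px: keeps the substrate grain
#'   finer than the frame so target and background regions sample many
#'   independent texture patches (a matched target is then matched in its
#'   measured spectra too, not just in expectation).
#' @param bg_amp background texture amplitude, reflectance units.
#' @param bg_base background base reflectance, 5 channels in (0, 1).
#' @param target_axes ellipse semi-axes (row, col), px.
#' @param lum_mismatch relative luminance offset of the target base colour
#'   (0.2 = 20% brighter).
#' @param pattern_scale factor by which target texture features are enlarged
#'   relative to the background (1 = matched).
#' @param contrast_mismatch relative increase of target texture amplitude.
#' @param colour_jnd chromatic offset of the target base colour, in JND of a
#'   reference equal-abundance dichromat reading the visG and uvB channels
#'   (analytically invertible, see [jnd_distance()]).
#' @param seed RNG seed.
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(size = 96L, px_per_mm = 2,
                       bg_beta = 2, bg_max_period = 8, bg_amp = 0.06,
                       bg_base = c(visR = 0.30, visG = 0.28, visB = 0.22,
                                   uvR = 0.10, uvB = 0.08),
                       target_axes = c(size / 3, size / 4.5),
                       lum_mismatch = 0, pattern_scale = 1,
                       contrast_mismatch = 0, colour_jnd = 0, seed = 1L) {
  if (size < 64) stop("scene size must be >= 64 px")
  if (bg_amp < 0 || any(bg_base <= 0 | bg_base >= 1))
    stop("amplitudes must be >= 0 and base reflectances in (0, 1)")
  if (any(target_axes >= size / 2)) stop("target larger than the image")
  structure(list(size = as.integer(size), px_per_mm = px_per_mm,
                 bg_beta = bg_beta, bg_max_period = bg_max_period,
                 bg_amp = bg_amp, bg_base = bg_base,
                 target_axes = target_axes, lum_mismatch = lum_mismatch,
                 pattern_scale = pattern_scale,
                 contrast_mismatch = contrast_mismatch,
                 colour_jnd = colour_jnd, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Generate a synthetic calibrated nest scene
#'
#' Renders the scene described by a [scene_spec()]: a seeded 1/f^beta
#' background texture applied identically to all five reflectance channels
#' around the base colour, and an elliptical target whose base colour, texture
#' amplitude, texture scale and chromaticity are offset by the requested
#' mismatch knobs. A matched target (`pattern_scale = 1`) reuses the
#' background's texture realization inside the ellipse. The colour knob
#' multiplies the target's visG channel by `exp(delta)` and uvB by
#' `exp(-delta)` with delta chosen so a reference equal-abundance dichromat
#' viewing those channels sees the requested JND offset.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` ([msimage]), `regions` ([region_set]) and
#'   `truth` (the generating parameters).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  size <- spec$size
  t_bg <- field_1f(size, spec$bg_beta, spec$bg_max_period)
  if (spec$pattern_scale == 1) {
    t_tg <- t_bg
  } else {
    sub <- max(8L, round(size / spec$pattern_scale))
    f <- field_1f(sub, spec$bg_beta, spec$bg_max_period)
    f <- matrix(as.numeric(EBImage::resize(f, w = size, h = size)), size, size)
    t_tg <- (f - mean(f)) / sd_pop(f)
  }
  # chromatic offset: reference dichromat with equal cone abundance,
  # weber = (0.05, 0.05); jnd = 2*delta / sqrt(2*0.05^2)
  delta <- spec$colour_jnd * sqrt(2 * 0.05^2) / 2
  t_base <- spec$bg_base * (1 + spec$lum_mismatch)
  t_base["visG"] <- t_base["visG"] * exp(delta)
  t_base["uvB"] <- t_base["uvB"] * exp(-delta)
  t_amp <- spec$bg_amp * (1 + spec$contrast_mismatch)
  ctr <- (size + 1) / 2
  rr <- row(t_bg); cc <- col(t_bg)
  ellipse <- ((rr - ctr) / spec$target_axes[1])^2 +
             ((cc - ctr) / spec$target_axes[2])^2 <= 1
  channels <- lapply(names(spec$bg_base), function(ch) {
    m <- spec$bg_base[[ch]] + spec$bg_amp * t_bg
    m[ellipse] <- t_base[[ch]] + t_amp * t_tg[ellipse]
    pmin(pmax(m, 0.005), 1.2)
  })
  img <- msimage(channels, px_per_mm = spec$px_per_mm)
  regions <- region_set(ellipse, !ellipse)
  list(image = img, regions = regions, truth = unclass(spec))
}

#' Study specification for synthetic nest fates
#'
#' Describes the survival design: number of nests, incubation length, the
#' log-hazard effect of a (standardized) camouflage mismatch covariate, the
#' baseline daily predation hazard, and independent censoring processes.
#' Defaults emulate the study conditions of a single-season plover dataset:
#' 79 nests, 28-day incubation, baseline hazard 0.015/day (about a third of
#' unmatched nests depredated before hatching), desertion much more common
#' than trampling or season-end censoring.
#'
#' @param n_nests number of nests.
#' @param incubation_days hatching horizon, days.
#' @param beta log hazard ratio per SD of the mismatch covariate.
#' @param baseline_hazard events per nest-day at mismatch = mean.
#' @param censor_rates named probabilities of each independent censoring
#'   cause; must sum to < 1.
#' @param seed RNG seed.
#' @return list of class `study_spec`.
#' @export
study_spec <- function(n_nests = 79L, incubation_days = 28, beta = 1,
                       baseline_hazard = 0.015,
                       censor_rates = c(desertion = 0.19, trampling = 0.03,
                                        season_end = 0.02),
                       seed = 1L) {
  if (n_nests < 1) stop("n_nests must be >= 1")
  if (any(censor_rates < 0) || sum(censor_rates) >= 1)
    stop("censoring rates must be in [0, 1] and sum below 1")
  structure(list(n_nests = as.integer(n_nests),
                 incubation_days = incubation_days, beta = beta,
                 baseline_hazard = baseline_hazard,
                 censor_rates = censor_rates, seed = as.integer(seed)),
            class = "study_spec")
}

#' Generate nest fates whose predation hazard depends on mismatch
#'
#' Predation times are exponential with hazard
#' `baseline_hazard * exp(beta * z)` where `z` is the standardized mismatch
#' covariate. Each censoring cause independently strikes a nest with its
#' configured probability at a uniform time within incubation. The observed
#' time is the earliest of predation, censoring and hatching; only predation
#' counts as an event.
#'
#' @param spec a [study_spec()].
#' @param mismatch per-nest camouflage mismatch values (length `n_nests`;
#'   recycled scalar allowed).
#' @return data.frame with `nest_id`, `time_days`, `event`, `censor_reason`
#'   and the `mismatch` covariate.
#' @export
generate_study <- function(spec, mismatch) {
  stopifnot(inherits(spec, "study_spec"))
  n <- spec$n_nests
  mismatch <- rep_len(mismatch, n)
  if (any(!is.finite(mismatch))) stop("mismatch values must be finite")
  set.seed(spec$seed)
  z <- if (sd(mismatch) > 0) (mismatch - mean(mismatch)) / sd(mismatch)
       else rep(0, n)
  hazard <- spec$baseline_hazard * exp(spec$beta * z)
  t_pred <- rexp(n, rate = hazard)
  t_cens <- rep(Inf, n)
  reason <- rep("hatched", n)
  for (cause in names(spec$censor_rates)) {
    hit <- runif(n) < spec$censor_rates[[cause]]
    t_cause <- ifelse(hit, runif(n, 0, spec$incubation_days), Inf)
    upd <- t_cause < t_cens
    t_cens[upd] <- t_cause[upd]
    reason[upd] <- cause
  }
  obs <- pmin(t_pred, t_cens, spec$incubation_days)
  event <- as.integer(t_pred <= pmin(t_cens, spec$incubation_days))
  data.frame(nest_id = sprintf("nest%03d", seq_len(n)),
             time_days = pmax(obs, 1e-6),
             event = event,
             censor_reason = ifelse(event == 1, "depredated",
                                    ifelse(t_cens < spec$incubation_days,
                                           reason, "hatched")),
             mismatch = mismatch)
}
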