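test_that("luminance channels follow each visual system's rule", {
  mk <- function(vals, receptors)
    as_cone_image(array(rep(vals, each = 16), c(4, 4, length(vals))), receptors)

  ferret <- vs_ferret()
  cone_f <- mk(c(0.7, 0.3), c("sws", "lws"))
  expect_equal(unique(as.vector(luminance_image(cone_f, ferret))), 0.3)

  human <- vs_human()
  cone_h <- mk(c(0.6, 0.4, 0.2), c("sws", "mws", "lws"))
  expect_equal(unique(as.vector(luminance_image(cone_h, human))), 0.3)

  peafowl <- vs_peafowl()
  cone_p <- mk(c(0.1, 0.2, 0.3, 0.4, 0.55), c("vs", "sws", "mws", "lws", "dbl"))
  expect_equal(unique(as.vector(luminance_image(cone_p, peafowl))), 0.55)

  expect_error(luminance_image(mk(c(1, 2), c("a", "b")), ferret),
               "lacks luminance channel")
})

test_that("mean luminance and contrast use the square-root transform", {
  mask <- matrix(TRUE, 4, 4)
  expect_equal(mean_luminance(matrix(0.25, 4, 4), mask), 0.5)
  expect_equal(mean_luminance(matrix(0, 4, 4), mask), 0)

  half <- matrix(c(rep(0.04, 8), rep(0.16, 8)), 4, 4)
  expect_equal(mean_luminance(half, mask), 0.3)     # mean of {0.2, 0.4}
  expect_equal(contrast(half, mask), 0.1)           # SD of {0.2, 0.4}
  expect_equal(contrast(matrix(0.7, 4, 4), mask), 0)

  # sqrt homogeneity: scaling luminance by c scales contrast by sqrt(c)
  set.seed(2)
  lum <- matrix(runif(64, 0, 1), 8, 8)
  m8 <- matrix(TRUE, 8, 8)
  expect_equal(contrast(4 * lum, m8), 2 * contrast(lum, m8), tolerance = 1e-12)

  # permutation invariance over masked pixels
  perm <- matrix(sample(as.vector(lum)), 8, 8)
  expect_equal(mean_luminance(perm, m8), mean_luminance(lum, m8))
  expect_equal(contrast(perm, m8), contrast(lum, m8))

  expect_error(mean_luminance(lum, m8 & FALSE), "empty")
  expect_error(contrast(lum, m8 & FALSE), "2 pixels")
})

test_that("luminance histograms bin 32 levels over 0-100% reflectance", {
  mask <- matrix(TRUE, 4, 4)
  h <- luminance_histogram(matrix(0.5, 4, 4), mask)
  expect_length(h, 32)
  expect_equal(h[17], 1)                       # bin index 16, 0-based
  expect_equal(sum(h), 1)

  two <- matrix(c(rep(0.1, 8), rep(0.9, 8)), 4, 4)
  h2 <- luminance_histogram(two, mask)
  expect_equal(h2[c(4, 29)], c(0.5, 0.5))      # floor(32 v): bins 3 and 28

  # values above 100% fall in the top bin
  h3 <- luminance_histogram(matrix(1.4, 4, 4), mask)
  expect_equal(h3[32], 1)

  set.seed(9)
  hr <- luminance_histogram(matrix(runif(100, 0, 1.2), 10, 10),
                            matrix(TRUE, 10, 10))
  expect_equal(sum(hr), 1, tolerance = 1e-9)
})

test_that("luminance_diff is an L1 metric on histograms", {
  u <- c(1, rep(0, 31))
  v <- c(0.5, 0.5, rep(0, 30))
  w <- c(rep(0, 31), 1)
  expect_equal(luminance_diff(u, u), 0)
  expect_equal(luminance_diff(u, w), 2)
  expect_equal(luminance_diff(u, v), 1)
  set.seed(4)
  for (i in 1:20) {
    a <- prop.table(runif(32)); b <- prop.table(runif(32)); c <- prop.table(runif(32))
    expect_equal(luminance_diff(a, b), luminance_diff(b, a))
    expect_gte(luminance_diff(a, b) + luminance_diff(b, c) -
                 luminance_diff(a, c), -1e-12)
  }
  expect_error(luminance_diff(u, u[1:16]), "bins")
})

test_that("bandpass bank spans 2 to 512 px in sqrt(2) steps", {
  b <- bandpass_bank()
  expect_length(b, 17)
  expect_equal(b[1], 2)
  expect_equal(b[17], 512)
  expect_equal(b[-1] / b[-17], rep(sqrt(2), 16), tolerance = 1e-12)
  expect_equal(bandpass_bank(4), c(2, 2 * sqrt(2), 4))
  expect_error(bandpass_bank(1), ">= 2")
})

# local copy of the population SD used as the independent total-energy oracle
sd_pop_test <- function(x) sqrt(mean((x - mean(x))^2))

test_that("pattern spectra localize energy at the generating scale", {
  mask <- matrix(TRUE, 64, 64)
  expect_true(all(pattern_spectrum(matrix(0.5, 64, 64), mask)$energy == 0))

  # horizontal sinusoid of period 8 px: energy in the band [8, 8 sqrt(2))
  x <- outer(rep(1, 64), sin(2 * pi * (1:64) / 8))
  sp <- pattern_spectrum(x, mask)
  band8 <- which(abs(sp$scale_px - 8) < 1e-9)
  expect_gte(sp$energy[band8], 10 * max(sp$energy[-band8]))

  # Parseval: quadrature sum of band energies ~ SD of the crop
  expect_equal(sqrt(sum(sp$energy^2)), sd_pop_test(x), tolerance = 0.05)

  expect_error(pattern_spectrum(x, matrix(c(TRUE, rep(FALSE, 64 * 64 - 1)), 64)),
               "bounding box")
})

test_that("pattern spectra are translation invariant for periodic textures", {
  set.seed(6)
  base <- sin(2 * pi * outer(1:64, rep(1, 64)) / 16) +
          0.5 * sin(2 * pi * outer(rep(1, 64), 1:64) / 8)
  mask <- matrix(TRUE, 64, 64)
  sp1 <- pattern_spectrum(base, mask)
  shifted <- base[c(17:64, 1:16), c(33:64, 1:32)]   # cyclic shift
  sp2 <- pattern_spectrum(shifted, mask)
  on <- sp1$energy > 1e-9
  expect_lt(max(abs(sp1$energy[on] - sp2$energy[on]) / sp1$energy[on]), 0.02)
})

test_that("pattern_diff is an L1 metric over matching scale banks", {
  mask <- matrix(TRUE, 64, 64)
  s8 <- pattern_spectrum(outer(rep(1, 64), sin(2 * pi * (1:64) / 8)), mask)
  s32 <- pattern_spectrum(outer(rep(1, 64), sin(2 * pi * (1:64) / 32)), mask)
  expect_equal(pattern_diff(s8, s8), 0)
  # non-overlapping bands: difference is the sum of the two peak energies
  expect_equal(pattern_diff(s8, s32),
               sum(s8$energy) + sum(s32$energy), tolerance = 0.02)

  set.seed(10)
  specs <- replicate(3, {
    sp <- s8; sp$energy <- runif(17); sp
  }, simplify = FALSE)
  expect_equal(pattern_diff(specs[[1]], specs[[2]]),
               pattern_diff(specs[[2]], specs[[1]]))
  expect_gte(pattern_diff(specs[[1]], specs[[2]]) +
               pattern_diff(specs[[2]], specs[[3]]) -
               pattern_diff(specs[[1]], specs[[3]]), -1e-12)

  bad <- pattern_spectrum(s8_src <- outer(rep(1, 64), sin(2 * pi * (1:64) / 8)),
                          mask, scales = bandpass_bank(16))
  expect_error(pattern_diff(s8, bad), "scale lists")
})
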