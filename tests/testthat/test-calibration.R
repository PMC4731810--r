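test_that("linearization recovers simulated power-law camera responses", {
  refl <- c(0.99, 0.8, 0.6, 0.4, 0.2, 0.1, 0.05, 0.02)
  std <- simulate_camera_counts(refl, exponent = 2.2)
  fit <- fit_linearization(std)
  r2 <- vapply(fit$channels, `[[`, numeric(1), "r_squared")
  expect_true(all(r2 >= 0.999))

  # querying at the 50% standard inverts the known simulated curve
  count50 <- 65535 * 0.5^(1 / 2.2)
  expect_lt(abs(linearize(fit, count50, "visR") - 0.5), 0.005)

  # already-linear standards: identity up to scale, R^2 = 1
  lin <- data.frame(channel = "ch", reflectance = refl,
                    mean_count = 65535 * refl)
  fit_lin <- fit_linearization(lin)
  expect_equal(fit_lin$channels$ch$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit_lin$channels$ch$g, 1, tolerance = 1e-3)
  expect_equal(linearize(fit_lin, 65535 * 0.3, "ch"), 0.3, tolerance = 1e-6)
})

test_that("linearization is monotone and rejects bad standards", {
  refl <- c(0.99, 0.8, 0.6, 0.4, 0.2, 0.1, 0.05, 0.02)
  std <- simulate_camera_counts(refl, exponent = 2.2)
  fit <- fit_linearization(std)
  grid <- seq(0, 65535, length.out = 200)
  for (ch in names(fit$channels))
    expect_true(all(diff(linearize(fit, grid, ch)) >= 0))

  few <- data.frame(channel = "a", reflectance = c(0.9, 0.5, 0.2),
                    mean_count = c(60000, 40000, 20000))
  expect_error(fit_linearization(few), "4 standards")
  nonmono <- data.frame(channel = "a", reflectance = c(0.9, 0.5, 0.3, 0.2),
                        mean_count = c(60000, 40000, 45000, 20000))
  expect_error(fit_linearization(nonmono), "monotone")
})

test_that("grey-standard normalization scales channels to true reflectance", {
  region <- matrix(FALSE, 10, 10); region[1:3, 1:3] <- TRUE
  img <- matrix(0.1, 10, 10); img[region] <- 0.2
  out <- normalize_to_reflectance(img, region, 0.40)
  expect_equal(mean(out[region]), 0.40)
  expect_equal(out[10, 10], 0.2)   # scaled by 2

  uniform <- matrix(0.37, 8, 8)
  expect_equal(unique(as.vector(
    normalize_to_reflectance(uniform, region[1:8, 1:8], 0.40))), 0.40)

  # render-then-recover round trip at known reflectances
  set.seed(5)
  truth <- matrix(runif(100, 0.05, 0.9), 10, 10)
  gain <- 0.137
  rendered <- truth * gain
  std_region <- truth > 0            # use whole image as its own standard
  recovered <- normalize_to_reflectance(rendered, std_region, mean(truth))
  expect_lt(max(abs(recovered - truth)), 1e-6)

  expect_error(normalize_to_reflectance(img * 0, region, 0.4), "calibration")
})

test_that("saturation rescaling records 1/M and round-trips losslessly", {
  set.seed(7)
  ch <- matrix(runif(64, 0, 1), 8, 8)
  ch[1] <- 1.2
  rs <- rescale_saturation(ch)
  expect_equal(rs$saturation_scale, 1 / 1.2)
  back <- reconstruct_reflectance(rs$stored, rs$saturation_scale)
  expect_lt(max(abs(back - ch)), 2^-15)

  ch9 <- matrix(runif(64, 0, 0.9), 8, 8)
  rs9 <- rescale_saturation(ch9)
  expect_equal(rs9$saturation_scale, 1)

  ch15 <- matrix(runif(400, 0, 1.5), 20, 20); ch15[1] <- 1.5
  rs15 <- rescale_saturation(ch15)
  back15 <- reconstruct_reflectance(rs15$stored, rs15$saturation_scale)
  expect_lt(max(abs(back15 - ch15)), 2^-15)

  expect_error(rescale_saturation(matrix(c(-1, 1), 1)), "non-negative")
})

test_that("UV/visible alignment recovers known synthetic transforms", {
  set.seed(11)
  base <- field_1f(64, 2) + 2
  vis <- list(base * 0.9, base, base * 1.1)
  # identity
  uv <- list(base * 0.5, base)
  al <- align_uv_visible(vis, uv, px_per_mm = 4)
  tr <- attr(al, "transform")
  expect_equal(tr$scale, 1)
  expect_equal(c(tr$dy, tr$dx), c(0, 0))
  expect_equal(attr(al, "px_per_mm"), 4)

  # known integer shift (content moved by dy = 5, dx = -3); alignment must undo it
  shifted <- lapply(uv, function(ch) camonest:::shift_image(ch, 5, -3))
  al2 <- align_uv_visible(vis, shifted, px_per_mm = 4)
  tr2 <- attr(al2, "transform")
  expect_equal(c(tr2$dy, tr2$dx), c(-5, 3))
  expect_equal(tr2$scale, 1)

  # known scale about centre, recovered within grid resolution
  scaled <- lapply(uv, function(ch) camonest:::scale_about_centre(ch, 1 / 1.02))
  al3 <- align_uv_visible(vis, scaled, px_per_mm = 4)
  expect_lt(abs(attr(al3, "transform")$scale - 1.02), 0.011)

  # uncorrelated images fail with an informative error
  noise <- list(matrix(rnorm(64^2), 64), matrix(rnorm(64^2), 64))
  expect_error(align_uv_visible(vis, noise, px_per_mm = 4), "alignment failed")
})

test_that("rescaling to a target pixel scale uses bilinear resampling", {
  img <- matrix(runif(100 * 100), 100, 100)
  expect_identical(resize_to_scale(img, 10, 10), img)
  half <- resize_to_scale(img, 10, 5)
  expect_equal(dim(half), c(50, 50))
  const <- matrix(0.42, 30, 30)
  expect_equal(range(resize_to_scale(const, 10, 7)), c(0.42, 0.42),
               tolerance = 1e-12)

  ms <- msimage(replicate(5, img, simplify = FALSE), px_per_mm = 10)
  ms2 <- resize_to_scale(ms, 10, 5)
  expect_equal(attr(ms2, "px_per_mm"), 5)
  expect_equal(dim(ms2), c(50, 50, 5))
  expect_error(resize_to_scale(img, -1, 5), "scales")
})

test_that("multispectral stacks and masks round-trip through disk", {
  set.seed(3)
  chans <- replicate(5, matrix(runif(64, 0, 1.3), 8, 8), simplify = FALSE)
  ms <- msimage(chans, px_per_mm = 3.5, saturation_scale = 1 / 1.3)
  path <- tempfile(fileext = ".tif")
  write_msimage(ms, path)
  back <- read_msimage(path)
  expect_lt(max(abs(back - ms)), 1e-6)
  expect_equal(attr(back, "px_per_mm"), 3.5)
  expect_equal(attr(back, "saturation_scale"), 1 / 1.3)

  mask <- matrix(runif(64) > 0.5, 8, 8)
  mpath <- tempfile(fileext = ".png")
  write_mask(mask, mpath)
  expect_identical(read_mask(mpath), mask)
})

test_that("region sets enforce disjointness and exclusions", {
  t <- matrix(FALSE, 6, 6); t[2:3, 2:3] <- TRUE
  b <- !t
  ex <- matrix(FALSE, 6, 6); ex[1, ] <- TRUE; ex[2, 2] <- TRUE
  rs <- region_set(t, b, ex)
  expect_false(any(rs$target & rs$background))
  expect_false(rs$target[2, 2])
  expect_false(any(rs$background[1, ]))
  expect_error(region_set(t, t), "overlap")
  expect_error(region_set(t, b, matrix(TRUE, 6, 6)), "empty")
})
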