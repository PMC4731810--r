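test_that("Weber fractions follow the square-root abundance rule", {
  expect_equal(unname(weber_fractions(c(1, 14))),
               c(0.05 * sqrt(14), 0.05), tolerance = 1e-12)
  expect_equal(unname(weber_fractions(c(1, 5.49, 10.99))),
               0.05 * sqrt(10.99 / c(1, 5.49, 10.99)), tolerance = 1e-12)
  expect_equal(unname(weber_fractions(c(3, 3, 3))), rep(0.05, 3))
  expect_error(weber_fractions(c(1, 0)), "positive")
})

test_that("JND distance matches hand-evaluated receptor-noise formulas", {
  w2 <- weber_fractions(c(1, 14))
  expect_equal(jnd_distance(c(0.3, 0.4), c(0.3, 0.4), w2), 0)
  # dichromat with log-catch difference (0.1, 0)
  a <- c(exp(0.1), 1); b <- c(1, 1)
  expect_equal(jnd_distance(a, b, w2), 0.1 / sqrt(sum(w2^2)), tolerance = 1e-12)
  # intensity invariance: common scaling of both catches changes nothing
  expect_equal(jnd_distance(7 * a, 7 * b, w2), jnd_distance(a, b, w2))

  # trichromat and tetrachromat quadratic forms against direct evaluation
  w3 <- weber_fractions(c(1, 5.49, 10.99))
  df <- c(0.08, -0.02, 0.01)
  num <- w3[1]^2 * (df[2] - df[3])^2 + w3[2]^2 * (df[1] - df[3])^2 +
         w3[3]^2 * (df[1] - df[2])^2
  den <- (w3[1] * w3[2])^2 + (w3[1] * w3[3])^2 + (w3[2] * w3[3])^2
  expect_equal(jnd_distance(exp(df), c(1, 1, 1), w3), sqrt(num / den))

  w4 <- weber_fractions(c(1, 1.9, 2.2, 2.1))
  df4 <- c(0.05, 0, -0.03, 0.02)
  expect_gt(jnd_distance(exp(df4), rep(1, 4), w4), 0)

  expect_error(jnd_distance(c(0, 1), c(1, 1), w2), "positive")
})

test_that("JND distance satisfies the metric axioms on log-catch space", {
  set.seed(12)
  for (w in list(weber_fractions(c(1, 14)), weber_fractions(c(1, 5.49, 10.99)),
                 weber_fractions(c(1, 1.9, 2.2, 2.1)))) {
    n <- length(w)
    for (i in 1:15) {
      a <- exp(rnorm(n, 0, 0.3)); b <- exp(rnorm(n, 0, 0.3)); c <- exp(rnorm(n, 0, 0.3))
      expect_equal(jnd_distance(a, b, w), jnd_distance(b, a, w))
      expect_gte(jnd_distance(a, b, w) + jnd_distance(b, c, w) -
                   jnd_distance(a, c, w), -1e-10)
    }
  }
})

test_that("uniform regions cluster to a single full-coverage colour", {
  cone <- as_cone_image(array(rep(c(0.3, 0.2), each = 36), c(6, 6, 2)),
                        c("g", "u"))
  w <- weber_fractions(c(1, 1))
  cl <- cluster_colours(cone, matrix(TRUE, 6, 6), setNames(w, c("g", "u")))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$coverage, 1)
  expect_equal(unname(unlist(cl[1, c("g", "u")])), c(0.3, 0.2))
})

test_that("distinct patches separate and smooth gradients merge", {
  w <- setNames(weber_fractions(c(1, 14)), c("g", "u"))
  # two homogeneous patches 5 JND apart, 70% / 30% of the region
  e <- 5 * sqrt(sum(w^2))
  g <- matrix(0.4, 10, 10); g[, 8:10] <- 0.4 * exp(e)
  u <- matrix(0.3, 10, 10)
  cone <- as_cone_image(array(c(g, u), c(10, 10, 2)), c("g", "u"))
  cl <- cluster_colours(cone, matrix(TRUE, 10, 10), w)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$coverage, c(0.7, 0.3))
  expect_true(all(diff(cl$coverage) <= 0))

  # smooth gradient: < 0.05 JND steps spanning 2 JND end-to-end -> one colour
  n <- 60
  step <- 2 / (n - 1)                       # JND per column
  expect_lt(step, 0.05)
  lg <- 0.4 * exp(seq(0, 2 * sqrt(sum(w^2)), length.out = n))
  cone_g <- as_cone_image(array(c(matrix(lg, 1), matrix(0.3, 1, n)),
                                c(1, n, 2)), c("g", "u"))
  cl_g <- cluster_colours(cone_g, matrix(TRUE, 1, n), w)
  expect_equal(nrow(cl_g), 1)
  expect_equal(cl_g$coverage, 1)
})

test_that("cluster reporting respects coverage ordering and stopping rules", {
  set.seed(14)
  w <- setNames(weber_fractions(c(1, 1)), c("g", "u"))
  # many tiny isolated colours: max_colours and coverage_stop bound the list
  vals <- exp(seq(0, 3, length.out = 48))    # all > 1 JND apart pairwise? no: mixed
  g <- matrix(rep(vals, each = 1), 4, 12)
  u <- matrix(0.5, 4, 12)
  cone <- as_cone_image(array(c(g, u), c(4, 12, 2)), c("g", "u"))
  cl <- cluster_colours(cone, matrix(TRUE, 4, 12), w, max_colours = 3,
                        coverage_stop = 0.99)
  expect_lte(nrow(cl), 3)
  expect_lte(sum(cl$coverage), 1 + 1e-9)
  expect_true(all(diff(cl$coverage) <= 1e-12))
})

test_that("colour match metrics take best and coverage-weighted mean JND", {
  w <- setNames(weber_fractions(c(1, 14)), c("g", "u"))
  mk_cl <- function(cov, gvals, uvals)
    structure(data.frame(cluster = seq_along(cov), coverage = cov,
                         n_pixels = round(cov * 100), g = gvals, u = uvals),
              class = c("colour_clusters", "data.frame"))
  target <- mk_cl(1, 0.4, 0.3)
  # background colours exactly 1 and 3 JND from the target colour
  s <- sqrt(sum(w^2))
  bg <- mk_cl(c(0.75, 0.25), 0.4 * exp(c(1, 3) * s), c(0.3, 0.3))
  res <- colour_match_metrics(target, bg, w)
  expect_equal(res$best_jnd, 1, tolerance = 1e-9)
  expect_equal(res$mean_jnd, 0.75 * 1 + 0.25 * 3, tolerance = 1e-9)

  # target colour present verbatim in the background
  bg0 <- mk_cl(c(0.5, 0.5), c(0.4, 0.9), c(0.3, 0.3))
  expect_equal(colour_match_metrics(target, bg0, w)$best_jnd, 0)

  # single-cluster background: best equals mean
  bg1 <- mk_cl(1, 0.5, 0.35)
  res1 <- colour_match_metrics(target, bg1, w)
  expect_equal(res1$best_jnd, res1$mean_jnd)
  expect_lte(res$best_jnd, res$mean_jnd)
})
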