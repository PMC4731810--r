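#' Luminance channel of a cone-catch image
#'
#' Pattern, luminance and contrast metrics are computed on an achromatic
#' luminance image because pattern is thought to be encoded primarily by
#' achromatic vision. The luminance channel is defined per visual system:
#' ferret uses the L cone, human the pixelwise mean of L and M, and peafowl
#' the double cone.
#'
#' @param cone a [apply_mapping()] cone-catch image.
#' @param system the [visual_system()] whose `luminance_rule` to apply.
#' @return object of class `lum_image`: matrix of luminance values >= 0 with
#'   `system` and `px_per_mm` attributes.
#' @export
luminance_image <- function(cone, system) {
  rule <- system$luminance_rule
  chans <- dimnames(cone)[[3]]
  missing <- setdiff(rule$receptors, chans)
  if (length(missing))
    stop("cone image lacks luminance channel(s): ", paste(missing, collapse = ", "))
  out <- matrix(0, dim(cone)[1], dim(cone)[2])
  for (i in seq_along(rule$receptors))
    out <- out + rule$weights[i] * cone[, , rule$receptors[i]]
  structure(out, system = system$name, px_per_mm = attr(cone, "px_per_mm"),
            class = c("lum_image", "matrix", "array"))
}

#' Mean luminance and contrast within a region
#'
#' Both are computed on square-root transformed luminance values (the
#' transform brings skewed natural luminance distributions close to normal):
#' mean luminance is the mean of sqrt(pixel) over the masked pixels, contrast
#' is the population standard deviation of the same values.
#'
#' @param lum luminance matrix (values >= 0).
#' @param mask logical matrix selecting the region.
#' @return scalar.
#' @export
mean_luminance <- function(lum, mask) {
  mask <- mask != 0
  if (!any(mask)) stop("empty mask")
  mean(sqrt(lum[mask]))
}

#' @rdname mean_luminance
#' @export
contrast <- function(lum, mask) {
  mask <- mask != 0
  if (sum(mask) < 2L) stop("contrast needs at least 2 pixels")
  sd_pop(sqrt(lum[mask]))
}

#' 32-level luminance histogram of a region
#'
#' Pixels are binned into 32 equal-width luminance levels spanning 0% to 100%
#' reflectance; values above 100% go to the top bin. Counts are normalized to
#' proportions so that target and background regions of unequal area compare
#' on appearance alone.
#'
#' @param lum luminance matrix.
#' @param mask logical region mask.
#' @param bins number of levels (32).
#' @return numeric vector of `bins` proportions summing to 1.
#' @export
luminance_histogram <- function(lum, mask, bins = 32L) {
  mask <- mask != 0
  if (!any(mask)) stop("empty mask")
  v <- lum[mask]
  idx <- pmin(pmax(floor(v * bins), 0L), bins - 1L) + 1L
  tabulate(idx, nbins = bins) / length(v)
}

#' Luminance distribution difference between target and background
#'
#' The L1 distance between two 32-bin luminance histograms: the sum over bins
#' of absolute differences in pixel proportions. 0 for identical
#' distributions, 2 for fully disjoint ones.
#'
#' @param target_hist,background_hist histogram proportion vectors of equal
#'   length (see [luminance_histogram()]).
#' @return scalar in [0, 2].
#' @export
luminance_diff <- function(target_hist, background_hist) {
  if (length(target_hist) != length(background_hist))
    stop("histograms have different numbers of bins")
  sum(abs(target_hist - background_hist))
}

#' Bandpass scale bank
#'
#' The spatial scales analysed by the pattern-energy (granularity) spectrum:
#' starting at 2 px and increasing exponentially by sqrt(2) up to `max_scale`.
#' The default of 512 px yields exactly 17 scales.
#'
#' @param max_scale largest scale, px (>= 2).
#' @return numeric vector of scales in px.
#' @export
bandpass_bank <- function(max_scale = 512) {
  if (max_scale < 2) stop("max_scale must be >= 2")
  k <- 0:floor(log(max_scale / 2, base = sqrt(2)) + 1e-9)
  # 2^(1 + k/2) keeps the power-of-two scales (2, 4, ..., 512) exact so band
  # membership of exact FFT frequencies is not lost to rounding
  2^(1 + k / 2)
}

#' Pattern-energy (granularity) spectrum of a region
#'
#' The region's luminance is cropped to the mask bounding box, masked-out
#' pixels are replaced by the region mean (avoiding spurious edge energy), and
#' the crop is passed through a bank of FFT annular bandpass filters. The
#' filter for scale s keeps spatial periods in the half-open octave
#' \[s, s*sqrt(2)) on the radial frequency plane. The "energy" at each scale
#' is the standard deviation of the filtered values over the masked pixels.
#' Scales larger than the crop have empty bands and energy 0, so spectra from
#' different regions always share the full scale list.
#'
#' @param lum luminance matrix.
#' @param mask logical region mask; bounding box must be at least 4 x 4 px.
#' @param scales scale bank (default [bandpass_bank()]).
#' @return object of class `pattern_spectrum`: data.frame with `scale_px` and
#'   `energy`.
#' @export
pattern_spectrum <- function(lum, mask, scales = bandpass_bank()) {
  mask <- mask != 0
  if (!any(mask)) stop("empty mask")
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  if (diff(rows) < 3 || diff(cols) < 3)
    stop("region bounding box smaller than 4 x 4 px")
  crop <- lum[rows[1]:rows[2], cols[1]:cols[2]]
  mcrop <- mask[rows[1]:rows[2], cols[1]:cols[2]]
  mu <- mean(crop[mcrop])
  crop[!mcrop] <- mu
  d <- dim(crop)
  ft <- fft(crop)
  # radial spatial frequency (cycles/px) of every FFT bin
  fy <- c(0:floor(d[1] / 2), -((ceiling(d[1] / 2) - 1):1)) / d[1]
  fx <- c(0:floor(d[2] / 2), -((ceiling(d[2] / 2) - 1):1)) / d[2]
  r <- sqrt(outer(fy^2, fx^2, `+`))
  # each bin belongs to exactly one half-open octave band [s, s*sqrt(2)):
  # band index floor(2 log2(p) - 2) of its period p partitions the plane
  # (bin-wise assignment avoids double counting at band edges)
  band_idx <- matrix(NA_real_, d[1], d[2])
  nz <- r > 0
  band_idx[nz] <- floor(2 * (-log2(r[nz])) - 2 + 1e-9)
  scale_idx <- round(2 * log2(scales) - 2)
  energy <- vapply(scale_idx, function(k) {
    keep <- !is.na(band_idx) & band_idx == k
    if (!any(keep)) return(0)
    filtered <- Re(fft(ft * keep, inverse = TRUE)) / length(ft)
    sd_pop(filtered[mcrop])
  }, numeric(1))
  structure(data.frame(scale_px = scales, energy = energy),
            class = c("pattern_spectrum", "data.frame"))
}

#' Pattern difference between two granularity spectra
#'
#' The L1 distance between target and background pattern-energy spectra:
#' the sum over spatial scales of absolute energy differences. Sensitive to
#' mismatches in marking size, spacing and contrast while disregarding phase,
#' so it tests background matching rather than template matching.
#'
#' @param spec_t,spec_b [pattern_spectrum()] results with identical scale
#'   lists.
#' @return scalar >= 0.
#' @export
pattern_diff <- function(spec_t, spec_b) {
  if (!isTRUE(all.equal(spec_t$scale_px, spec_b$scale_px)))
    stop("pattern spectra have different scale lists")
  sum(abs(spec_t$energy - spec_b$energy))
}
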