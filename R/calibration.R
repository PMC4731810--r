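#' Fit per-channel camera linearization curves
#'
#' Consumer and SLR camera sensors record pixel counts that are a non-linear
#' (roughly power-law) function of scene radiance. A set of calibrated diffuse
#' reflectance standards (e.g. eight Spectralon panels from 99% down to 2%
#' reflectance) photographed under the study illuminant lets us fit, per camera
#' channel, a monotone curve mapping raw counts back to a linear response.
#'
#' The fitted form is `reflectance = a * (count / full_scale)^g + b` with
#' `a > 0`, `g > 0`, estimated by least squares with the exponent profiled out
#' numerically. This family contains the identity (g = 1) and typical gamma
#' responses, and fits noise-free power-law simulations exactly.
#'
#' @param standards data.frame with columns `channel`, `reflectance` (fraction
#'   in (0, 1]) and `mean_count` (mean raw count over the standard, 0..65535).
#' @param full_scale raw count of a full-scale pixel (default 65535 for 16-bit).
#' @return object of class `linearization_model`: per-channel list of
#'   coefficients `a`, `b`, exponent `g` and training `r_squared`.
#' @examples
#' refl <- c(0.99, 0.8, 0.6, 0.4, 0.2, 0.1, 0.05, 0.02)
#' std <- data.frame(channel = "visR", reflectance = refl,
#'                   mean_count = 65535 * refl^(1 / 2.2))
#' fit <- fit_linearization(std)
#' fit$channels$visR$r_squared
#' @export
fit_linearization <- function(standards, full_scale = 65535) {
  required <- c("channel", "reflectance", "mean_count")
  if (!all(required %in% names(standards)))
    stop("standards needs columns channel, reflectance, mean_count")
  fits <- lapply(split(standards, standards$channel), function(d) {
    if (nrow(d) < 4L)
      stop("need at least 4 standards per channel (got ", nrow(d),
           " for ", d$channel[1], ")")
    if (anyDuplicated(d$reflectance) || any(d$reflectance <= 0 | d$reflectance > 1))
      stop("standard reflectances must be distinct and in (0, 1]")
    d <- d[order(d$reflectance), ]
    if (any(diff(d$mean_count) <= 0))
      stop("raw counts are not monotone in reflectance for channel ", d$channel[1])
    u <- d$mean_count / full_scale
    y <- d$reflectance
    rss_for <- function(log_g) {
      fit <- lm.fit(cbind(1, u^exp(log_g)), y)
      sum(fit$residuals^2)
    }
    opt <- optimize(rss_for, interval = log(c(0.05, 10)), tol = 1e-12)
    g <- exp(opt$minimum)
    fit <- lm.fit(cbind(1, u^g), y)
    a <- fit$coefficients[2]
    if (!is.finite(a) || a <= 0)
      stop("fitted response is non-increasing for channel ", d$channel[1])
    tss <- sum((y - mean(y))^2)
    list(a = unname(a), b = unname(fit$coefficients[1]), g = g,
         r_squared = 1 - sum(fit$residuals^2) / tss)
  })
  structure(list(channels = fits, full_scale = full_scale),
            class = "linearization_model")
}

#' @export
print.linearization_model <- function(x, ...) {
  cat("linearization_model (reflectance = a * u^g + b):\n")
  for (ch in names(x$channels)) {
    f <- x$channels[[ch]]
    cat(sprintf("  %-6s a = %.5g, b = %+.4g, g = %.4f, R^2 = %.6f\n",
                ch, f$a, f$b, f$g, f$r_squared))
  }
  invisible(x)
}

#' Apply a linearization model to raw counts
#'
#' @param model a [fit_linearization()] model.
#' @param counts numeric vector/matrix of raw counts.
#' @param channel channel name present in the model.
#' @return linear responses with the same shape as `counts`.
#' @export
linearize <- function(model, counts, channel) {
  f <- model$channels[[channel]]
  if (is.null(f)) stop("no linearization fitted for channel ", channel)
  f$a * (counts / model$full_scale)^f$g + f$b
}

#' Normalize linear channels to reflectance against a grey standard
#'
#' Each channel is scaled so that the mean linear response over the standard
#' region equals the standard's known reflectance (sequential grey-standard
#' calibration, e.g. a 40% Spectralon panel photographed beside the clutch).
#'
#' @param channels list of linear-response matrices (one per channel) or a 3-d
#'   array.
#' @param standard_region logical matrix marking the grey-standard pixels.
#' @param standard_reflectance known reflectance of the standard (e.g. 0.40).
#' @return same structure as `channels`, in reflectance units.
#' @export
normalize_to_reflectance <- function(channels, standard_region, standard_reflectance) {
  standard_region <- standard_region != 0
  if (!any(standard_region)) stop("standard region is empty")
  scale_one <- function(ch) {
    m <- mean(ch[standard_region])
    if (!is.finite(m) || m <= 0)
      stop("grey standard has non-positive mean linear response; calibration failed")
    ch * (standard_reflectance / m)
  }
  if (is.list(channels)) lapply(channels, scale_one)
  else if (length(dim(channels)) == 3L) {
    out <- channels
    for (k in seq_len(dim(channels)[3])) out[, , k] <- scale_one(channels[, , k])
    out
  } else scale_one(channels)
}

#' Rescale reflectance channels to eliminate pixel saturation
#'
#' Reflectance can legitimately exceed 100% of the grey standard (specular
#' highlights, brighter substrate). Rather than clipping, the whole stack is
#' divided by its global maximum M when M > 1, and the factor 1/M is recorded
#' so processing can restore the true values in floating point. For example an
#' image whose brightest pixel is 120% reflectance is stored scaled by 1/1.2.
#'
#' @param channels numeric array or list of matrices, finite and >= 0.
#' @return list with `stored` (16-bit integer counts, same structure as input),
#'   `saturation_scale` (1/M, or 1 when M <= 1) and `full_scale` (65535).
#' @seealso [reconstruct_reflectance()]
#' @export
rescale_saturation <- function(channels) {
  vals <- if (is.list(channels)) unlist(channels) else channels
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("channels must be finite and non-negative")
  m <- max(vals)
  scale <- if (m > 1) 1 / m else 1
  quantize <- function(ch) {
    storage <- round(ch * scale * 65535)
    storage.mode(storage) <- "integer"
    storage
  }
  stored <- if (is.list(channels)) lapply(channels, quantize) else quantize(channels)
  list(stored = stored, saturation_scale = scale, full_scale = 65535)
}

#' @rdname rescale_saturation
#' @param stored 16-bit stored counts from [rescale_saturation()].
#' @param saturation_scale the recorded scale factor.
#' @param full_scale stored full-scale value (65535).
#' @return `reconstruct_reflectance` returns floating-point reflectance,
#'   restoring values above 1 that the storage rescaling removed.
#' @export
reconstruct_reflectance <- function(stored, saturation_scale, full_scale = 65535) {
  restore <- function(ch) ch / full_scale / saturation_scale
  if (is.list(stored)) lapply(stored, restore) else restore(stored)
}

# scale a matrix about its centre keeping dimensions, bilinear resampling;
# exposed border (scale < 1) is filled with the image mean
scale_about_centre <- function(img, s, fill = mean(img)) {
  if (abs(s - 1) < 1e-12) return(img)
  d <- dim(img)
  nd <- pmax(round(d * s), 2L)
  res <- EBImage::resize(img, w = nd[1], h = nd[2])
  res <- matrix(as.numeric(res), nd[1], nd[2])
  out <- matrix(fill, d[1], d[2])
  # centre-align the resized image on the original canvas
  src0 <- pmax(floor((nd - d) / 2), 0)
  dst0 <- pmax(floor((d - nd) / 2), 0)
  n <- pmin(d, nd)
  out[dst0[1] + seq_len(n[1]), dst0[2] + seq_len(n[2])] <-
    res[src0[1] + seq_len(n[1]), src0[2] + seq_len(n[2])]
  out
}

# integer translate: content moves by (dy, dx); exposed border filled
shift_image <- function(img, dy, dx, fill = mean(img)) {
  d <- dim(img)
  out <- matrix(fill, d[1], d[2])
  src_r <- seq_len(d[1]) - dy
  src_c <- seq_len(d[2]) - dx
  ok_r <- src_r >= 1 & src_r <= d[1]
  ok_c <- src_c >= 1 & src_c <= d[2]
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

# pearson correlation between reference and moved image over the valid
# overlap for an integer shift (dy, dx) of `mov`
overlap_cor <- function(ref, mov, dy, dx) {
  d <- dim(ref)
  r1 <- max(1, 1 + dy); r2 <- min(d[1], d[1] + dy)
  c1 <- max(1, 1 + dx); c2 <- min(d[2], d[2] + dx)
  if (r2 - r1 < 8 || c2 - c1 < 8) return(-Inf)
  a <- ref[r1:r2, c1:c2]
  b <- mov[(r1:r2) - dy, (c1:c2) - dx]
  if (sd(a) == 0 || sd(b) == 0) return(-Inf)
  stats::cor(as.vector(a), as.vector(b))
}

#' Align the UV exposure to the visible exposure
#'
#' Refocusing for the UV-pass exposure changes focal length slightly and the
#' camera may move between the two shots, so the UV stack must be rescaled and
#' translated onto the visible stack. The transform is restricted to a uniform
#' scale plus integer translation, found by exhaustive search over a grid,
#' maximizing the normalized cross-correlation between the visible green
#' channel and the UV blue channel (the two most correlated channels).
#'
#' @param vis_stack list or array of the 3 visible channels (R, G, B).
#' @param uv_stack list or array of the 2 UV channels (R, B).
#' @param px_per_mm spatial scale of the visible stack.
#' @param max_shift maximum translation searched, px (each direction).
#' @param scales candidate uniform scale factors.
#' @param min_cor correlation floor below which alignment is declared failed
#'   (caller may then supply a manual transform via `transform`).
#' @param transform optional list(scale, dy, dx) to apply directly, skipping
#'   the search.
#' @return an [msimage] of the 3 visible + 2 resampled UV channels, with the
#'   chosen transform (scale, dy, dx, correlation) attached.
#' @export
align_uv_visible <- function(vis_stack, uv_stack, px_per_mm,
                             max_shift = 10,
                             scales = seq(0.95, 1.05, by = 0.01),
                             min_cor = 0.5, transform = NULL) {
  as_list <- function(x, n) {
    if (is.list(x)) x else lapply(seq_len(n), function(k) x[, , k])
  }
  vis <- as_list(vis_stack, 3)
  uv <- as_list(uv_stack, 2)
  if (length(vis) != 3L || length(uv) != 2L)
    stop("expected 3 visible and 2 UV channels")
  if (!identical(dim(vis[[1]]), dim(uv[[1]])))
    stop("visible and UV stacks must share dimensions")
  ref <- vis[[2]]   # visible green
  mov <- uv[[2]]    # UV blue
  if (is.null(transform)) {
    shifts <- -max_shift:max_shift
    best <- list(cor = -Inf)
    for (s in scales) {
      scaled <- scale_about_centre(mov, s)
      for (dy in shifts) for (dx in shifts) {
        cc <- overlap_cor(ref, scaled, dy, dx)
        if (cc > best$cor) best <- list(cor = cc, scale = s, dy = dy, dx = dx)
      }
    }
    if (!is.finite(best$cor) || best$cor < min_cor)
      stop(sprintf(
        "UV/visible alignment failed: peak correlation %.3f below floor %.3f",
        best$cor, min_cor))
    transform <- best
  } else {
    transform$cor <- NA_real_
  }
  uv_aligned <- lapply(uv, function(ch)
    shift_image(scale_about_centre(ch, transform$scale), transform$dy, transform$dx))
  msimage(c(vis, uv_aligned), px_per_mm = px_per_mm, transform = transform)
}

#' Resize an image to a target spatial scale
#'
#' Bilinear resampling to match the pixels/mm of another image (e.g. eggs
#' photographed under controlled conditions resized to the scale of the in
#' situ surrounds before pattern analysis).
#'
#' @param image matrix, 3-d array or [msimage].
#' @param from_px_per_mm,to_px_per_mm source and target scales (> 0).
#' @return resized image; for an [msimage] the `px_per_mm` attribute is updated.
#' @export
resize_to_scale <- function(image, from_px_per_mm, to_px_per_mm) {
  if (from_px_per_mm <= 0 || to_px_per_mm <= 0)
    stop("pixel scales must be > 0")
  r <- to_px_per_mm / from_px_per_mm
  if (abs(r - 1) < 1e-12) return(image)
  resize_mat <- function(m) {
    nd <- pmax(round(dim(m) * r), 1L)
    matrix(as.numeric(EBImage::resize(m, w = nd[1], h = nd[2])), nd[1], nd[2])
  }
  if (is.matrix(image)) return(resize_mat(image))
  is_ms <- inherits(image, "msimage")
  nk <- dim(image)[3]
  out <- lapply(seq_len(nk), function(k) resize_mat(image[, , k]))
  if (is_ms)
    msimage(out, px_per_mm = to_px_per_mm,
            saturation_scale = attr(image, "saturation_scale"),
            transform = attr(image, "transform"))
  else array(unlist(out), dim = c(dim(out[[1]]), nk))
}

#' Read calibration standards from CSV
#'
#' @param path CSV with columns `channel`, `reflectance`, `mean_count`.
#' @return data.frame suitable for [fit_linearization()].
#' @export
read_standards <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("channel", "reflectance", "mean_count")
  if (!all(required %in% names(d)))
    stop("standards CSV needs columns channel, reflectance, mean_count")
  d
}
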