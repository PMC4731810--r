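#' Multispectral image container
#'
#' An aligned five-channel reflectance stack: red, green and blue from the
#' visible-pass exposure plus red and blue from the UV-pass exposure (the UV
#' green channel carries almost no signal and is discarded). Values are
#' reflectance relative to a perfect diffuse reflector and may exceed 1; they
#' are not clipped.
#'
#' @param channels numeric array `h x w x 5`, or a list of five matrices of
#'   equal dimension, in order visR, visG, visB, uvR, uvB.
#' @param px_per_mm spatial scale of the image (> 0).
#' @param saturation_scale factor in (0, 1] recorded by [rescale_saturation()];
#'   1 means no rescaling was needed.
#' @param transform optional list describing the UV/visible alignment transform.
#' @return object of class `msimage`: the array with scale metadata attached.
#' @seealso [rescale_saturation()], [align_uv_visible()], [write_msimage()]
#' @export
msimage <- function(channels, px_per_mm, saturation_scale = 1, transform = NULL) {
  if (is.list(channels)) {
    dims <- unique(lapply(channels, dim))
    if (length(dims) != 1L) stop("all channels must share one shape")
    channels <- array(unlist(channels), dim = c(dims[[1]], length(channels)))
  }
  if (length(dim(channels)) != 3L || dim(channels)[3] != 5L)
    stop("an msimage needs exactly 5 channels (visR, visG, visB, uvR, uvB)")
  if (!is.numeric(px_per_mm) || px_per_mm <= 0) stop("px_per_mm must be > 0")
  if (saturation_scale <= 0 || saturation_scale > 1)
    stop("saturation_scale must lie in (0, 1]")
  dimnames(channels)[[3]] <- c("visR", "visG", "visB", "uvR", "uvB")
  structure(channels,
            px_per_mm = px_per_mm,
            saturation_scale = saturation_scale,
            transform = transform,
            class = c("msimage", "array"))
}

#' @export
print.msimage <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("msimage: %d x %d px, 5 channels, %.3g px/mm, saturation scale %.4g\n",
              d[1], d[2], attr(x, "px_per_mm"), attr(x, "saturation_scale")))
  rng <- range(x)
  cat(sprintf("  reflectance range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Target/background/exclusion masks for one scene
#'
#' Masks are logical matrices congruent with the image; nonzero/`TRUE` means
#' membership. Excluded pixels (obstructions such as grass blades and their
#' shadows) are removed from both the target and the background before any
#' metric is computed.
#'
#' @param target_mask,background_mask,exclusion_mask logical or 0/1 matrices of
#'   identical dimension; `exclusion_mask` may be `NULL`.
#' @return object of class `region_set` with logical `target` and `background`
#'   members (exclusions already subtracted) and the raw `exclusion` mask.
#' @export
region_set <- function(target_mask, background_mask, exclusion_mask = NULL) {
  target_mask <- target_mask != 0
  background_mask <- background_mask != 0
  if (!identical(dim(target_mask), dim(background_mask)))
    stop("target and background masks must be congruent")
  if (any(target_mask & background_mask))
    stop("target and background masks overlap")
  if (is.null(exclusion_mask)) {
    exclusion_mask <- array(FALSE, dim = dim(target_mask))
  } else {
    exclusion_mask <- exclusion_mask != 0
    if (!identical(dim(exclusion_mask), dim(target_mask)))
      stop("exclusion mask must be congruent with the others")
  }
  target <- target_mask & !exclusion_mask
  background <- background_mask & !exclusion_mask
  if (!any(target)) stop("target mask is empty after exclusions")
  if (!any(background)) stop("background mask is empty after exclusions")
  structure(list(target = target, background = background,
                 exclusion = exclusion_mask),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: %d target px, %d background px, %d excluded px\n",
              sum(x$target), sum(x$background), sum(x$exclusion)))
  invisible(x)
}

#' Write / read a multispectral stack as multipage TIFF plus JSON sidecar
#'
#' The five channels are written as a multipage 32-bit TIFF. Because
#' reflectance may exceed 1, pixel values are divided by a stored `file_scale`
#' (the global maximum, when above 1) before writing and multiplied back on
#' read; the sidecar records `px_per_mm`, `saturation_scale`, `file_scale` and
#' any alignment transform. Round trip is lossless to 32-bit quantization.
#'
#' @param x an [msimage].
#' @param path TIFF path; the sidecar is written at `<path>.json`.
#' @return `write_msimage` returns `path` invisibly; `read_msimage` returns an
#'   [msimage].
#' @export
write_msimage <- function(x, path) {
  stopifnot(inherits(x, "msimage"))
  file_scale <- max(1, max(x))
  pages <- lapply(seq_len(dim(x)[3]), function(k) pmax(x[, , k], 0) / file_scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- list(px_per_mm = attr(x, "px_per_mm"),
                  saturation_scale = attr(x, "saturation_scale"),
                  file_scale = file_scale,
                  transform = attr(x, "transform"))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_msimage
#' @export
read_msimage <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  channels <- lapply(pages, function(p) p * meta$file_scale)
  msimage(channels, px_per_mm = meta$px_per_mm,
          saturation_scale = meta$saturation_scale,
          transform = meta$transform)
}

#' Read a binary mask from an 8-bit PNG or TIFF file
#'
#' Nonzero pixels are members. Multi-channel mask images are collapsed by
#' taking the first channel.
#'
#' @param path PNG or TIFF file.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img != 0
}

#' @rdname read_mask
#' @param mask logical matrix to write (stored as 8-bit PNG, 0/255).
#' @export
write_mask <- function(mask, path) {
  png::writePNG(ifelse(mask != 0, 1, 0), path)
  invisible(path)
}
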