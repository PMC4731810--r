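#' Spectral sensitivity curves
#'
#' A sensitivity curve is a data.frame with columns `wavelength_nm` (ascending)
#' and `value` (>= 0, not all zero). `sensitivity_gaussian()` builds a smooth
#' synthetic curve; measured curves can be loaded with `read_sensitivity()`.
#'
#' @param centre peak wavelength, nm.
#' @param width Gaussian standard deviation, nm.
#' @param wl wavelength grid, nm (must cover the range of interest; default
#'   300-700 nm in 2 nm steps, spanning the avian-visible spectrum).
#' @return sensitivity curve data.frame.
#' @export
sensitivity_gaussian <- function(centre, width, wl = default_wl()) {
  data.frame(wavelength_nm = wl, value = exp(-0.5 * ((wl - centre) / width)^2))
}

#' @rdname sensitivity_gaussian
#' @export
default_wl <- function() seq(300, 700, by = 2)

#' @rdname sensitivity_gaussian
#' @param wl_or_path for `flat_illuminant`, a wavelength grid; for
#'   `read_sensitivity`, a CSV path with columns `wavelength_nm`, `value`.
#' @export
flat_illuminant <- function(wl_or_path = default_wl()) {
  data.frame(wavelength_nm = wl_or_path, value = rep(1, length(wl_or_path)))
}

#' @rdname sensitivity_gaussian
#' @export
read_sensitivity <- function(wl_or_path) {
  d <- read.csv(wl_or_path, stringsAsFactors = FALSE)
  if (!all(c("wavelength_nm", "value") %in% names(d)))
    stop("sensitivity CSV needs columns wavelength_nm, value")
  d
}

check_curve <- function(s, name = "curve") {
  if (is.unsorted(s$wavelength_nm)) stop(name, ": wavelengths must ascend")
  if (any(s$value < 0) || all(s$value == 0)) stop(name, ": invalid values")
  invisible(s)
}

#' Predator visual system description
#'
#' Bundles the chromatic receptor set (shortest to longest wavelength), the
#' relative cone abundances used to derive Weber fractions, the rule defining
#' the luminance (achromatic) channel, and the spectral sensitivity of every
#' receptor including any dedicated luminance receptor (the avian double cone).
#'
#' @param name system label, e.g. "ferret".
#' @param receptors character vector of chromatic receptor names, shortest to
#'   longest wavelength (>= 2).
#' @param cone_ratio relative abundances of the chromatic receptors (> 0), same
#'   order and length as `receptors`.
#' @param luminance_rule list with `receptors` (channel names) and `weights`;
#'   luminance = weighted sum of those cone-catch channels.
#' @param sensitivities named list of sensitivity curves, one per chromatic
#'   receptor plus any extra luminance receptor named in `luminance_rule`.
#' @param base_noise noise-to-signal ratio of the most abundant cone (0.05).
#' @return object of class `visual_system`, with the derived Weber fractions in
#'   `$weber`.
#' @seealso [weber_fractions()], [luminance_image()]
#' @export
visual_system <- function(name, receptors, cone_ratio, luminance_rule,
                          sensitivities, base_noise = 0.05) {
  if (length(receptors) < 2L) stop("a visual system needs >= 2 receptors")
  if (length(cone_ratio) != length(receptors) || any(cone_ratio <= 0))
    stop("cone_ratio must be positive, one entry per receptor")
  all_channels <- union(receptors, luminance_rule$receptors)
  if (!all(luminance_rule$receptors %in% names(sensitivities)) ||
      !all(receptors %in% names(sensitivities)))
    stop("luminance_rule or receptors reference channels without sensitivities")
  if (length(luminance_rule$weights) != length(luminance_rule$receptors))
    stop("luminance_rule weights/receptors length mismatch")
  for (ch in all_channels) check_curve(sensitivities[[ch]], ch)
  structure(list(name = name, receptors = receptors,
                 cone_ratio = setNames(cone_ratio, receptors),
                 luminance_rule = luminance_rule,
                 sensitivities = sensitivities[all_channels],
                 weber = weber_fractions(setNames(cone_ratio, receptors),
                                         base_noise = base_noise)),
            class = "visual_system")
}

#' @export
print.visual_system <- function(x, ...) {
  cat(sprintf("visual_system '%s': %d chromatic receptors (%s)\n", x$name,
              length(x$receptors), paste(x$receptors, collapse = ", ")))
  cat("  cone ratio:", paste(format(x$cone_ratio), collapse = " : "), "\n")
  cat("  Weber fractions:", paste(sprintf("%.4f", x$weber), collapse = ", "), "\n")
  cat("  luminance =", paste(sprintf("%g*%s", x$luminance_rule$weights,
                                     x$luminance_rule$receptors), collapse = " + "), "\n")
  invisible(x)
}

#' Built-in predator visual systems
#'
#' Synthetic Gaussian-sensitivity stand-ins for the three predator classes:
#' a dichromat mammal (ferret; S, L cones at ratio 1:14, luminance = L), a
#' trichromat primate (human; S, M, L at 1:5.49:10.99, luminance = (L+M)/2)
#' and a tetrachromat bird (peafowl; VS, S, M, L at 1:1.9:2.2:2.1, luminance =
#' double cone). Peak wavelengths approximate the published pigment maxima;
#' measured curves can be substituted via [visual_system()].
#'
#' @param wl wavelength grid.
#' @return a `visual_system`.
#' @export
vs_ferret <- function(wl = default_wl()) {
  visual_system("ferret", c("sws", "lws"), c(1, 14),
                list(receptors = "lws", weights = 1),
                list(sws = sensitivity_gaussian(430, 40, wl),
                     lws = sensitivity_gaussian(558, 55, wl)))
}

#' @rdname vs_ferret
#' @export
vs_human <- function(wl = default_wl()) {
  visual_system("human", c("sws", "mws", "lws"), c(1, 5.49, 10.99),
                list(receptors = c("mws", "lws"), weights = c(0.5, 0.5)),
                list(sws = sensitivity_gaussian(420, 35, wl),
                     mws = sensitivity_gaussian(534, 45, wl),
                     lws = sensitivity_gaussian(564, 50, wl)))
}

#' @rdname vs_ferret
#' @export
vs_peafowl <- function(wl = default_wl()) {
  visual_system("peafowl", c("vs", "sws", "mws", "lws"), c(1, 1.9, 2.2, 2.1),
                list(receptors = "dbl", weights = 1),
                list(vs  = sensitivity_gaussian(432, 36, wl),
                     sws = sensitivity_gaussian(477, 38, wl),
                     mws = sensitivity_gaussian(537, 40, wl),
                     lws = sensitivity_gaussian(605, 45, wl),
                     dbl = sensitivity_gaussian(567, 65, wl)))
}

#' Quantum catch of a receptor viewing a reflectance spectrum
#'
#' The integrated stimulation of a photoreceptor by light reflected from a
#' surface: the trapezoidal-rule integral of reflectance x sensitivity x
#' illuminant over wavelength, normalized by the integral of sensitivity x
#' illuminant so that a perfect diffuse reflector scores exactly 1.
#'
#' @param reflectance numeric vector of reflectances on the same wavelength
#'   grid as `sensitivity`, or a matrix (spectra in rows).
#' @param sensitivity,illuminant sensitivity curves (data.frames with
#'   `wavelength_nm`, `value`) on a shared grid.
#' @return catch value(s) in [0, 1] for reflectances in [0, 1].
#' @export
quantum_catch <- function(reflectance, sensitivity, illuminant = flat_illuminant(sensitivity$wavelength_nm)) {
  wl <- sensitivity$wavelength_nm
  if (!isTRUE(all.equal(wl, illuminant$wavelength_nm)))
    stop("sensitivity and illuminant wavelength grids differ")
  w <- sensitivity$value * illuminant$value
  denom <- pracma::trapz(wl, w)
  if (is.matrix(reflectance)) {
    if (ncol(reflectance) != length(wl))
      stop("reflectance grid length does not match sensitivity grid")
    apply(reflectance, 1, function(r) pracma::trapz(wl, r * w)) / denom
  } else {
    if (length(reflectance) != length(wl))
      stop("reflectance grid length does not match sensitivity grid")
    pracma::trapz(wl, reflectance * w) / denom
  }
}

# degree-2 polynomial basis over the 5 camera catches:
# intercept, linear, squares, pairwise interactions
poly_basis <- function(x, degree = 2) {
  x <- as.matrix(x)
  n <- ncol(x)
  cols <- list(intercept = rep(1, nrow(x)))
  for (i in seq_len(n)) cols[[paste0("x", i)]] <- x[, i]
  if (degree >= 2) {
    for (i in seq_len(n)) cols[[paste0("x", i, "^2")]] <- x[, i]^2
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      cols[[paste0("x", i, ":x", j)]] <- x[, i] * x[, j]
  }
  do.call(cbind, cols)
}

#' Fit polynomial camera-to-cone-catch mapping
#'
#' Cameras and animal eyes sample the spectrum differently, so cone catches
#' cannot be obtained from camera channels by a linear transform alone. Over a
#' library of natural reflectance spectra, however, a low-order polynomial in
#' the five camera-channel catches predicts each receptor's quantum catch very
#' accurately. This fits, per receptor, a least-squares polynomial (default
#' degree 2 with pairwise interactions and intercept) from camera catches to
#' receptor catches and reports the training R-squared.
#'
#' @param library spectral library: matrix of reflectance spectra (rows) on a
#'   shared wavelength grid given by `attr(library, "wavelength_nm")`, or by
#'   the sensitivity grids.
#' @param camera_sensitivities named list of 5 sensitivity curves (visR, visG,
#'   visB, uvR, uvB).
#' @param receptor_sensitivities named list of receptor sensitivity curves.
#' @param illuminant illuminant curve (default flat/equal energy).
#' @param degree polynomial degree (1 or 2).
#' @return object of class `cone_mapping`: coefficient matrix (basis terms x
#'   receptors), per-receptor training `r_squared`, channel names.
#' @export
fit_cone_catch_mapping <- function(library, camera_sensitivities,
                                   receptor_sensitivities,
                                   illuminant = NULL, degree = 2) {
  if (length(camera_sensitivities) != 5L)
    stop("expected 5 camera channel sensitivities")
  wl <- camera_sensitivities[[1]]$wavelength_nm
  if (is.null(illuminant)) illuminant <- flat_illuminant(wl)
  lib <- as.matrix(library)
  cam <- sapply(camera_sensitivities, function(s) quantum_catch(lib, s, illuminant))
  rec <- sapply(receptor_sensitivities, function(s) quantum_catch(lib, s, illuminant))
  X <- poly_basis(cam, degree)
  if (nrow(X) <= ncol(X))
    stop("spectral library smaller than the polynomial basis (need > ",
         ncol(X), " spectra)")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient polynomial design; degenerate terms: ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qx, rec)
  fitted <- X %*% coefs
  r2 <- sapply(seq_len(ncol(rec)), function(j) {
    1 - sum((rec[, j] - fitted[, j])^2) / sum((rec[, j] - mean(rec[, j]))^2)
  })
  structure(list(coefficients = coefs, degree = degree,
                 camera_channels = names(camera_sensitivities),
                 receptors = colnames(rec),
                 r_squared = setNames(r2, colnames(rec))),
            class = "cone_mapping")
}

#' @export
print.cone_mapping <- function(x, ...) {
  cat(sprintf("cone_mapping: degree-%d polynomial, %d camera channels -> %d receptors\n",
              x$degree, length(x$camera_channels), length(x$receptors)))
  cat("  training R^2:", paste(sprintf("%s=%.5f", x$receptors, x$r_squared),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Predict receptor catches from camera catches
#'
#' @param object a [fit_cone_catch_mapping()] model.
#' @param newdata matrix of camera catches (columns in mapping channel order).
#' @param ... unused.
#' @return matrix of predicted receptor catches (unclamped).
#' @export
predict.cone_mapping <- function(object, newdata, ...) {
  poly_basis(as.matrix(newdata), object$degree) %*% object$coefficients
}

#' Map a multispectral image into predator cone-catch channels
#'
#' Evaluates the fitted polynomial mapping per pixel. Calibrated reflectance
#' channels are treated as the camera's quantum catches (a camera channel
#' normalized to the grey standard is the camera-sensitivity-weighted catch of
#' the pixel's spectrum). Small negative predictions arising from polynomial
#' extrapolation are clamped to `floor`, keeping downstream log-ratio colour
#' distances defined.
#'
#' @param image an [msimage] (or `h x w x 5` array).
#' @param mapping a [fit_cone_catch_mapping()] model.
#' @param system optional [visual_system()] whose name is attached.
#' @param floor clamp for non-positive predicted catches (default 1e-6).
#' @return object of class `cone_image`: array `h x w x n_receptors` with
#'   attributes `system`, `px_per_mm`, `floor`.
#' @export
apply_mapping <- function(image, mapping, system = NULL, floor = 1e-6) {
  if (length(dim(image)) != 3L || dim(image)[3] != 5L)
    stop("image must have 5 channels")
  if (floor < 0) stop("floor must be >= 0")
  d <- dim(image)
  px <- matrix(image, d[1] * d[2], 5)
  pred <- predict(mapping, px)
  pred[pred < floor] <- floor
  out <- array(pred, dim = c(d[1], d[2], ncol(pred)))
  dimnames(out)[[3]] <- mapping$receptors
  structure(out,
            system = if (is.null(system)) NA_character_ else system$name,
            px_per_mm = attr(image, "px_per_mm"),
            floor = floor,
            class = c("cone_image", "array"))
}

#' @export
print.cone_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("cone_image (%s): %d x %d px, receptors %s\n",
              attr(x, "system"), d[1], d[2],
              paste(dimnames(x)[[3]], collapse = ", ")))
  invisible(x)
}

#' Bundle a visual system with its fitted camera mapping
#'
#' @param system a [visual_system()].
#' @param mapping a [fit_cone_catch_mapping()] fitted for all of the system's
#'   receptor channels (chromatic plus any luminance receptor).
#' @return object of class `predator_model`.
#' @export
predator_model <- function(system, mapping) {
  needed <- union(system$receptors, system$luminance_rule$receptors)
  if (!all(needed %in% mapping$receptors))
    stop("mapping lacks receptor channels: ",
         paste(setdiff(needed, mapping$receptors), collapse = ", "))
  structure(list(system = system, mapping = mapping), class = "predator_model")
}

#' @rdname predator_model
#' @param library,camera_sensitivities,illuminant,degree passed to
#'   [fit_cone_catch_mapping()] using the system's own receptor sensitivities.
#' @export
fit_predator_model <- function(system, library, camera_sensitivities,
                               illuminant = NULL, degree = 2) {
  mapping <- fit_cone_catch_mapping(library, camera_sensitivities,
                                    system$sensitivities, illuminant, degree)
  predator_model(system, mapping)
}

#' Synthetic full-spectrum camera channel sensitivities
#'
#' Gaussian stand-ins for a UV-converted SLR: visible R/G/B channels through a
#' UV/IR blocking filter (420-680 nm) and the red and blue channels through a
#' UV pass filter (320-380 nm).
#'
#' @param wl wavelength grid.
#' @return named list of 5 sensitivity curves (visR, visG, visB, uvR, uvB).
#' @export
camera_gaussian <- function(wl = default_wl()) {
  list(visR = sensitivity_gaussian(600, 55, wl),
       visG = sensitivity_gaussian(535, 50, wl),
       visB = sensitivity_gaussian(455, 55, wl),
       uvR  = sensitivity_gaussian(372, 30, wl),
       uvB  = sensitivity_gaussian(342, 28, wl))
}

#' Persist / load a cone-catch mapping as JSON
#'
#' @param mapping a `cone_mapping`.
#' @param path JSON file path.
#' @export
write_mapping <- function(mapping, path) {
  obj <- list(degree = mapping$degree,
              camera_channels = mapping$camera_channels,
              receptors = mapping$receptors,
              terms = rownames(mapping$coefficients),
              coefficients = unclass(as.data.frame(mapping$coefficients)),
              r_squared = as.list(mapping$r_squared))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- as.matrix(as.data.frame(obj$coefficients))
  colnames(coefs) <- obj$receptors
  structure(list(coefficients = coefs, degree = obj$degree,
                 camera_channels = obj$camera_channels,
                 receptors = obj$receptors,
                 r_squared = setNames(unlist(obj$r_squared), obj$receptors)),
            class = "cone_mapping")
}
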