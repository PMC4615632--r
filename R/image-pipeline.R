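# Images are plain base arrays: dim c(H, W, 3), channel responses or linear
# reflectances in [0, 1] (calibrated values may reach 1.5 for speculars).
# Masks are logical H x W matrices; row-major, origin top-left.

.checkImage <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an H x W x 3 array")
  if (anyNA(image)) stop("image contains NA")
  invisible(dim(image))
}

.checkMask <- function(mask, image) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix")
  d <- dim(image)
  if (!all(dim(mask) == d[1:2]))
    stop("mask dimensions must match the image exactly")
  if (!any(mask)) stop("mask has no TRUE pixels")
  invisible(sum(mask))
}

#' Read an RGB image or region mask from file
#'
#' PNG and TIFF rasters (8/16 bit) are read with the png and tiff packages
#' and returned as an H x W x 3 array scaled to `[0, 1]`; greyscale images
#' are replicated across channels, alpha is dropped. Masks are single-channel
#' images whose nonzero pixels are inside the region.
#'
#' @param path image file (`.png`, `.tif`, `.tiff`).
#' @return `readImageRaster`: numeric H x W x 3 array; `readMaskImage`:
#'   logical H x W matrix.
#' @export
readImageRaster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname readImageRaster
#' @export
readMaskImage <- function(path) {
  img <- readImageRaster(path)
  img[, , 1] > 0
}

#' Fit the camera linearization model from a grey-scale ramp
#'
#' Recovers, per channel, the monotone response curve linking camera
#' response to scene reflectance from (at least three) grey-scale squares of
#' known reflectance, as a power law `reflectance = a * response^gamma`
#' fitted by least squares in log-log space. The channel mean ("luminance")
#' is calibrated alongside R, G and B. Non-monotone response/reflectance
#' pairs trigger a warning and an isotonic-regression fallback before
#' fitting.
#'
#' @param responses numeric matrix (squares x 3 channels) or data.frame with
#'   columns `R`, `G`, `B` of mean camera responses in `[0, 1]`, one row per
#'   grey square.
#' @param knownReflectances reflectance fractions of the squares, same
#'   length as rows.
#' @return An object of class `calibrationModel`: list with `gain`, `gamma`
#'   (length-3, per channel), `luminance` (gain/gamma of the channel mean)
#'   and per-channel `residuals` (log-space).
#' @examples
#' refl <- c(0.03, 0.09, 0.19, 0.36, 0.59, 0.90)
#' resp <- cbind(R = refl, G = refl, B = refl)^(1 / 2.2)
#' fitLinearization(resp, refl)$gamma  # ~2.2 each
#' @export
fitLinearization <- function(responses, knownReflectances) {
  responses <- as.matrix(responses)
  if (ncol(responses) != 3L) stop("responses must have 3 channels")
  refl <- as.numeric(knownReflectances)
  if (nrow(responses) != length(refl))
    stop("one reflectance per row of responses is required")
  keep <- !duplicated(cbind(responses, refl))
  responses <- responses[keep, , drop = FALSE]
  refl <- refl[keep]
  if (nrow(responses) < 3L)
    stop("at least 3 distinct (response, reflectance) pairs are required")
  if (any(refl <= 0)) stop("known reflectances must be positive")
  fit1 <- function(resp, label) {
    ord <- order(refl)
    r <- resp[ord]
    if (any(diff(r) <= 0)) {
      warning(sprintf("channel %s responses not monotone in reflectance; using isotonic fit", label))
      r <- stats::isoreg(refl[ord], r)$yf
      r <- pmax(r, 1e-6)
      r <- r + seq_along(r) * 1e-9  # break exact ties for the log-log fit
    }
    fit <- stats::lm(log(refl[ord]) ~ log(r))
    list(gain = exp(unname(stats::coef(fit)[1])),
         gamma = unname(stats::coef(fit)[2]),
         residuals = unname(stats::residuals(fit)))
  }
  ch <- lapply(1:3, function(c) fit1(responses[, c], c("R", "G", "B")[c]))
  lum <- fit1(rowMeans(responses), "luminance")
  structure(list(
    gain = vapply(ch, `[[`, numeric(1), "gain"),
    gamma = vapply(ch, `[[`, numeric(1), "gamma"),
    luminance = list(gain = lum$gain, gamma = lum$gamma),
    residuals = lapply(ch, `[[`, "residuals")),
    class = "calibrationModel")
}

#' @export
print.calibrationModel <- function(x, ...) {
  cat("Camera linearization (reflectance = gain * response^gamma):\n")
  for (c in 1:3)
    cat(sprintf("  %s: gain %.4f  gamma %.4f  rms log residual %.2e\n",
                c("R", "G", "B")[c], x$gain[c], x$gamma[c],
                sqrt(mean(x$residuals[[c]]^2))))
  invisible(x)
}

#' Linearize an image through a fitted calibration model
#'
#' Maps each pixel channel through its power-law response curve so pixel
#' values are on a linear scene-reflectance scale, clipped to `[0, 1.5]`
#' (values above 1 are allowed for specular highlights).
#'
#' @param image H x W x 3 response array in `[0, 1]`.
#' @param model a `calibrationModel` from [fitLinearization()].
#' @return Calibrated H x W x 3 array.
#' @export
applyCalibration <- function(image, model) {
  .checkImage(image)
  if (!inherits(model, "calibrationModel"))
    stop("model must come from fitLinearization()")
  out <- image
  for (c in 1:3)
    out[, , c] <- model$gain[c] * image[, , c]^model$gamma[c]
  out[!is.finite(out)] <- 0  # 0^negative-gamma guards
  pmin(pmax(out, 0), 1.5)
}

#' Equalize channels to the in-frame grey photographic standard
#'
#' Multiplies each channel by `targetReflectance / mean(channel over the
#' standard mask)` so the grey standard region reads exactly its known
#' reflectance in every channel, removing residual lighting variation
#' between photographs.
#'
#' @param image calibrated H x W x 3 array.
#' @param standardMask logical H x W mask of the grey standard patch.
#' @param targetReflectance known reflectance of the standard (default
#'   0.30).
#' @return Equalized image array, with the per-channel scale factors in
#'   attribute `"scaleFactors"`.
#' @export
equalizeToStandard <- function(image, standardMask, targetReflectance = 0.30) {
  .checkImage(image)
  .checkMask(standardMask, image)
  if (targetReflectance <= 0) stop("targetReflectance must be positive")
  m <- vapply(1:3, function(c) mean(image[, , c][standardMask]), numeric(1))
  if (any(m <= 0))
    stop("degenerate input: grey standard region has a zero-mean channel")
  f <- targetReflectance / m
  out <- image
  for (c in 1:3) out[, , c] <- image[, , c] * f[c]
  attr(out, "scaleFactors") <- stats::setNames(f, c("R", "G", "B"))
  out
}

#' Segment a throat region into red, yellow and grey layers
#'
#' Classifies each throat-mask pixel of a calibrated, grey-equalized image
#' from its luminance-standardized chromatic coordinates
#' `(r, g, b) = (R, G, B) / (R + G + B)`: a pixel is red when the redness
#' score `r - g` reaches the red threshold, otherwise yellow when the
#' yellowness score `min(r, g) - b` reaches the yellow threshold, otherwise
#' grey. Red is tested first; the conservative red threshold keeps orange
#' and yellow colouration clearly distinguished. Pixels with zero channel
#' sum carry no chromatic signal and are counted as grey.
#'
#' @param image calibrated + equalized H x W x 3 array.
#' @param throatMask logical H x W mask of the throat region.
#' @param thresholds named numeric: `red` and `yellow` score thresholds in
#'   (0, 1); defaults `c(red = 0.20, yellow = 0.15)`.
#' @return A [SegmentationResult-class].
#' @export
segmentThroat <- function(image, throatMask,
                          thresholds = c(red = 0.20, yellow = 0.15)) {
  .checkImage(image)
  n <- .checkMask(throatMask, image)
  if (!all(c("red", "yellow") %in% names(thresholds)))
    stop("thresholds must be named 'red' and 'yellow'")
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie in (0, 1)")
  R <- image[, , 1][throatMask]
  G <- image[, , 2][throatMask]
  B <- image[, , 3][throatMask]
  s <- R + G + B
  zero <- s == 0
  s[zero] <- 1
  r <- R / s; g <- G / s; b <- B / s
  redness <- r - g
  yellowness <- pmin(r, g) - b
  isRed <- !zero & redness >= thresholds[["red"]]
  isYellow <- !zero & !isRed & yellowness >= thresholds[["yellow"]]
  nRed <- sum(isRed); nYellow <- sum(isYellow)
  new("SegmentationResult",
      propRed = nRed / n, propYellow = nYellow / n,
      propGrey = (n - nRed - nYellow) / n,
      nPixels = as.integer(n),
      thresholds = c(red = thresholds[["red"]],
                     yellow = thresholds[["yellow"]]))
}

#' @rdname segmentThroat
#' @param x a `SegmentationResult`.
#' @return `layerProportions`: named numeric `(red, yellow, grey)`.
#' @export
layerProportions <- function(x) {
  stopifnot(is(x, "SegmentationResult"))
  c(red = x@propRed, yellow = x@propYellow, grey = x@propGrey)
}

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf(
    "SegmentationResult: %d px | red %.3f  yellow %.3f  grey %.3f (thresholds red %.2f, yellow %.2f)\n",
    object@nPixels, object@propRed, object@propYellow, object@propGrey,
    object@thresholds[["red"]], object@thresholds[["yellow"]]))
})
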