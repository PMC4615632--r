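#' Construct a Spectrum
#'
#' @param wavelength numeric vector of strictly increasing wavelengths (nm).
#' @param value numeric vector of nonnegative values (same length).
#' @param kind one of `"reflectance"`, `"irradiance"`, `"sensitivity"`.
#' @return A [Spectrum-class] object.
#' @examples
#' s <- Spectrum(300:700, rep(0.3, 401), "reflectance")
#' s
#' @export
Spectrum <- function(wavelength, value, kind = c("reflectance", "irradiance",
                                                 "sensitivity")) {
  kind <- match.arg(kind)
  new("Spectrum", wavelength = as.numeric(wavelength),
      value = as.numeric(value), kind = kind)
}

#' @rdname Spectrum
#' @param x a `Spectrum`.
#' @export
wavelengths <- function(x) {
  stopifnot(is(x, "Spectrum"))
  x@wavelength
}

#' @rdname Spectrum
#' @export
specValues <- function(x) {
  stopifnot(is(x, "Spectrum"))
  x@value
}

#' @rdname Spectrum
#' @export
specKind <- function(x) {
  stopifnot(is(x, "Spectrum"))
  x@kind
}

setMethod("show", "Spectrum", function(object) {
  w <- object@wavelength
  cat(sprintf("Spectrum (%s): %d samples, %g-%g nm, values [%.4g, %.4g]\n",
              object@kind, length(w), min(w), max(w),
              min(object@value), max(object@value)))
})

setMethod("length", "Spectrum", function(x) length(x@wavelength))

#' Default 1-nm analysis grid, 300-700 nm
#'
#' @return Integer wavelengths 300..700.
#' @export
analysisGrid <- function() 300:700

#' Flat (spectrally neutral) reflectance spectrum
#'
#' @param level reflectance fraction (0.30 = the grey photographic standard).
#' @param grid wavelength grid in nm.
#' @return A reflectance [Spectrum-class].
#' @export
flatSpectrum <- function(level = 0.30, grid = analysisGrid()) {
  stopifnot(is.numeric(level), length(level) == 1L, level >= 0)
  Spectrum(grid, rep(level, length(grid)), "reflectance")
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation within the measured range; extrapolation is refused.
#' Interpolated values are clipped at zero and the `kind` is preserved.
#'
#' @param spectrum a [Spectrum-class].
#' @param grid target wavelengths (nm), strictly increasing, inside the
#'   measured range.
#' @return A [Spectrum-class] on `grid`.
#' @examples
#' s <- Spectrum(c(400, 402), c(0.2, 0.4), "reflectance")
#' specValues(resampleSpectrum(s, 401))  # 0.3
#' @export
resampleSpectrum <- function(spectrum, grid) {
  stopifnot(is(spectrum, "Spectrum"))
  grid <- as.numeric(grid)
  if (length(grid) == 0L) stop("empty target grid")
  if (any(diff(grid) <= 0)) stop("target grid must be strictly increasing")
  w <- spectrum@wavelength
  if (min(grid) < min(w) || max(grid) > max(w))
    stop(sprintf("grid [%g, %g] outside measured range [%g, %g]: no extrapolation",
                 min(grid), max(grid), min(w), max(w)))
  v <- stats::approx(w, spectrum@value, xout = grid, method = "linear")$y
  Spectrum(grid, pmax(v, 0), spectrum@kind)
}

.sameGrid <- function(a, b) {
  length(a@wavelength) == length(b@wavelength) &&
    all(abs(a@wavelength - b@wavelength) < 1e-9)
}

.gridStep <- function(w) {
  d <- diff(w)
  if (max(d) - min(d) > 1e-6 * mean(d))
    stop("analysis grid must be (near-)uniform for rectangle-rule integration")
  mean(d)
}
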