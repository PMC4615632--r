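#' @import methods
NULL

.SPECTRUM_KINDS <- c("reflectance", "irradiance", "sensitivity")

#' Wavelength-indexed spectral curve
#'
#' A `Spectrum` holds a single spectral curve sampled at strictly increasing
#' wavelengths: a reflectance (fraction of the white standard), an irradiance
#' (arbitrary quantal units) or a receptor sensitivity (0-1). The analysis
#' grid used throughout the package is 1 nm over 300-700 nm, the visual
#' spectrum of most diurnal lizards.
#'
#' @slot wavelength numeric, strictly increasing wavelengths in nm.
#' @slot value numeric, nonnegative values, one per wavelength.
#' @slot kind character, one of `"reflectance"`, `"irradiance"`,
#'   `"sensitivity"`.
#' @seealso [Spectrum()], [resampleSpectrum()], [quantumCatches()]
#' @exportClass Spectrum
setClass("Spectrum",
  representation(wavelength = "numeric", value = "numeric", kind = "character"))

setValidity("Spectrum", function(object) {
  w <- object@wavelength
  v <- object@value
  if (length(w) == 0L) return("spectrum has no samples")
  if (length(w) != length(v)) return("wavelength and value lengths differ")
  if (anyNA(w) || anyNA(v)) return("NA in wavelength or value")
  if (any(diff(w) <= 0)) return("wavelengths must be strictly increasing")
  if (any(v < 0)) return("spectral values must be nonnegative")
  if (length(object@kind) != 1L || !object@kind %in% .SPECTRUM_KINDS)
    return(sprintf("kind must be one of %s",
                   paste(.SPECTRUM_KINDS, collapse = ", ")))
  TRUE
})

#' Receptor set of a visual system
#'
#' Ordered receptor classes of a (di- to tetra-chromatic) visual system:
#' labels, peak-sensitivity wavelengths, relative photoreceptor abundances
#' (eta) and Weber-fraction channel noise (omega). One receptor is flagged as
#' the achromatic (luminance) channel.
#'
#' @slot receptors data.frame with columns `name`, `lambdaMax`, `abundance`,
#'   `noise`, one row per receptor class in short- to long-wavelength order.
#' @slot achromatic character, name of the receptor driving luminance
#'   contrast.
#' @slot referenceReceptor character, receptor whose noise anchored the
#'   others.
#' @seealso [visualSystem()], [tawnyDragonVisualSystem()],
#'   [deriveReceptorNoise()]
#' @exportClass VisualSystem
setClass("VisualSystem",
  representation(receptors = "data.frame", achromatic = "character",
                 referenceReceptor = "character"))

setValidity("VisualSystem", function(object) {
  r <- object@receptors
  need <- c("name", "lambdaMax", "abundance", "noise")
  if (!all(need %in% names(r))) return("receptors must have columns name, lambdaMax, abundance, noise")
  if (nrow(r) < 2L) return("a visual system needs at least 2 receptor classes")
  if (anyDuplicated(r$name)) return("receptor names must be unique")
  if (any(r$abundance <= 0)) return("receptor abundances must be positive")
  if (any(r$noise <= 0)) return("receptor noise (omega) must be positive")
  if (any(r$lambdaMax < 300 | r$lambdaMax > 700))
    return("lambdaMax must lie in [300, 700] nm")
  if (!object@achromatic %in% r$name)
    return("achromatic receptor is not a member of the system")
  if (!object@referenceReceptor %in% r$name)
    return("reference receptor is not a member of the system")
  TRUE
})

#' Per-receptor quantum catches
#'
#' Photon catches q_i of each receptor class for one stimulus under one
#' illuminant, in arbitrary (illuminant-scale) units. Catches are strictly
#' positive; log catch ratios between two stimuli feed the receptor-noise
#' contrast model.
#'
#' @slot catch named numeric, one strictly positive catch per receptor.
#' @slot systemId character, fingerprint of the `VisualSystem` used.
#' @seealso [quantumCatches()], [chromaticContrast()]
#' @exportClass QuantumCatchSet
setClass("QuantumCatchSet",
  representation(catch = "numeric", systemId = "character"))

setValidity("QuantumCatchSet", function(object) {
  if (is.null(names(object@catch)) || anyDuplicated(names(object@catch)))
    return("catches must be uniquely named by receptor")
  if (any(!is.finite(object@catch)) || any(object@catch <= 0))
    return("all quantum catches must be finite and strictly positive")
  TRUE
})

#' Receptor-noise contrast of two stimuli
#'
#' Chromatic and achromatic perceptual distance between two stimuli in units
#' of just noticeable differences (JND), with the per-receptor log catch
#' ratios they derive from. 1 JND is the discrimination threshold.
#'
#' @slot logRatios named numeric, per-receptor delta-f = ln(qA/qB).
#' @slot chromaticJND numeric, colour distance (>= 0).
#' @slot achromaticJND numeric, luminance distance (>= 0).
#' @seealso [contrastVsBackground()]
#' @exportClass ContrastResult
setClass("ContrastResult",
  representation(logRatios = "numeric", chromaticJND = "numeric",
                 achromaticJND = "numeric"))

setValidity("ContrastResult", function(object) {
  if (length(object@chromaticJND) != 1L || object@chromaticJND < 0)
    return("chromaticJND must be a single nonnegative number")
  if (length(object@achromaticJND) != 1L || object@achromaticJND < 0)
    return("achromaticJND must be a single nonnegative number")
  TRUE
})

#' Colour-layer proportions of a segmented throat
#'
#' Fractions of throat-mask pixels assigned to the red, yellow and grey
#' layers by threshold segmentation; grey is the remainder class so the
#' three proportions sum to 1.
#'
#' @slot propRed,propYellow,propGrey numeric fractions in `[0, 1]`.
#' @slot nPixels integer, number of mask pixels classified.
#' @slot thresholds named numeric, the `red` and `yellow` score thresholds
#'   used.
#' @seealso [segmentThroat()]
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(propRed = "numeric", propYellow = "numeric",
                 propGrey = "numeric", nPixels = "integer",
                 thresholds = "numeric"))

setValidity("SegmentationResult", function(object) {
  p <- c(object@propRed, object@propYellow, object@propGrey)
  if (any(p < 0 | p > 1)) return("proportions must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9) return("proportions must sum to 1")
  if (object@nPixels < 1L) return("nPixels must be >= 1")
  if (!all(c("red", "yellow") %in% names(object@thresholds)))
    return("thresholds must be named 'red' and 'yellow'")
  TRUE
})
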