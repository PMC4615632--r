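#' Vitamin-A1 visual pigment absorbance template
#'
#' Evaluates the standard A1 rhodopsin/porphyropsin absorbance template
#' (Govardovskii-type alpha band plus beta band) for a pigment with peak
#' absorbance `lambdaMax`, normalized so the maximum on the grid is 1. This
#' is the conventional way to reconstruct receptor spectral sensitivities in
#' lizard visual modelling when only lambda-max values are reported.
#'
#' @param lambdaMax peak wavelength in nm, within `[300, 700]`.
#' @param grid wavelength grid in nm.
#' @return A sensitivity [Spectrum-class] with maximum 1.
#' @examples
#' s <- pigmentTemplate(571)
#' specValues(s)[wavelengths(s) == 571]  # 1
#' @export
pigmentTemplate <- function(lambdaMax, grid = analysisGrid()) {
  if (length(lambdaMax) != 1L || !is.finite(lambdaMax) ||
      lambdaMax < 300 || lambdaMax > 700)
    stop("lambdaMax must be a single wavelength in [300, 700] nm")
  grid <- as.numeric(grid)
  x <- lambdaMax / grid
  a <- 0.8795 + 0.0459 * exp(-(lambdaMax - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lambdaMax   # beta-band peak
  b <- -40.5 + 0.195 * lambdaMax   # beta-band width
  beta <- 0.26 * exp(-((grid - lmb) / b)^2)
  s <- alpha + beta
  Spectrum(grid, s / max(s), "sensitivity")
}

#' Quantum catches of a stimulus
#'
#' Photon catch of each receptor class: the rectangle-rule integral
#' `q_i = sum_lambda R(lambda) I(lambda) S_i(lambda) dlambda` of reflectance
#' times illuminant times receptor sensitivity over the shared grid.
#' Receptor sensitivities are built from the system's lambda-max values with
#' [pigmentTemplate()].
#'
#' @param reflectance reflectance [Spectrum-class] on the analysis grid.
#' @param illuminant irradiance [Spectrum-class] on the same grid (default
#'   [d65Illuminant()]).
#' @param system a [VisualSystem-class] (default
#'   [tawnyDragonVisualSystem()]).
#' @return A [QuantumCatchSet-class].
#' @export
quantumCatches <- function(reflectance, illuminant = NULL,
                           system = tawnyDragonVisualSystem()) {
  stopifnot(is(reflectance, "Spectrum"), is(system, "VisualSystem"))
  if (specKind(reflectance) != "reflectance")
    stop("'reflectance' must be a reflectance spectrum")
  if (is.null(illuminant)) illuminant <- d65Illuminant(wavelengths(reflectance))
  stopifnot(is(illuminant, "Spectrum"))
  if (!.sameGrid(reflectance, illuminant))
    stop("reflectance and illuminant must share the same wavelength grid")
  if (all(specValues(reflectance) == 0))
    stop("degenerate input: identically zero reflectance (log ratios undefined)")
  w <- wavelengths(reflectance)
  dl <- .gridStep(w)
  ri <- specValues(reflectance) * specValues(illuminant)
  r <- system@receptors
  q <- vapply(seq_len(nrow(r)), function(i) {
    s <- specValues(pigmentTemplate(r$lambdaMax[i], w))
    sum(ri * s) * dl
  }, numeric(1))
  names(q) <- r$name
  if (any(q <= 0)) stop("nonpositive quantum catch (check spectra overlap)")
  new("QuantumCatchSet", catch = q, systemId = .systemId(system))
}

#' @rdname quantumCatches
#' @param x a `QuantumCatchSet`.
#' @export
catches <- function(x) {
  stopifnot(is(x, "QuantumCatchSet"))
  x@catch
}

setMethod("show", "QuantumCatchSet", function(object) {
  cat("QuantumCatchSet:\n")
  print(signif(object@catch, 5))
})

.checkCatchPair <- function(qA, qB, system) {
  stopifnot(is(qA, "QuantumCatchSet"), is(qB, "QuantumCatchSet"),
            is(system, "VisualSystem"))
  id <- .systemId(system)
  if (!identical(qA@systemId, id) || !identical(qB@systemId, id))
    stop("catch sets were not computed with this visual system")
  nm <- system@receptors$name
  if (!identical(names(qA@catch), nm) || !identical(names(qB@catch), nm))
    stop("receptor mismatch between catch sets and system")
  if (any(qA@catch <= 0) || any(qB@catch <= 0))
    stop("quantum catches must be strictly positive")
}

#' Chromatic contrast (receptor-noise-limited colour distance)
#'
#' Perceptual distance between two stimuli for the colour channels, in JND,
#' under the receptor-noise-limited model: discrimination is limited by
#' Weber-fraction noise omega_i in each receptor channel, acting on the log
#' catch ratios delta-f_i = ln(qA_i / qB_i). For n receptors,
#' \deqn{\Delta S^2 = \frac{\sum_{i<j} (\prod_{k \ne i,j}\omega_k)^2
#'   (\Delta f_i - \Delta f_j)^2}{\sum_i (\prod_{k \ne i}\omega_k)^2}}
#' which reduces to the classic dichromat, trichromat and tetrachromat
#' forms.
#'
#' @param qA,qB [QuantumCatchSet-class] objects from the same system.
#' @param system the [VisualSystem-class] used to compute them.
#' @return Nonnegative chromatic distance in JND.
#' @export
chromaticContrast <- function(qA, qB, system = tawnyDragonVisualSystem()) {
  .checkCatchPair(qA, qB, system)
  df <- log(qA@catch / qB@catch)
  .rnlChromatic(df, receptorNoise(system))
}

# general n-receptor receptor-noise quadratic form on log catch ratios
.rnlChromatic <- function(df, omega) {
  df <- unname(df)
  omega <- unname(omega)
  n <- length(df)
  num <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      wprod <- prod(omega[-c(i, j)])
      num <- num + wprod^2 * (df[i] - df[j])^2
    }
  }
  den <- sum(vapply(seq_len(n), function(i) prod(omega[-i])^2, numeric(1)))
  sqrt(num / den)
}

#' Achromatic contrast (luminance distance)
#'
#' Luminance distance between two stimuli in JND through the achromatic
#' channel: `|ln(qA_ach / qB_ach)| / omega_ach`, using the system's
#' achromatic receptor (LWS by default, omega = 0.05).
#'
#' @inheritParams chromaticContrast
#' @return Nonnegative achromatic distance in JND.
#' @export
achromaticContrast <- function(qA, qB, system = tawnyDragonVisualSystem()) {
  .checkCatchPair(qA, qB, system)
  ach <- system@achromatic
  abs(log(qA@catch[[ach]] / qB@catch[[ach]])) / receptorNoise(system)[[ach]]
}

#' Contrast of a target against a neutral grey background
#'
#' Builds a spectrally flat background of the given reflectance (default the
#' 30% grey used as viewing background), computes quantum catches of target
#' and background under the same illuminant, and returns both chromatic and
#' achromatic JND.
#'
#' @param target reflectance [Spectrum-class] on the analysis grid.
#' @param system a [VisualSystem-class].
#' @param illuminant irradiance [Spectrum-class] (default [d65Illuminant()]).
#' @param backgroundReflectance flat background reflectance fraction
#'   (default 0.30).
#' @return A [ContrastResult-class].
#' @examples
#' vs <- tawnyDragonVisualSystem()
#' contrastVsBackground(flatSpectrum(0.6), vs)  # achromatic only
#' @export
contrastVsBackground <- function(target, system = tawnyDragonVisualSystem(),
                                 illuminant = NULL,
                                 backgroundReflectance = 0.30) {
  stopifnot(is(target, "Spectrum"))
  if (length(backgroundReflectance) != 1L || backgroundReflectance <= 0)
    stop("backgroundReflectance must be a single positive fraction")
  grid <- wavelengths(target)
  if (is.null(illuminant)) illuminant <- d65Illuminant(grid)
  bg <- flatSpectrum(backgroundReflectance, grid)
  qT <- quantumCatches(target, illuminant, system)
  qB <- quantumCatches(bg, illuminant, system)
  new("ContrastResult",
      logRatios = log(qT@catch / qB@catch),
      chromaticJND = chromaticContrast(qT, qB, system),
      achromaticJND = achromaticContrast(qT, qB, system))
}

#' @rdname contrastVsBackground
#' @param x a `ContrastResult`.
#' @export
chromaticJND <- function(x) {
  stopifnot(is(x, "ContrastResult"))
  x@chromaticJND
}

#' @rdname contrastVsBackground
#' @export
achromaticJND <- function(x) {
  stopifnot(is(x, "ContrastResult"))
  x@achromaticJND
}

setMethod("show", "ContrastResult", function(object) {
  cat(sprintf("ContrastResult: chromatic %.3f JND, achromatic %.3f JND\n",
              object@chromaticJND, object@achromaticJND))
})
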