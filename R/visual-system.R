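#' Derive Weber-fraction noise from receptor abundances
#'
#' Channel noise scales with the inverse square root of relative receptor
#' abundance: `omega_i = omega_ref * sqrt(eta_ref / eta_i)`, with the
#' reference receptor's value returned unchanged.
#'
#' @param abundances named numeric vector of relative receptor frequencies
#'   (eta), all positive.
#' @param reference single named numeric: the reference receptor's Weber
#'   fraction, e.g. `c(LWS = 0.05)`.
#' @return Named numeric vector of omega_i, same order as `abundances`.
#' @examples
#' deriveReceptorNoise(c(UVS = 1, SWS = 1, MWS = 3.5, LWS = 6), c(LWS = 0.05))
#' @export
deriveReceptorNoise <- function(abundances, reference = c(LWS = 0.05)) {
  if (is.null(names(abundances)) || anyDuplicated(names(abundances)))
    stop("abundances must be uniquely named by receptor")
  if (any(abundances <= 0)) stop("all abundances must be positive")
  if (length(reference) != 1L || is.null(names(reference)))
    stop("reference must be a single named Weber fraction, e.g. c(LWS = 0.05)")
  ref <- names(reference)
  if (!ref %in% names(abundances))
    stop(sprintf("reference receptor '%s' not among abundances", ref))
  omega <- unname(reference) * sqrt(abundances[[ref]] / abundances)
  omega[ref] <- unname(reference)
  omega
}

#' Construct a visual system
#'
#' @param lambdaMax named numeric of receptor peak sensitivities (nm), in
#'   short- to long-wavelength order.
#' @param abundance named numeric of relative receptor frequencies, same
#'   names.
#' @param referenceNoise single named numeric Weber fraction anchoring the
#'   channel noise (see [deriveReceptorNoise()]).
#' @param achromatic name of the receptor used for luminance contrast.
#' @return A [VisualSystem-class].
#' @export
visualSystem <- function(lambdaMax, abundance,
                         referenceNoise = c(LWS = 0.05),
                         achromatic = names(referenceNoise)) {
  if (is.null(names(lambdaMax)) || is.null(names(abundance)))
    stop("lambdaMax and abundance must be named by receptor")
  if (!identical(names(lambdaMax), names(abundance)))
    stop("lambdaMax and abundance must share receptor names and order")
  omega <- deriveReceptorNoise(abundance, referenceNoise)
  new("VisualSystem",
      receptors = data.frame(name = names(lambdaMax),
                             lambdaMax = as.numeric(lambdaMax),
                             abundance = as.numeric(abundance),
                             noise = as.numeric(omega),
                             stringsAsFactors = FALSE),
      achromatic = achromatic,
      referenceReceptor = names(referenceNoise))
}

#' Tetrachromatic visual system of the tawny dragon
#'
#' The default viewer: a UVS/SWS/MWS/LWS tetrachromat with peak sensitivities
#' 365, 440, 493 and 571 nm, relative receptor frequencies 1 : 1 : 3.5 : 6,
#' and channel noise anchored at omega = 0.05 for the LWS class (the
#' remaining Weber fractions derived from the abundance ratios). LWS doubles
#' as the achromatic (luminance) channel.
#'
#' @return A [VisualSystem-class].
#' @examples
#' vs <- tawnyDragonVisualSystem()
#' receptorNoise(vs)
#' @export
tawnyDragonVisualSystem <- function() {
  visualSystem(
    lambdaMax = c(UVS = 365, SWS = 440, MWS = 493, LWS = 571),
    abundance = c(UVS = 1, SWS = 1, MWS = 3.5, LWS = 6),
    referenceNoise = c(LWS = 0.05),
    achromatic = "LWS")
}

#' @rdname visualSystem
#' @param x a `VisualSystem`.
#' @export
receptorNames <- function(x) {
  stopifnot(is(x, "VisualSystem"))
  x@receptors$name
}

#' @rdname visualSystem
#' @export
receptorNoise <- function(x) {
  stopifnot(is(x, "VisualSystem"))
  stats::setNames(x@receptors$noise, x@receptors$name)
}

#' @rdname visualSystem
#' @export
receptorLambdaMax <- function(x) {
  stopifnot(is(x, "VisualSystem"))
  stats::setNames(x@receptors$lambdaMax, x@receptors$name)
}

#' @rdname visualSystem
#' @export
achromaticReceptor <- function(x) {
  stopifnot(is(x, "VisualSystem"))
  x@achromatic
}

setMethod("show", "VisualSystem", function(object) {
  r <- object@receptors
  cat(sprintf("VisualSystem: %d receptor classes (achromatic: %s)\n",
              nrow(r), object@achromatic))
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-4s lambda_max %3g nm  abundance %4.1f  omega %.4f\n",
                r$name[i], r$lambdaMax[i], r$abundance[i], r$noise[i]))
})

.systemId <- function(system) {
  r <- system@receptors
  paste(r$name, r$lambdaMax, signif(r$noise, 10), sep = ":", collapse = "|")
}
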