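# Seeded generators emulating the structure of the study's measurements:
# morph-typical reflectance spectra, calibration-target throat photographs,
# the 35-female seven-variable feature table, the hormone panel and the
# longitudinal colour trajectories. Every generator is a pure function of
# its arguments and seed.

#' Morph reflectance archetypes
#'
#' Parametric idealizations of the three throat colour classes: orange is a
#' sigmoidal long-pass reflectance with midpoint near 580 nm, yellow a
#' long-pass with midpoint near 500 nm, grey/cream spectrally flat; all have
#' minimal ultraviolet (300-400 nm) reflectance.
#'
#' @param name one of `"orange"`, `"yellow"`, `"grey"`.
#' @return list of archetype parameters (`cutoff`, `slope`, `peak`, `base`).
#' @export
morphArchetype <- function(name = c("orange", "yellow", "grey")) {
  name <- match.arg(name)
  switch(name,
    orange = list(name = "orange", cutoff = 580, slope = 0.08, peak = 0.55,
                  base = 0.03),
    yellow = list(name = "yellow", cutoff = 500, slope = 0.06, peak = 0.50,
                  base = 0.03),
    grey = list(name = "grey", cutoff = NA_real_, slope = NA_real_,
                peak = 0.30, base = 0.30))
}

#' Generate a morph-typical reflectance spectrum
#'
#' A 1-nm spectrum on 300-700 nm built from the archetype's long-pass (or
#' flat) shape with multiplicative lognormal noise, and ultraviolet
#' reflectance suppressed below the visible plateau.
#'
#' @param archetype an archetype from [morphArchetype()] or its name.
#' @param noiseSD lognormal noise standard deviation (log scale).
#' @param seed RNG seed.
#' @return A reflectance [Spectrum-class].
#' @examples
#' s <- genReflectance("orange", seed = 1)
#' contrastVsBackground(s)
#' @export
genReflectance <- function(archetype = "orange", noiseSD = 0.02, seed = 1L) {
  if (is.character(archetype)) archetype <- morphArchetype(archetype)
  grid <- analysisGrid()
  base <- if (is.na(archetype$cutoff)) {
    rep(archetype$peak, length(grid))
  } else {
    archetype$base + (archetype$peak - archetype$base) /
      (1 + exp(-archetype$slope * (grid - archetype$cutoff)))
  }
  # keep UV reflectance minimal regardless of archetype
  uvRolloff <- 1 / (1 + exp(-(grid - 340) / 12))
  base <- base * (0.15 + 0.85 * uvRolloff)
  withr::with_seed(seed, {
    noisy <- base * exp(stats::rnorm(length(grid), 0, noiseSD))
    Spectrum(grid, pmax(noisy, 0), "reflectance")
  })
}

# linear-scene RGB of the three layer classes; scores relative to the
# segmentation thresholds: red patch r - g ~ 0.41, yellow patch
# min(r, g) - b ~ 0.38, grey patch achromatic.
.LAYER_RGB <- list(red = c(0.55, 0.20, 0.10),
                   yellow = c(0.45, 0.38, 0.05),
                   grey = c(0.30, 0.30, 0.30))
.GREY_RAMP <- c(0.03, 0.09, 0.19, 0.36, 0.59, 0.90)

#' Generate a synthetic calibrated-photography scene
#'
#' Composes a throat region whose pixel counts follow the requested
#' red/yellow/grey proportions exactly (largest-remainder apportionment),
#' plus an in-frame 30% grey photographic standard and a six-step grey
#' calibration ramp. The linear scene is then passed through a per-channel
#' power-law camera response (`response = linear^(1/gamma)`) and additive
#' Gaussian sensor noise, emulating an uncalibrated photograph.
#'
#' @param proportions named numeric `(red, yellow, grey)` summing to 1.
#' @param throatSize c(height, width) of the throat region in pixels.
#' @param cameraGamma power-law exponent of the simulated camera response
#'   (1 = already linear).
#' @param noiseSD additive Gaussian noise SD on camera responses.
#' @param seed RNG seed.
#' @return list with `image` (raw H x W x 3 responses), `throatMask`,
#'   `standardMask` (logical matrices), `graySquares` (data.frame
#'   `reflectance`, `R`, `G`, `B` of measured ramp responses for
#'   [fitLinearization()]) and `truth` (the generating proportions).
#' @examples
#' sc <- genThroatImage(c(red = 0.4, yellow = 0.3, grey = 0.3),
#'                      cameraGamma = 1, noiseSD = 0, seed = 1)
#' layerProportions(segmentThroat(sc$image, sc$throatMask))
#' @export
genThroatImage <- function(proportions = c(red = 0.4, yellow = 0.3, grey = 0.3),
                           throatSize = c(40, 40), cameraGamma = 2.2,
                           noiseSD = 0.01, seed = 1L) {
  if (!all(c("red", "yellow", "grey") %in% names(proportions)))
    stop("proportions must be named red, yellow, grey")
  proportions <- proportions[c("red", "yellow", "grey")]
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must be nonnegative and sum to 1")
  th <- as.integer(throatSize[1]); tw <- as.integer(throatSize[2])
  nThroat <- th * tw
  if (nThroat < 3L) stop("throat layout too small for the requested proportions")
  # largest-remainder apportionment of pixels to layers
  raw <- proportions * nThroat
  counts <- floor(raw)
  rem <- nThroat - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  patchH <- 8L
  # bottom strip: six ramp squares then the grey standard, side by side
  H <- th + patchH; W <- max(tw, 7L * patchH)
  linear <- array(0.3, dim = c(H, W, 3))  # neutral backdrop
  # throat block: layer label per pixel, filled in fixed raster order
  labels <- rep(c("red", "yellow", "grey"), times = counts)
  throatMask <- matrix(FALSE, H, W)
  throatMask[seq_len(th), seq_len(tw)] <- TRUE
  idx <- which(throatMask)
  for (k in c("red", "yellow", "grey")) {
    sel <- idx[labels == k]
    for (c in 1:3) {
      plane <- linear[, , c]
      plane[sel] <- .LAYER_RGB[[k]][c]
      linear[, , c] <- plane
    }
  }
  # six-step calibration ramp, then the 30% grey standard patch
  rampMasks <- lapply(seq_along(.GREY_RAMP) - 1L, function(i) {
    m <- matrix(FALSE, H, W)
    m[(th + 1L):H, (i * patchH + 1L):((i + 1L) * patchH)] <- TRUE
    m
  })
  standardMask <- matrix(FALSE, H, W)
  standardMask[(th + 1L):H, (W - patchH + 1L):W] <- TRUE
  for (i in seq_along(rampMasks)) {
    for (c in 1:3) {
      plane <- linear[, , c]
      plane[rampMasks[[i]]] <- .GREY_RAMP[i]
      linear[, , c] <- plane
    }
  }
  for (c in 1:3) {
    plane <- linear[, , c]
    plane[standardMask] <- 0.30
    linear[, , c] <- plane
  }
  img <- withr::with_seed(seed, {
    resp <- linear^(1 / cameraGamma)
    if (noiseSD > 0)
      resp <- resp + array(stats::rnorm(length(resp), 0, noiseSD), dim = dim(resp))
    pmin(pmax(resp, 0), 1)
  })
  graySquares <- data.frame(
    reflectance = .GREY_RAMP,
    R = vapply(rampMasks, function(m) mean(img[, , 1][m]), numeric(1)),
    G = vapply(rampMasks, function(m) mean(img[, , 2][m]), numeric(1)),
    B = vapply(rampMasks, function(m) mean(img[, , 3][m]), numeric(1)))
  list(image = img, throatMask = throatMask, standardMask = standardMask,
       graySquares = graySquares,
       truth = list(proportions = proportions, cameraGamma = cameraGamma,
                    noiseSD = noiseSD, seed = seed))
}

# per-morph means of the seven colour variables (proportions; throat and bib
# chromatic/achromatic JND) used as feature-table defaults
.MORPH_FEATURE_MEANS <- rbind(
  orange = c(0.45, 0.05, 0.50, 12, 8, 4, 8),
  yellow = c(0.05, 0.40, 0.55, 8, 7, 9, 7),
  grey = c(0.02, 0.05, 0.93, 2, 13, 3, 12),
  orange_yellow = c(0.35, 0.30, 0.35, 11, 6, 9, 6))
colnames(.MORPH_FEATURE_MEANS) <- .featureNames

#' Generate a synthetic morph feature table
#'
#' Multivariate-normal draws of the seven colour variables per morph around
#' morph-typical means with a shared (pooled) covariance, mirroring the
#' 35-female study design: 10 orange, 7 yellow, 7 grey and 11 orange+yellow
#' females by default.
#'
#' @param means g x 7 matrix of per-morph feature means (rownames are the
#'   morph labels).
#' @param cov pooled 7 x 7 covariance matrix (default: diagonal with SD
#'   0.08 on proportions and 1.5 JND on contrasts).
#' @param counts named integer vector of females per morph.
#' @param seed RNG seed.
#' @return data.frame with columns `id`, `morph` and the seven features.
#' @export
genFeatureTable <- function(means = .MORPH_FEATURE_MEANS, cov = NULL,
                            counts = c(orange = 10, yellow = 7, grey = 7,
                                       orange_yellow = 11),
                            seed = 1L) {
  p <- ncol(means)
  if (is.null(cov)) cov <- diag(c(rep(0.08, 3), rep(1.5, p - 3))^2)
  if (any(counts < 2)) stop("need at least 2 females per morph")
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("covariance must be positive-definite")
  morphs <- rownames(means)
  stopifnot(identical(sort(morphs), sort(names(counts))))
  withr::with_seed(seed, {
    rows <- lapply(morphs, function(m) {
      X <- MASS::mvrnorm(counts[[m]], means[m, ], cov)
      X <- matrix(X, ncol = p)
      df <- as.data.frame(X)
      names(df) <- colnames(means)
      df$morph <- m
      df
    })
    out <- do.call(rbind, rows)
    out$id <- sprintf("F%02d", seq_len(nrow(out)))
    out[, c("id", "morph", colnames(means))]
  })
}

#' Generate a synthetic plasma testosterone panel
#'
#' Concentrations are lognormal around the timepoint means (positivity and
#' right skew), with a per-female random intercept on the log scale.
#' Defaults follow the experiment's printed summaries: means 55.95, 262.16
#' and 134.02 ng/mL at pre-implant, week 1 and week 4, sampled from 18
#' females with exactly 7 week-1 and 3 week-4 records missing
#' (n = 18/11/15).
#'
#' @param means named timepoint means in ng/mL.
#' @param betweenSD,withinSD between-female and residual SDs on the log
#'   scale.
#' @param nFemales number of implanted females sampled pre-implant.
#' @param missing named integer counts of females missing each
#'   post-implant sample (chosen at random but in fixed number, so the
#'   design is reproducible).
#' @param seed RNG seed.
#' @return data.frame with columns `female`, `timepoint`, `testosterone`.
#' @export
genHormonePanel <- function(means = c(pre = 55.95, week1 = 262.16,
                                      week4 = 134.02),
                            betweenSD = 0.25, withinSD = 0.30,
                            nFemales = 18, missing = c(week1 = 7, week4 = 3),
                            seed = 1L) {
  stopifnot(all(means > 0), betweenSD >= 0, withinSD >= 0)
  tps <- names(means)
  # anchor the log-scale location so the arithmetic mean equals `means`
  means <- means * exp(-(betweenSD^2 + withinSD^2) / 2)
  withr::with_seed(seed, {
    u <- stats::rnorm(nFemales, 0, betweenSD)
    recs <- expand.grid(female = sprintf("F%02d", seq_len(nFemales)),
                        timepoint = tps, stringsAsFactors = FALSE)
    fIdx <- match(recs$female, sprintf("F%02d", seq_len(nFemales)))
    recs$testosterone <- exp(log(means[recs$timepoint]) + u[fIdx] +
                               stats::rnorm(nrow(recs), 0, withinSD))
    drop <- unlist(lapply(names(missing), function(tp) {
      gone <- sample(seq_len(nFemales), missing[[tp]])
      which(recs$timepoint == tp & fIdx %in% gone)
    }))
    if (length(drop)) recs <- recs[-drop, , drop = FALSE]
    rownames(recs) <- NULL
    recs
  })
}

# default quadratic trajectories of proportion red per morph: rising
# curvature for the orange-bearing morphs, flat for yellow and grey
.TIMECOURSE_COEF <- rbind(
  orange = c(intercept = 0.02, time = 0.075, time2 = -0.0030),
  orange_yellow = c(intercept = 0.02, time = 0.060, time2 = -0.0022),
  yellow = c(intercept = 0.03, time = 0.000, time2 = 0.0000),
  grey = c(intercept = 0.03, time = 0.000, time2 = 0.0000))

#' Generate synthetic longitudinal colour trajectories
#'
#' Per-female weekly values of one colour variable following morph-specific
#' quadratic mean trajectories plus a per-female random intercept and
#' residual noise, over the observation weeks 1-6, 10 and 12.
#'
#' @param coefficients g x 3 matrix (`intercept`, `time`, `time2`) of the
#'   generating quadratic per morph (rownames = morph labels).
#' @param interceptSD SD of the per-female random intercept.
#' @param residualSD residual SD.
#' @param weeks observation weeks.
#' @param counts named females per morph.
#' @param response name for the response column.
#' @param seed RNG seed.
#' @return data.frame with columns `female`, `morph`, `week` and the
#'   response.
#' @export
genTimecourse <- function(coefficients = .TIMECOURSE_COEF,
                          interceptSD = 0.03, residualSD = 0.05,
                          weeks = c(1:6, 10, 12),
                          counts = c(orange = 10, yellow = 7, grey = 7,
                                     orange_yellow = 11),
                          response = "prop_red", seed = 1L) {
  if (any(counts < 2)) stop("need at least 2 females per morph")
  morphs <- rownames(coefficients)
  stopifnot(identical(sort(morphs), sort(names(counts))))
  withr::with_seed(seed, {
    rows <- list()
    fid <- 0L
    for (m in morphs) {
      for (i in seq_len(counts[[m]])) {
        fid <- fid + 1L
        u <- stats::rnorm(1, 0, interceptSD)
        mu <- coefficients[m, "intercept"] + coefficients[m, "time"] * weeks +
          coefficients[m, "time2"] * weeks^2
        rows[[fid]] <- data.frame(
          female = sprintf("F%02d", fid), morph = m, week = weeks,
          value = mu + u + stats::rnorm(length(weeks), 0, residualSD))
      }
    }
    out <- do.call(rbind, rows)
    names(out)[names(out) == "value"] <- response
    rownames(out) <- NULL
    out
  })
}
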