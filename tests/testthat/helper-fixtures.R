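# Shared fixtures, all built in code.

# random reflectance spectrum on the analysis grid
randomSpectrum <- function(seed = 1L, grid = analysisGrid()) {
  withr::with_seed(seed, {
    knots <- seq(min(grid), max(grid), length.out = 9)
    v <- stats::runif(9, 0.05, 0.9)
    Spectrum(grid, stats::approx(knots, v, xout = grid)$y, "reflectance")
  })
}

# dichromat with equal-noise channels for closed-form checks
dichromatSystem <- function(omega = 0.05) {
  visualSystem(c(S = 450, L = 560), c(S = 1, L = 1),
               referenceNoise = stats::setNames(omega, "L"),
               achromatic = "L")
}

# feature table with group centroids `sep` pooled SDs apart on the first axis
separatedTable <- function(sep = 10, counts = c(orange = 10, yellow = 7,
                                                grey = 7, orange_yellow = 11),
                           seed = 1L) {
  base <- matrix(rep(c(0.3, 0.3, 0.4, 8, 8, 6, 8), each = 4), nrow = 4)
  colnames(base) <- c("prop_red", "prop_yellow", "prop_grey",
                      "throat_cc", "throat_ac", "bib_cc", "bib_ac")
  rownames(base) <- names(counts)
  sds <- c(rep(0.02, 3), rep(0.5, 4))
  base[, "throat_cc"] <- base[, "throat_cc"] + sep * 0.5 * (0:3)
  base[, "bib_cc"] <- base[, "bib_cc"] + sep * 0.5 * c(0, 1, 0, 1)
  genFeatureTable(means = base, cov = diag(sds^2), counts = counts,
                  seed = seed)
}

# independent tetrachromat receptor-noise formula, written out term by term
tetraChromaticOracle <- function(df, w) {
  num <- (w[1] * w[2])^2 * (df[4] - df[3])^2 +
    (w[1] * w[3])^2 * (df[4] - df[2])^2 +
    (w[1] * w[4])^2 * (df[3] - df[2])^2 +
    (w[2] * w[3])^2 * (df[4] - df[1])^2 +
    (w[2] * w[4])^2 * (df[3] - df[1])^2 +
    (w[3] * w[4])^2 * (df[2] - df[1])^2
  den <- (w[1] * w[2] * w[3])^2 + (w[1] * w[2] * w[4])^2 +
    (w[1] * w[3] * w[4])^2 + (w[2] * w[3] * w[4])^2
  sqrt(num / den)
}

# balanced toy hormone panel: female block effects + timepoint means + noise
toyPanel <- function(tpMeans = c(pre = 10, week1 = 20, week4 = 15),
                     femaleEffects = c(-2, 0, 2), noise = NULL) {
  d <- expand.grid(female = paste0("F", seq_along(femaleEffects)),
                   timepoint = names(tpMeans), stringsAsFactors = FALSE)
  d$testosterone <- tpMeans[d$timepoint] +
    femaleEffects[match(d$female, paste0("F", seq_along(femaleEffects)))]
  if (!is.null(noise)) d$testosterone <- d$testosterone + noise
  d
}
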