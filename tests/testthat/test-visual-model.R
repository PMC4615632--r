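test_that("receptor noise derives from abundances by inverse square root", {
  eta <- c(UVS = 1, SWS = 1, MWS = 3.5, LWS = 6)
  omega <- deriveReceptorNoise(eta, c(LWS = 0.05))
  expect_identical(omega[["LWS"]], 0.05)
  expect_equal(omega[["MWS"]], 0.05 * sqrt(6 / 3.5), tolerance = 1e-12)
  expect_equal(omega[["UVS"]], 0.05 * sqrt(6), tolerance = 1e-12)
  expect_equal(omega[["SWS"]], 0.05 * sqrt(6), tolerance = 1e-12)

  equalEta <- c(A = 2, B = 2, C = 2)
  expect_true(all(deriveReceptorNoise(equalEta, c(B = 0.1)) == 0.1))
  expect_error(deriveReceptorNoise(c(A = -1, B = 1), c(B = 0.05)), "positive")
})

test_that("pigment template peaks at lambda-max with a decreasing long flank", {
  tp <- pigmentTemplate(571)
  w <- wavelengths(tp)
  v <- specValues(tp)
  expect_equal(v[w == 571], 1, tolerance = 1e-9)
  expect_lt(v[w == 671], v[w == 621])  # long-wave flank decreasing
  expect_error(pigmentTemplate(250), "300")
})

test_that("template matches an independent evaluation of the A1 equations", {
  # hand evaluation at 500 nm for a 571 nm pigment: alpha band in x =
  # lmax/lambda plus the beta band, peak-normalized on the same grid
  lmax <- 571; lam <- 500
  a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
  alphaAt <- function(l) {
    x <- lmax / l
    1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
           exp(-14.9 * (1.104 - x)) + 0.674)
  }
  betaAt <- function(l)
    0.26 * exp(-((l - (189 + 0.315 * lmax)) / (-40.5 + 0.195 * lmax))^2)
  grid <- analysisGrid()
  expected <- (alphaAt(lam) + betaAt(lam)) /
    max(alphaAt(grid) + betaAt(grid))
  tp <- pigmentTemplate(571)
  expect_equal(specValues(tp)[wavelengths(tp) == 500], expected,
               tolerance = 1e-12)
})

test_that("quantum catches integrate reflectance x illuminant x sensitivity", {
  vs <- tawnyDragonVisualSystem()
  grid <- analysisGrid()
  unitIll <- Spectrum(grid, rep(1, length(grid)), "irradiance")
  qWhite <- quantumCatches(flatSpectrum(1), unitIll, vs)
  sensInt <- vapply(receptorLambdaMax(vs), function(lm)
    sum(specValues(pigmentTemplate(lm, grid))), numeric(1))
  expect_equal(unname(catches(qWhite)), unname(sensInt), tolerance = 1e-9)

  # linear in the reflectance: 30% grey is 0.3 x white, every receptor
  qGrey <- quantumCatches(flatSpectrum(0.3), unitIll, vs)
  expect_equal(catches(qGrey), 0.3 * catches(qWhite), tolerance = 1e-12)
})

test_that("catches match a brute-force 1-nm summation oracle", {
  grid <- analysisGrid()
  refl <- Spectrum(grid, 0.6 * exp(-((grid - 600) / 30)^2 / 2), "reflectance")
  ill <- d65Illuminant(grid)
  vsOne <- visualSystem(c(L = 571, M = 493), c(L = 1, M = 1), c(L = 0.05),
                        achromatic = "L")
  q <- quantumCatches(refl, ill, vsOne)
  s571 <- specValues(pigmentTemplate(571, grid))
  brute <- sum(specValues(refl) * specValues(ill) * s571)  # dl = 1
  expect_equal(catches(q)[["L"]], brute, tolerance = 1e-12)
})

test_that("catch computation rejects degenerate inputs", {
  vs <- tawnyDragonVisualSystem()
  expect_error(quantumCatches(flatSpectrum(0), system = vs), "zero reflectance")
  ill <- d65Illuminant(seq(300, 700, by = 2))
  expect_error(quantumCatches(flatSpectrum(0.3), ill, vs), "same wavelength grid")
})

test_that("chromatic contrast is zero at identity, symmetric, and matches the dichromat closed form", {
  vs <- dichromatSystem(0.05)
  q <- quantumCatches(randomSpectrum(seed = 2), system = vs)
  expect_equal(chromaticContrast(q, q, vs), 0)

  for (seed in 1:5) {
    qA <- quantumCatches(randomSpectrum(seed = seed), system = vs)
    qB <- quantumCatches(randomSpectrum(seed = seed + 50), system = vs)
    expect_equal(chromaticContrast(qA, qB, vs),
                 chromaticContrast(qB, qA, vs), tolerance = 1e-12)
  }

  # delta-f = (ln 2, 0), omega = (0.05, 0.05): JND = ln 2 / sqrt(0.005)
  qA <- quantumCatches(flatSpectrum(0.3), system = vs)
  doubledL <- catches(qA); doubledL[["S"]] <- 2 * doubledL[["S"]]
  qB <- new("QuantumCatchSet", catch = doubledL, systemId = qA@systemId)
  expect_equal(chromaticContrast(qB, qA, vs), log(2) / sqrt(2 * 0.05^2),
               tolerance = 1e-9)
})

test_that("tetrachromat contrast equals the explicit six-term quadratic form", {
  vs <- tawnyDragonVisualSystem()
  w <- unname(receptorNoise(vs))
  for (seed in 1:10) {
    qA <- quantumCatches(randomSpectrum(seed = seed), system = vs)
    qB <- quantumCatches(randomSpectrum(seed = seed + 100), system = vs)
    df <- unname(log(catches(qA) / catches(qB)))
    expect_equal(chromaticContrast(qA, qB, vs), tetraChromaticOracle(df, w),
                 tolerance = 1e-9)
  }
})

test_that("chromatic contrast is invariant to illuminant scale", {
  vs <- tawnyDragonVisualSystem()
  grid <- analysisGrid()
  ill <- d65Illuminant(grid)
  ill5 <- Spectrum(grid, 5 * specValues(ill), "irradiance")
  a <- randomSpectrum(seed = 4); b <- randomSpectrum(seed = 5)
  d1 <- chromaticContrast(quantumCatches(a, ill, vs),
                          quantumCatches(b, ill, vs), vs)
  d2 <- chromaticContrast(quantumCatches(a, ill5, vs),
                          quantumCatches(b, ill5, vs), vs)
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("achromatic contrast follows the luminance log ratio", {
  vs <- tawnyDragonVisualSystem()
  q6 <- quantumCatches(flatSpectrum(0.6), system = vs)
  q3 <- quantumCatches(flatSpectrum(0.3), system = vs)
  expect_equal(achromaticContrast(q6, q3, vs), abs(log(2)) / 0.05,
               tolerance = 1e-9)
  expect_equal(achromaticContrast(q3, q3, vs), 0)

  # doubling both spectra leaves the ratio unchanged
  s <- randomSpectrum(seed = 6)
  s2 <- Spectrum(wavelengths(s), 2 * specValues(s), "reflectance")
  bg <- flatSpectrum(0.3)
  bg2 <- flatSpectrum(0.6)
  expect_equal(
    achromaticContrast(quantumCatches(s, system = vs),
                       quantumCatches(bg, system = vs), vs),
    achromaticContrast(quantumCatches(s2, system = vs),
                       quantumCatches(bg2, system = vs), vs),
    tolerance = 1e-12)
})

test_that("contrast against the 30% grey background behaves as closed forms predict", {
  vs <- tawnyDragonVisualSystem()
  same <- contrastVsBackground(flatSpectrum(0.30), vs)
  expect_equal(chromaticJND(same), 0, tolerance = 1e-9)
  expect_equal(achromaticJND(same), 0, tolerance = 1e-9)

  bright <- contrastVsBackground(flatSpectrum(0.60), vs)
  expect_equal(chromaticJND(bright), 0, tolerance = 1e-9)
  expect_equal(achromaticJND(bright), abs(log(2)) / 0.05, tolerance = 1e-9)

  orange <- genReflectance("orange", noiseSD = 0, seed = 1)
  flatSame <- flatSpectrum(mean(specValues(orange)))
  expect_gt(chromaticJND(contrastVsBackground(orange, vs)),
            chromaticJND(contrastVsBackground(flatSame, vs)))

  expect_error(contrastVsBackground(flatSpectrum(0.3), vs,
                                    backgroundReflectance = 0), "positive")
})
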