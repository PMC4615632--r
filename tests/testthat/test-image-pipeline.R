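test_that("linearization recovers a power-law camera response", {
  refl <- c(0.03, 0.09, 0.19, 0.36, 0.59, 0.90)

  # responses already proportional to reflectance: gamma ~ 1, gain ~ slope
  resp <- cbind(R = refl / 0.9, G = refl / 0.9, B = refl / 0.9)
  m <- fitLinearization(resp, refl)
  expect_equal(unname(m$gamma), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(m$gain), rep(0.9, 3), tolerance = 1e-9)
  expect_true(all(abs(unlist(m$residuals)) < 1e-9))

  # gamma-distorted responses: recovered exponent 2.2 exactly (noise-free)
  respG <- cbind(R = refl, G = refl, B = refl)^(1 / 2.2)
  mG <- fitLinearization(respG, refl)
  expect_equal(unname(mG$gamma), rep(2.2, 3), tolerance = 1e-6)

  # duplicated pairs do not change the fit
  mDup <- fitLinearization(respG[c(1:6, 1, 1), ], refl[c(1:6, 1, 1)])
  expect_equal(mDup$gamma, mG$gamma, tolerance = 1e-12)

  expect_error(fitLinearization(respG[1:2, ], refl[1:2]), "at least 3")
  bent <- respG; bent[1, 1] <- bent[2, 1] + 0.001  # R channel dips once
  expect_warning(fitLinearization(bent, refl), "channel R .* not monotone")
})

test_that("calibration application is an identity/round-trip/monotone map", {
  sc <- genThroatImage(c(red = 0.4, yellow = 0.3, grey = 0.3),
                       cameraGamma = 2.2, noiseSD = 0, seed = 1)
  ident <- structure(list(gain = rep(1, 3), gamma = rep(1, 3),
                          luminance = list(gain = 1, gamma = 1),
                          residuals = list(0, 0, 0)),
                     class = "calibrationModel")
  expect_equal(applyCalibration(sc$image, ident), sc$image,
               ignore_attr = TRUE)

  m <- fitLinearization(sc$graySquares[, c("R", "G", "B")],
                        sc$graySquares$reflectance)
  linear <- applyCalibration(sc$image, m)
  # the scene was built linear then gamma-distorted: round trip recovers it
  scLin <- genThroatImage(c(red = 0.4, yellow = 0.3, grey = 0.3),
                          cameraGamma = 1, noiseSD = 0, seed = 1)
  expect_equal(linear, scLin$image, tolerance = 1e-6, ignore_attr = TRUE)

  # pixelwise monotone: larger response never maps below a smaller one
  v <- seq(0.05, 1, length.out = 20)
  img <- array(rep(v, 3), dim = c(4, 5, 3))
  out <- applyCalibration(img, m)
  for (c in 1:3) expect_true(all(diff(out[, , c][order(img[, , c])]) >= 0))
})

test_that("grey-standard equalization pins the standard at its reflectance", {
  sc <- genThroatImage(c(red = 0.4, yellow = 0.3, grey = 0.3),
                       cameraGamma = 1, noiseSD = 0, seed = 1)
  eq <- equalizeToStandard(sc$image, sc$standardMask)
  for (c in 1:3)
    expect_equal(mean(eq[, , c][sc$standardMask]), 0.30, tolerance = 1e-12)
  # already-equalized image is a fixed point
  expect_equal(equalizeToStandard(eq, sc$standardMask), eq,
               ignore_attr = TRUE)

  # global lighting change is removed
  dimmed <- sc$image * 0.5
  expect_equal(equalizeToStandard(dimmed, sc$standardMask), eq,
               tolerance = 1e-12, ignore_attr = TRUE)

  # hand-computed channel factors for a colour-cast standard
  img <- array(0, dim = c(2, 2, 3))
  img[, , 1] <- 0.6; img[, , 2] <- 0.3; img[, , 3] <- 0.2
  mask <- matrix(TRUE, 2, 2)
  out <- equalizeToStandard(img, mask)
  expect_equal(unname(attr(out, "scaleFactors")), c(0.5, 1.0, 1.5))

  img[, , 2] <- 0
  expect_error(equalizeToStandard(img, mask), "degenerate")
})

test_that("segmentation classifies constructed patches exactly", {
  # achromatic image: everything grey
  img <- array(0.4, dim = c(10, 10, 3))
  mask <- matrix(TRUE, 10, 10)
  expect_equal(unname(layerProportions(segmentThroat(img, mask))),
               c(0, 0, 1))

  # constructed 40/30/30 scene, noise-free, gamma 1
  sc <- genThroatImage(c(red = 0.4, yellow = 0.3, grey = 0.3),
                       cameraGamma = 1, noiseSD = 0, seed = 1)
  seg <- segmentThroat(sc$image, sc$throatMask)
  expect_equal(unname(layerProportions(seg)), c(0.4, 0.3, 0.3))
  expect_identical(seg@nPixels, sum(sc$throatMask))

  # zero-sum pixels carry no chromatic signal: counted as grey
  dark <- sc$image
  dark[1, 1, ] <- 0
  segDark <- segmentThroat(dark, sc$throatMask)
  expect_gte(segDark@propGrey, seg@propGrey)
})

test_that("segmentation proportions sum to 1, ignore scale, and respond monotonically to thresholds", {
  sc <- genThroatImage(c(red = 0.5, yellow = 0.2, grey = 0.3),
                       cameraGamma = 1, noiseSD = 0.02, seed = 9)
  seg <- segmentThroat(sc$image, sc$throatMask)
  expect_equal(sum(layerProportions(seg)), 1, tolerance = 1e-12)

  segScaled <- segmentThroat(sc$image * 0.5, sc$throatMask)
  expect_equal(layerProportions(segScaled), layerProportions(seg))

  # raising the red threshold never increases the red proportion
  reds <- vapply(c(0.1, 0.2, 0.3, 0.4), function(t)
    segmentThroat(sc$image, sc$throatMask,
                  c(red = t, yellow = 0.15))@propRed, numeric(1))
  expect_true(all(diff(reds) <= 0))

  expect_error(segmentThroat(sc$image, sc$throatMask,
                             c(red = 0, yellow = 0.15)), "\\(0, 1\\)")
})

test_that("image and mask files round-trip through PNG", {
  sc <- genThroatImage(c(red = 0.4, yellow = 0.3, grey = 0.3),
                       cameraGamma = 1, noiseSD = 0, seed = 1)
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(sc$image, f)
  img <- readImageRaster(f)
  expect_lt(max(abs(img - sc$image)), 1 / 255)  # 8-bit quantization only

  fm <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(as.numeric(sc$throatMask), nrow(sc$throatMask)), fm)
  expect_identical(readMaskImage(fm), sc$throatMask)
})
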