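test_that("the blocked testosterone ANOVA reproduces the repeat-sampling design df", {
  panel <- genHormonePanel(seed = 1)
  expect_identical(as.vector(table(panel$timepoint)[c("pre", "week1", "week4")]),
                   c(18L, 11L, 15L))
  at <- anovaTime(panel)
  expect_identical(at$df, c(2L, 24L))
  expect_identical(at$nRecords, 44L)
  expect_identical(at$nFemales, 18L)
})

test_that("ANOVA F matches a hand sums-of-squares decomposition on a balanced toy panel", {
  withr::with_seed(13, noise <- rnorm(9, 0, 1))
  d <- toyPanel(noise = noise)
  at <- anovaTime(d)
  # hand two-way decomposition: balanced 3 females x 3 timepoints
  y <- matrix(d$testosterone, nrow = 3)  # rows = females, cols = timepoints
  grand <- mean(y)
  ssTime <- 3 * sum((colMeans(y) - grand)^2)
  ssFemale <- 3 * sum((rowMeans(y) - grand)^2)
  ssTotal <- sum((y - grand)^2)
  ssErr <- ssTotal - ssTime - ssFemale
  expect_equal(at$F, (ssTime / 2) / (ssErr / 4), tolerance = 1e-9)
  expect_identical(at$df, c(2L, 4L))
  expect_equal(sort(at$lsmeans$mean), sort(colMeans(y)), tolerance = 1e-9)
})

test_that("ANOVA null and invariance properties hold", {
  # response depends on female only: time effect vanishes
  d <- toyPanel(femaleEffects = c(-5, 0, 5),
                tpMeans = c(pre = 10, week1 = 10, week4 = 10))
  withr::with_seed(3, d$testosterone <- d$testosterone + rnorm(9, 0, 0.5))
  at <- anovaTime(d)
  expect_lt(at$F, 5)  # no systematic time signal

  # adding a per-female constant is absorbed by the block factor
  panel <- genHormonePanel(seed = 2)
  shifted <- panel
  bump <- stats::setNames(seq_len(18) * 3, sprintf("F%02d", 1:18))
  shifted$testosterone <- shifted$testosterone + bump[shifted$female]
  expect_equal(anovaTime(shifted)$F, anovaTime(panel)$F, tolerance = 1e-9)

  noiseless <- genHormonePanel(betweenSD = 0, withinSD = 0, seed = 1)
  expect_error(anovaTime(noiseless), "degenerate")
})

test_that("pairwise contrasts are Tukey-adjusted least-squares differences", {
  panel <- genHormonePanel(seed = 4)
  at <- anovaTime(panel)
  pw <- pairwiseAdjusted(at)
  expect_identical(nrow(pw), 3L)
  expect_true(all(pw$df == at$df[2]))

  # adjusted p never below the unadjusted two-sided p
  raw <- 2 * stats::pt(abs(pw$t), pw$df, lower.tail = FALSE)
  expect_true(all(pw$pAdjusted >= raw - 1e-12))

  # balanced toy: t equals mean difference / (s * sqrt(2/n))
  withr::with_seed(17, noise <- rnorm(9))
  d <- toyPanel(noise = noise)
  atT <- anovaTime(d)
  pwT <- pairwiseAdjusted(atT)
  y <- matrix(d$testosterone, nrow = 3)
  s2 <- sum(stats::residuals(atT$fit)^2) / atT$df[2]
  tHand <- (colMeans(y)[1] - colMeans(y)[2]) / sqrt(s2 * 2 / 3)
  expect_equal(pwT$t[pwT$contrast == "pre - week1"], unname(tHand),
               tolerance = 1e-9)

  # identical observed timepoint means: noise balanced across the design
  # (zero row and column sums) leaves residual variance but t exactly 0
  flat <- toyPanel(tpMeans = c(pre = 10, week1 = 10, week4 = 10))
  balanced <- c(0.1, -0.1, 0, -0.1, 0.1, 0, 0, 0, 0)
  flat$testosterone <- flat$testosterone + balanced
  pwF <- pairwiseAdjusted(anovaTime(flat))
  expect_equal(pwF$t, rep(0, 3), tolerance = 1e-9)
  expect_true(all(pwF$pAdjusted > 0.999))
})

test_that("the exact r x c test reproduces hand enumerations", {
  res <- freemanHaltonExact(matrix(c(3, 1, 1, 3), 2))
  expect_equal(res$pValue, 34 / 70, tolerance = 1e-12)
  expect_identical(res$nTables, 5L)

  expect_equal(freemanHaltonExact(matrix(1, 2, 2))$pValue, 1)

  # hand enumeration of the 3 tables with margins (2,3)/(2,3):
  # p = P(k=2) = C(2,2)C(3,0)/C(5,2) = 0.1, the unique most extreme table
  diagTab <- freemanHaltonExact(matrix(c(2, 0, 0, 3), 2))
  expect_equal(diagTab$pValue, 0.1, tolerance = 1e-12)
  expect_identical(diagTab$nTables, 3L)

  # margins admitting a single table: p = 1
  expect_equal(freemanHaltonExact(matrix(c(2, 3), 1, 2))$pValue, 1)

  expect_error(freemanHaltonExact(matrix(c(1, -1, 1, 1), 2)), "nonnegative")
  expect_error(freemanHaltonExact(matrix(c(0, 0, 1, 1), 2)), "margins")
})

test_that("2 x 2 enumeration agrees with the classic Fisher exact test on random tables", {
  withr::with_seed(42, {
    for (i in 1:50) {
      tab <- matrix(rpois(4, 4) + 1, 2)
      expect_equal(freemanHaltonExact(tab)$pValue,
                   stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    }
  })
})

test_that("large tables route to the seeded Monte-Carlo mode", {
  big <- matrix(c(80, 40, 30, 70), 2)
  expect_error(freemanHaltonExact(big), "enumeration bound")
  mc <- freemanHaltonExact(big, monteCarlo = TRUE, B = 2e4, seed = 7)
  expect_identical(mc$method, "monte-carlo")
  exact <- freemanHaltonExact(big, enumerationBound = 300)
  expect_equal(mc$pValue, exact$pValue, tolerance = 0.02)
  expect_identical(freemanHaltonExact(big, monteCarlo = TRUE, B = 1e4,
                                      seed = 7)$pValue,
                   freemanHaltonExact(big, monteCarlo = TRUE, B = 1e4,
                                      seed = 7)$pValue)
})

test_that("BH adjustment matches the step-up rule and preserves ranks", {
  expect_equal(fdrBH(0.03), 0.03)
  expect_equal(fdrBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  withr::with_seed(31, p <- runif(20))
  adj <- fdrBH(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= 0))  # monotone in raw rank

  # thresholding adjusted values at q reproduces the step-up rejection set
  q <- 0.2
  m <- length(p)
  ord <- order(p)
  k <- max(c(0, which(p[ord] <= seq_len(m) / m * q)))
  rejected <- if (k > 0) sort(ord[seq_len(k)]) else integer(0)
  expect_identical(which(adj <= q), rejected)

  expect_error(fdrBH(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fdrBH(numeric(0)), "empty")
})
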