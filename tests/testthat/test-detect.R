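test_that("profile normalisation and distance have their closed forms", {
  expect_identical(normalizeProfile(c(2, 2, 0, 0)), c(0.5, 0.5, 0, 0))
  expect_identical(normalizeProfile(c(0, 5, 0)), c(0, 1, 0))
  set.seed(1)
  v <- runif(96)
  expect_lt(abs(sum(normalizeProfile(v)) - 1), 1e-12)
  expect_error(normalizeProfile(c(0, 0)), "all-zero")

  expect_identical(profileDistance(c(3, 1), c(3, 1)), 0)
  expect_equal(profileDistance(c(1, 0), c(0, 1)), sqrt(2), tolerance = 1e-12)
  # triangle inequality on random count triples
  for (i in 1:25) {
    a <- rpois(10, 5) + 1; b <- rpois(10, 5) + 1; c <- rpois(10, 5) + 1
    expect_lte(profileDistance(a, c),
               profileDistance(a, b) + profileDistance(b, c) + 1e-12)
  }
})

test_that("bootstrap replicates conserve totals and match multinomial moments", {
  counts <- c(10, 0, 0)
  reps <- bootstrapProfiles(counts, 50L, seed = 1)
  expect_true(all(reps[1, ] == 10L))
  expect_true(all(colSums(reps) == 10L))

  counts <- c(120, 40, 30, 10)
  reps <- bootstrapProfiles(counts, 7000L, seed = 2)
  expect_true(all(colSums(reps) == 200L))
  p <- counts / sum(counts)
  se <- sqrt(200 * p * (1 - p) / 7000)
  expect_true(all(abs(rowMeans(reps) - counts) <= 3 * se + 1e-9))
  expect_error(bootstrapProfiles(c(0, 0), 10L), "zero-total")
})

test_that("shift test separates orthogonal spectra and stays quiet on copies", {
  K <- 20
  pA <- normalizeProfile(c(rep(4, 10), rep(0.1, 10)))
  pB <- normalizeProfile(c(rep(0.1, 10), rep(4, 10)))
  set.seed(3)
  par <- sapply(1:5, function(i) rmultinom(1, 500, pA)[, 1])
  rownames(par) <- NULL
  subSame <- sapply(1:4, function(i) rmultinom(1, 500, pA)[, 1])
  subDiff <- sapply(1:4, function(i) rmultinom(1, 500, pB)[, 1])

  same <- spectrumShiftTest(par, subSame, fastBoot(seed = 11))
  diff <- spectrumShiftTest(par, subDiff, fastBoot(seed = 11))
  expect_false(isShifted(same))
  expect_true(isShifted(diff))
  expect_gt(diff@dPS, 0.3)  # large separation for near-orthogonal spectra
  expect_error(spectrumShiftTest(par[, 1, drop = FALSE], subSame,
                                 fastBoot(seed = 1)), "2 parental")
})

test_that("shift test is deterministic under a seed and uses floor-rank thresholds", {
  set.seed(9)
  par <- sapply(1:4, function(i) rmultinom(1, 300, rep(1 / 8, 8))[, 1])
  sub <- sapply(1:3, function(i) rmultinom(1, 300, rep(1 / 8, 8))[, 1])
  a <- spectrumShiftTest(par, sub, fastBoot(seed = 21))
  b <- spectrumShiftTest(par, sub, fastBoot(seed = 21))
  expect_identical(a, b)
  # threshold coherence: empirical (1 - alpha) quantile at the floor rank
  n <- length(a@dPCDistribution)
  expect_identical(a@dPCThreshold,
                   sort(a@dPCDistribution)[floor(0.99 * n)])
  expect_identical(a@dSCThreshold,
                   sort(a@dSCDistribution)[floor(0.99 * n)])
})

test_that("parental null threshold tightens as totals grow", {
  p <- normalizeProfile(c(4, 3, 2, 1, rep(0.5, 8)))
  set.seed(5)
  small <- sapply(1:5, function(i) rmultinom(1, 200, p)[, 1])
  big <- sapply(1:5, function(i) rmultinom(1, 2000, p)[, 1])
  thrSmall <- parentalBootstrapNull(small, fastBoot(seed = 31))$threshold
  thrBig <- parentalBootstrapNull(big, fastBoot(seed = 31))$threshold
  expect_lt(thrBig, thrSmall)
})

test_that("count elevation p-values behave like an add-one bootstrap", {
  baseline <- rep(c(90, 100, 110), 20)
  # target at the baseline mean: p close to 1/2
  res <- countElevationTest(rep(100, 7), baseline, nBoot = 4000L, seed = 1)
  expect_gt(pValue(res), 0.4)
  expect_lt(pValue(res), 0.6)
  # unreachable aggregate: the add-one floor
  res2 <- countElevationTest(rep(1000, 7), baseline, nBoot = 4000L,
                             seed = 1)
  expect_identical(pValue(res2), 1 / 4001)
  # monotonicity: doubling the target cannot increase p
  res3 <- countElevationTest(rep(120, 7), baseline, nBoot = 4000L, seed = 2)
  res4 <- countElevationTest(rep(240, 7), baseline, nBoot = 4000L, seed = 2)
  expect_lte(pValue(res4), pValue(res3))
  expect_error(countElevationTest(rep(1, 3), numeric(0)), "baseline")
})

test_that("knockout calls require both a shift and a count elevation", {
  shiftYes <- new("ShiftTestResult", dPS = 0.5, dPCThreshold = 0.1,
                  dSCThreshold = 0.1, alpha = 0.01, shifted = TRUE,
                  dPCDistribution = numeric(0), dSCDistribution = numeric(0))
  shiftNo <- new("ShiftTestResult", dPS = 0.05, dPCThreshold = 0.1,
                 dSCThreshold = 0.1, alpha = 0.01, shifted = FALSE,
                 dPCDistribution = numeric(0), dSCDistribution = numeric(0))
  mkCount <- function(p) new("CountTestResult", observed = 1, pValue = p,
                             nBoot = 10000L, nTarget = 7L,
                             baselineQuantiles = numeric(0))
  # a clear indel spectrum shift without a count increase is negative
  expect_false(hasSignature(callKnockout(shiftYes, mkCount(0.9966))))
  # a count p-value at the border of the threshold is negative (strict <)
  expect_false(hasSignature(callKnockout(shiftYes, mkCount(0.0105),
                                         alpha = 0.01)))
  expect_false(hasSignature(callKnockout(shiftNo, mkCount(0.001))))
  expect_true(hasSignature(callKnockout(shiftYes, mkCount(0.001))))
  expect_match(callKnockout(shiftYes, mkCount(0.9966))@reason,
               "no count elevation")
})

test_that("null knockouts are rarely shifted at the configured alpha", {
  # small-scale null calibration; the full-size run lives in the
  # acceptance suite
  # the full experimental layout (9 parental clones, 7 subclones); a
  # trimmed-down design with fewer samples makes the subclone cloud too
  # tight and is not representative
  shifted <- vapply(1:20, function(i) {
    sim <- simulateCatalogs(simulationConfig(
      "substitution", seed = 5000L + i))
    isShifted(spectrumShiftTest(sim$parental, sim$subclones,
                                fastBoot(seed = 100L + i)))
  }, NA)
  expect_lte(sum(shifted), 2L)
})
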