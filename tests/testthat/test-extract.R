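test_that("parental mean profile pools counts, weighting by burden", {
  m <- matrix(c(4, 0, 0, 4), nrow = 2)
  expect_equal(unname(profileWeights(parentalMeanProfile(
    rbind(m, matrix(0, 6, 2))))[1:2]), c(0.5, 0.5))
  # pooling is not an average of proportions: [9,1] and [0,10] -> .45/.55
  m2 <- rbind(matrix(c(9, 1, 0, 10), nrow = 2), matrix(0, 6, 2))
  expect_equal(unname(profileWeights(parentalMeanProfile(m2))[1:2]),
               c(0.45, 0.55))
  # single parental clone: its own normalised profile
  single <- rbind(matrix(c(3, 1), nrow = 2), matrix(0, 6, 1))
  expect_equal(unname(profileWeights(parentalMeanProfile(single))[1:2]),
               c(0.75, 0.25))
})

test_that("channel boundaries are degenerate-safe, nested and well-ordered", {
  oneHot <- rbind(matrix(c(0, 20, 0), nrow = 3), matrix(0, 7, 1))
  b <- subcloneChannelBoundaries(oneHot, nBoot = 200L, seed = 1)
  expect_identical(b$lower[2], 20L)
  expect_identical(b$upper[2], 20L)
  expect_identical(b$lower[1], 0L)
  expect_identical(b$upper[1], 0L)

  set.seed(2)
  counts <- sapply(1:5, function(i) rmultinom(1, 400, rep(1 / 10, 10))[, 1])
  b90 <- subcloneChannelBoundaries(counts, nBoot = 3000L, ciLevel = 0.90,
                                   seed = 3)
  b99 <- subcloneChannelBoundaries(counts, nBoot = 3000L, ciLevel = 0.99,
                                   seed = 3)
  expect_true(all(b99$lower <= b90$lower))
  expect_true(all(b99$upper >= b90$upper))
  expect_true(all(b99$lower <= b99$upper))
})

test_that("boundary coverage is close to the nominal level", {
  # a fresh multinomial draw of the centroid should land inside the 99%
  # bounds in roughly 99% of channels/replicates
  p <- normalizeProfile(c(5, 4, 3, 2, 1, 1, 1, 1, 1, 1))
  set.seed(4)
  counts <- sapply(1:7, function(i) rmultinom(1, 800, p)[, 1])
  b <- subcloneChannelBoundaries(counts, nBoot = 5000L, seed = 5)
  hits <- replicate(300, {
    draw <- rmultinom(1, b$centroidTotal, b$centroidProportions)[, 1]
    all(draw >= b$lower & draw <= b$upper)
  })
  expect_gt(mean(hits), 0.85)  # joint coverage over 10 channels
})

test_that("background exposure estimation recovers trivial regimes", {
  p <- SignatureProfile(rep(1 / 8, 8), "indel")
  wide <- structure(list(lower = rep(0L, 8), upper = rep(10000L, 8),
                         centroidTotal = 100, ciLevel = 0.99),
                    class = "ChannelBoundaries")
  e <- estimateBackgroundExposure(p, 100, wide, seed = 1)
  expect_identical(as.integer(e), 100L)
  expect_identical(attr(e, "iterations"), 1L)
  expect_identical(attr(e, "acceptanceFraction"), 1)

  # subclones that are pure background stop within noise of the start
  set.seed(6)
  counts <- sapply(1:7, function(i) rmultinom(1, 400, rep(1 / 8, 8))[, 1])
  b <- subcloneChannelBoundaries(counts, nBoot = 4000L, seed = 7)
  e2 <- estimateBackgroundExposure(p, b$centroidTotal, b, seed = 8)
  expect_gt(as.integer(e2), 0.95 * b$centroidTotal)

  expect_error(estimateBackgroundExposure(p, 100, wide, step = 0), "step")
})

test_that("the two-sided rule degenerates when the knockout occupies empty channels", {
  # background on channels 1-4 only; knockout mass on channels 5-8 pushes
  # their lower bounds above anything a background profile can reach
  p <- SignatureProfile(c(rep(0.25, 4), rep(0, 4)), "indel")
  set.seed(9)
  counts <- sapply(1:7, function(i) {
    rmultinom(1, 300, c(rep(0.25, 4), rep(0, 4)))[, 1] +
      rmultinom(1, 300, c(rep(0, 4), rep(0.25, 4)))[, 1]
  })
  b <- subcloneChannelBoundaries(counts, nBoot = 4000L, seed = 10)
  expect_warning(
    eBoth <- estimateBackgroundExposure(p, b$centroidTotal, b, seed = 11,
                                        search = "coarse",
                                        boundaryRule = "both"),
    "returning 0")
  expect_identical(as.integer(eBoth), 0L)
  # the envelope rule recovers a positive background exposure instead
  eUp <- estimateBackgroundExposure(p, b$centroidTotal, b, seed = 11)
  expect_gt(as.integer(eUp), 200L)
  expect_lt(as.integer(eUp), 450L)
})

test_that("coarse search returns the same exposure as unit stepping", {
  p <- defaultBackgroundProfile()
  ko <- knockoutProfile("mmr")
  set.seed(12)
  counts <- sapply(1:7, function(i) {
    rmultinom(1, 600, profileWeights(p))[, 1] +
      rmultinom(1, 600, profileWeights(ko))[, 1]
  })
  b <- subcloneChannelBoundaries(counts, nBoot = 4000L, seed = 13)
  eUnit <- estimateBackgroundExposure(p, b$centroidTotal, b, seed = 14,
                                      search = "unit")
  eCoarse <- estimateBackgroundExposure(p, b$centroidTotal, b, seed = 14,
                                        search = "coarse")
  expect_identical(as.integer(eUnit), as.integer(eCoarse))
  expect_lt(attr(eCoarse, "iterations"), attr(eUnit, "iterations"))
})

test_that("widening boundaries can only increase the returned exposure", {
  p <- SignatureProfile(rep(1 / 8, 8), "indel")
  set.seed(15)
  counts <- sapply(1:5, function(i) {
    rmultinom(1, 200, rep(1 / 8, 8))[, 1] +
      rmultinom(1, 200, c(rep(0, 6), 0.5, 0.5))[, 1]
  })
  b <- subcloneChannelBoundaries(counts, nBoot = 3000L, seed = 16)
  wide <- b
  wide$upper <- b$upper + 20L
  eNarrow <- estimateBackgroundExposure(p, b$centroidTotal, b, seed = 17)
  eWide <- estimateBackgroundExposure(p, b$centroidTotal, wide, seed = 17)
  expect_gte(as.integer(eWide), as.integer(eNarrow))
})

test_that("signature extraction obeys its exact algebra", {
  # e_p = 0: the signature is the normalised centroid
  counts <- rbind(matrix(c(10, 30, 20, 40), nrow = 2), matrix(0, 6, 2))
  p <- SignatureProfile(c(1, rep(0, 7)), "indel")
  ex <- extractSignature(counts, p, backgroundExposure = 0)
  centroid <- rowMeans(counts)
  expect_equal(unname(profileWeights(extractedSignature(ex))),
               unname(centroid / sum(centroid)), tolerance = 1e-9)

  # disjoint supports: exact recovery of the knockout component
  bg <- c(0.5, 0.5, rep(0, 6))
  ko <- c(0, 0, 0.25, 0.75, rep(0, 4))
  mix <- 400 * bg + 100 * ko
  counts2 <- matrix(round(mix), ncol = 1)
  ex2 <- extractSignature(counts2, SignatureProfile(bg, "indel"),
                          backgroundExposure = 400)
  expect_equal(unname(profileWeights(extractedSignature(ex2))),
               ko, tolerance = 1e-9)
  expect_identical(backgroundExposure(ex2) + knockoutExposure(ex2),
                   ex2@centroidTotal)

  # zero knockout exposure is an explicit error
  expect_error(extractSignature(counts2, SignatureProfile(bg, "indel"),
                                backgroundExposure = 500),
               "no knockout exposure")
  expect_error(extractSignature(counts2, SignatureProfile(bg, "indel"),
                                backgroundExposure = 501),
               "exceeds")
})

test_that("mutation rate per division is plain arithmetic", {
  expect_identical(mutationsPerDivision(360, 36), 10)
  expect_identical(mutationsPerDivision(0, 36), 0)
  expect_equal(mutationsPerDivision(100, 18),
               2 * mutationsPerDivision(100, 36), tolerance = 1e-12)
  expect_error(mutationsPerDivision(10, 0), "positive")
})

test_that("end-to-end extraction recovers a planted signature", {
  cfg <- simulationConfig("substitution", knockoutExposure = 1200,
                          backgroundMean = 1200, seed = 18L)
  sim <- simulateCatalogs(cfg)
  ex <- extractKnockoutSignature(sim$subclones, sim$parental, seed = 19,
                                 search = "coarse")
  truth <- profileWeights(knockoutProfile("mmr"))
  got <- profileWeights(extractedSignature(ex))
  expect_gt(cosineSimilarity(got, truth), 0.9)
  expect_identical(backgroundExposure(ex) + knockoutExposure(ex),
                   ex@centroidTotal)
})
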