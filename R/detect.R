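#' Bootstrap configuration for the spectrum-shift test
#'
#' Bundles the resampling sizes of [spectrumShiftTest()]. Defaults follow
#' the published workflow: 7000 bootstrap replicates per parental clone
#' (9 clones pooled into one shared 63,000-replicate cloud), 9000 per
#' subclone, centroid draws of 7 replicates from the parental pool and 9
#' from the subclone pool, 10,000 centroid-distance samples, and alpha 0.01.
#' The draw sizes are deliberately kept as printed (7 from the parental
#' pool, 9 from the subclone pool) even though they look swapped relative
#' to the group sizes; both are configurable.
#'
#' @param nRepsPerParental,nRepsPerSubclone Bootstrap replicates generated
#'   per parental clone / per subclone.
#' @param nDrawParental,nDrawSubclone Replicates drawn from each pool per
#'   centroid-distance sample.
#' @param nDistanceSamples Number of centroid-distance samples forming each
#'   threshold distribution.
#' @param alpha Significance level for the distance thresholds and the
#'   count-elevation call.
#' @param seed Optional integer seed making the test deterministic.
#' @return A validated list of class `"BootstrapConfig"`.
#' @export
bootstrapConfig <- function(nRepsPerParental = 7000L,
                            nRepsPerSubclone = 9000L,
                            nDrawParental = 7L,
                            nDrawSubclone = 9L,
                            nDistanceSamples = 10000L,
                            alpha = 0.01,
                            seed = NULL) {
  config <- list(
    nRepsPerParental = as.integer(nRepsPerParental),
    nRepsPerSubclone = as.integer(nRepsPerSubclone),
    nDrawParental = as.integer(nDrawParental),
    nDrawSubclone = as.integer(nDrawSubclone),
    nDistanceSamples = as.integer(nDistanceSamples),
    alpha = alpha,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  counts <- unlist(config[1:5])
  if (any(is.na(counts)) || any(counts <= 0L)) {
    stop("all bootstrap sizes must be positive")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1")
  }
  structure(config, class = "BootstrapConfig")
}

#' Normalise a channel-count vector to proportions
#'
#' @param counts Non-negative numeric vector with positive total.
#' @return A vector summing to 1.
#' @examples
#' normalizeProfile(c(2, 2, 0, 0))
#' @export
normalizeProfile <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot <= 0) stop("cannot normalize an all-zero count vector")
  counts / tot
}

#' Distance between two mutation spectra
#'
#' The Frobenius (Euclidean) norm of the difference between the two
#' normalised profiles — or between the raw count vectors when
#' `normalized = FALSE`, available for sensitivity analysis. Normalised
#' distance makes spectra comparable across samples with different burdens.
#'
#' @param a,b Channel-count vectors over the same taxonomy.
#' @param normalized Compare unit-sum proportions (default) or raw counts.
#' @return Non-negative scalar; zero iff the (normalised) profiles are equal.
#' @examples
#' profileDistance(c(1, 0), c(0, 1))  # sqrt(2)
#' @export
profileDistance <- function(a, b, normalized = TRUE) {
  if (length(a) != length(b)) stop("profiles must share a taxonomy")
  if (normalized) {
    a <- normalizeProfile(a)
    b <- normalizeProfile(b)
  }
  sqrt(sum((a - b)^2))
}

#' Multinomial bootstrap replicates of one sample
#'
#' Each replicate is a multinomial draw whose size equals the sample's total
#' mutation count and whose channel probabilities are the sample's observed
#' proportions, so the expected frequency of each mutation type is its
#' probability in the clone multiplied by the total count; replicate totals
#' equal the original total exactly.
#'
#' @param counts Channel-count vector with positive total.
#' @param nReps Number of replicates.
#' @param seed Optional seed.
#' @return Integer matrix, channels x `nReps`.
#' @export
bootstrapProfiles <- function(counts, nReps, seed = NULL) {
  tot <- sum(counts)
  if (tot <= 0) stop("cannot bootstrap a zero-total sample")
  withSeed(seed, {
    reps <- stats::rmultinom(nReps, tot, normalizeProfile(counts))
    rownames(reps) <- names(counts)
    reps
  })
}

# Centroid of a counts matrix: mean of the normalised columns.
profileCentroid <- function(counts) {
  rowMeans(normalizeColumns(asCountsMatrix(counts)))
}

# Pool of normalised bootstrap replicates over all samples of a catalog.
bootstrapPool <- function(counts, nRepsPerSample) {
  cols <- lapply(seq_len(ncol(counts)), function(i) {
    normalizeColumns(bootstrapProfiles(counts[, i], nRepsPerSample))
  })
  do.call(cbind, cols)
}

# Distribution of distances between bootstrap-draw centroids and the
# original centroid, plus its empirical upper-alpha threshold (floor rank).
centroidDistanceNull <- function(pool, centroid, nDraw, nDistanceSamples,
                                 alpha) {
  n <- ncol(pool)
  if (nDraw > n) stop("draw size exceeds pool size")
  d <- vapply(seq_len(nDistanceSamples), function(j) {
    idx <- sample.int(n, nDraw)
    sqrt(sum((rowMeans(pool[, idx, drop = FALSE]) - centroid)^2))
  }, 0)
  rank <- max(1L, floor((1 - alpha) * nDistanceSamples))
  list(distribution = d, threshold = sort(d)[rank])
}

#' Precompute the pooled parental bootstrap null
#'
#' Builds the shared parental bootstrap cloud once: every parental clone
#' contributes `nRepsPerParental` multinomial replicates to one pool (all
#' knockouts' parental clones jointly), from which `nDistanceSamples`
#' centroids of `nDrawParental` replicates are drawn and their distances to
#' the original parental centroid collected. The resulting threshold
#' (`d_pc` at the upper alpha quantile) is global, so it can be reused
#' across every knockout's [spectrumShiftTest()].
#'
#' @param parental [MutationCatalog] (or counts matrix) of parental clones;
#'   at least 2 samples, all with positive totals.
#' @param config A [bootstrapConfig()].
#' @return A list of class `"ParentalBootstrapNull"` with elements
#'   `centroid`, `distribution`, `threshold` and `alpha`.
#' @export
parentalBootstrapNull <- function(parental, config = bootstrapConfig()) {
  counts <- asCountsMatrix(parental)
  if (ncol(counts) < 2L) stop("at least 2 parental samples are required")
  withSeed(config$seed, {
    centroid <- profileCentroid(counts)
    pool <- bootstrapPool(counts, config$nRepsPerParental)
    null <- centroidDistanceNull(pool, centroid, config$nDrawParental,
                                 config$nDistanceSamples, config$alpha)
    structure(
      list(centroid = centroid, distribution = null$distribution,
           threshold = null$threshold, alpha = config$alpha),
      class = "ParentalBootstrapNull"
    )
  })
}

#' Test a knockout's subclones for a mutation-spectrum shift
#'
#' Step 1 of the knockout-signature workflow. Bootstrap clouds are generated
#' around the parental clones (shared across knockouts, see
#' [parentalBootstrapNull()]) and around the knockout's subclones; the
#' distance `d_ps` between the original parental and subclone centroids is
#' compared against the upper-alpha quantiles of both clouds'
#' centroid-distance distributions. The spectrum is called shifted only when
#' `d_ps` strictly exceeds both thresholds; ties are non-shifted.
#'
#' @param parental [MutationCatalog] (or counts matrix) of parental clones.
#' @param subclones [MutationCatalog] (or counts matrix) of the knockout's
#'   subclones; at least 2 samples, all totals positive.
#' @param config A [bootstrapConfig()].
#' @param parentalNull Optional precomputed [parentalBootstrapNull()];
#'   when supplied, its alpha must match the config and the parental cloud
#'   is not recomputed.
#' @return A [ShiftTestResult-class].
#' @export
spectrumShiftTest <- function(parental, subclones,
                              config = bootstrapConfig(),
                              parentalNull = NULL) {
  subCounts <- asCountsMatrix(subclones)
  if (ncol(subCounts) < 2L) stop("at least 2 subclones are required")
  withSeed(config$seed, {
    if (is.null(parentalNull)) {
      parentalNull <- parentalBootstrapNull(parental, bootstrapConfig(
        nRepsPerParental = config$nRepsPerParental,
        nRepsPerSubclone = config$nRepsPerSubclone,
        nDrawParental = config$nDrawParental,
        nDrawSubclone = config$nDrawSubclone,
        nDistanceSamples = config$nDistanceSamples,
        alpha = config$alpha
      ))
    } else if (!identical(parentalNull$alpha, config$alpha)) {
      stop("parentalNull was computed at alpha ", parentalNull$alpha,
           ", config requests ", config$alpha)
    }
    subCentroid <- profileCentroid(subCounts)
    subPool <- bootstrapPool(subCounts, config$nRepsPerSubclone)
    subNull <- centroidDistanceNull(subPool, subCentroid,
                                    config$nDrawSubclone,
                                    config$nDistanceSamples, config$alpha)
    dPS <- sqrt(sum((parentalNull$centroid - subCentroid)^2))
    new("ShiftTestResult",
        dPS = dPS,
        dPCThreshold = parentalNull$threshold,
        dSCThreshold = subNull$threshold,
        alpha = config$alpha,
        shifted = dPS > parentalNull$threshold && dPS > subNull$threshold,
        dPCDistribution = parentalNull$distribution,
        dSCDistribution = subNull$distribution)
  })
}

#' Test a knockout's subclones for an elevated mutation count
#'
#' Step 2 of the workflow. The per-subclone de novo totals of all knockouts
#' whose spectra were NOT shifted form the baseline pool — the expected
#' burden when a knockout has no effect. Bootstrap aggregates are built by
#' summing `length(targetTotals)` draws (with replacement) from that pool;
#' the p-value is the add-one estimator
#' \eqn{(1 + \#\{aggregate \ge observed\}) / (1 + n_{boot})}, so it is never
#' exactly zero.
#'
#' @param targetTotals Per-subclone de novo totals of the knockout under
#'   test.
#' @param baselineTotals Per-subclone totals pooled from all non-shifted
#'   knockouts; must be non-empty.
#' @param nBoot Number of bootstrap aggregates.
#' @param seed Optional seed.
#' @return A [CountTestResult-class].
#' @export
countElevationTest <- function(targetTotals, baselineTotals, nBoot = 10000L,
                               seed = NULL) {
  if (length(baselineTotals) == 0L) {
    stop("empty baseline pool: no knockout without a spectrum shift is ",
         "available; supply an external baseline of per-subclone totals")
  }
  nTarget <- length(targetTotals)
  if (nTarget == 0L) stop("targetTotals must be non-empty")
  withSeed(seed, {
    draws <- matrix(sample(baselineTotals, nTarget * nBoot, replace = TRUE),
                    nrow = nTarget)
    agg <- colSums(draws)
    observed <- sum(targetTotals)
    p <- (1 + sum(agg >= observed)) / (1 + nBoot)
    new("CountTestResult",
        observed = observed,
        pValue = p,
        nBoot = as.integer(nBoot),
        nTarget = as.integer(nTarget),
        baselineQuantiles = stats::quantile(
          agg, c(0.025, 0.25, 0.5, 0.75, 0.975)))
  })
}

#' Combine the shift and count tests into a knockout call
#'
#' A knockout is determined to generate a mutational signature for a
#' mutation class only when its spectrum is shifted AND its count-elevation
#' p-value is strictly below `alpha`. A detectable spectrum shift without a
#' clear count increase — or a count increase with a p-value at the
#' threshold — is conservatively called negative, with the reason recorded.
#'
#' @param shift A [ShiftTestResult-class].
#' @param count A [CountTestResult-class] computed on the same mutation
#'   class.
#' @param alpha Significance level (default 0.01).
#' @param knockout,mutationClass Labels carried into the call.
#' @return A [KnockoutCall-class].
#' @export
callKnockout <- function(shift, count, alpha = 0.01,
                         knockout = NA_character_,
                         mutationClass = NA_character_) {
  if (!is(shift, "ShiftTestResult")) stop("shift must be a ShiftTestResult")
  if (!is(count, "CountTestResult")) stop("count must be a CountTestResult")
  shifted <- isShifted(shift)
  p <- pValue(count)
  has <- shifted && p < alpha
  reason <- if (has) {
    "spectrum shifted and count elevated"
  } else if (!shifted && p < alpha) {
    "count elevated but no spectrum shift"
  } else if (shifted) {
    sprintf("spectrum shifted but no count elevation (p = %.4g)", p)
  } else {
    "no spectrum shift, no count elevation"
  }
  new("KnockoutCall",
      knockout = as.character(knockout),
      mutationClass = as.character(mutationClass),
      shifted = shifted,
      countPValue = p,
      alpha = alpha,
      hasSignature = has,
      reason = reason)
}
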