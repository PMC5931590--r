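#' Pooled parental mean profile (the background signature)
#'
#' The background mutational spectrum \eqn{\bar P_p} is the channel-wise sum
#' of all parental-clone counts divided by the grand total — i.e. pooling
#' weights each clone by its mutation burden rather than averaging
#' per-clone proportions.
#'
#' @param parental [MutationCatalog] (or counts matrix/vector) of parental
#'   clones; pooled total must be positive.
#' @return A [SignatureProfile-class].
#' @export
parentalMeanProfile <- function(parental) {
  counts <- asCountsMatrix(parental)
  pooled <- rowSums(counts)
  if (sum(pooled) <= 0) stop("pooled parental total is zero")
  mutationClass <- if (is(parental, "MutationCatalog")) {
    mutationClass(parental)
  } else {
    classFromChannelCount(nrow(counts))
  }
  SignatureProfile(pooled / sum(pooled), mutationClass)
}

classFromChannelCount <- function(k) {
  hit <- vapply(mutationClasses(), function(cl) channelCount(cl) == k, NA)
  if (!any(hit)) stop("cannot infer mutation class from ", k, " channels")
  mutationClasses()[which(hit)[1L]]
}

#' Per-channel bootstrap boundaries of the subclone centroid
#'
#' Bootstraps the subclone centroid — multinomial draws of size equal to the
#' rounded mean subclone total with probabilities equal to the centroid
#' proportions — and returns per-channel empirical confidence bounds at
#' `ciLevel` (99\% by default: quantiles at (1-ci)/2 and 1-(1-ci)/2).
#' `pooling = "per-subclone"` instead bootstraps each subclone at its own
#' total and pools all replicates, which widens the bounds by the
#' between-subclone variation.
#'
#' @param subclones [MutationCatalog] (or counts matrix) of subclones.
#' @param nBoot Number of bootstrap replicates.
#' @param ciLevel Central confidence level of the per-channel bounds.
#' @param seed Optional seed.
#' @param pooling `"centroid"` (default) or `"per-subclone"`.
#' @return A list of class `"ChannelBoundaries"`: integer vectors `lower`
#'   and `upper` (one entry per channel, `lower <= upper`), plus
#'   `centroidTotal`, `centroidProportions` and `ciLevel`.
#' @export
subcloneChannelBoundaries <- function(subclones, nBoot = 10000L,
                                      ciLevel = 0.99, seed = NULL,
                                      pooling = c("centroid",
                                                  "per-subclone")) {
  pooling <- match.arg(pooling)
  counts <- asCountsMatrix(subclones)
  if (ncol(counts) < 1L) stop("subclones must be non-empty")
  totals <- colSums(counts)
  centroidTotal <- round(mean(totals))
  centroidCounts <- rowMeans(counts)
  if (centroidTotal <= 0 || sum(centroidCounts) <= 0) {
    stop("zero centroid total")
  }
  prob <- centroidCounts / sum(centroidCounts)
  lowerQ <- (1 - ciLevel) / 2
  withSeed(seed, {
    reps <- if (pooling == "centroid") {
      stats::rmultinom(nBoot, centroidTotal, prob)
    } else {
      perSample <- max(1L, ceiling(nBoot / ncol(counts)))
      do.call(cbind, lapply(seq_len(ncol(counts)), function(i) {
        bootstrapProfiles(counts[, i], perSample)
      }))
    }
    lower <- apply(reps, 1L, stats::quantile, probs = lowerQ, type = 1)
    upper <- apply(reps, 1L, stats::quantile, probs = 1 - lowerQ, type = 1)
    structure(
      list(lower = as.integer(lower), upper = as.integer(upper),
           centroidTotal = centroidTotal, centroidProportions = prob,
           ciLevel = ciLevel),
      class = "ChannelBoundaries"
    )
  })
}

#' Estimate the background exposure by iterative quantile comparison
#'
#' Starting from the assumption of no knockout signature — the background
#' exposure \eqn{e_p} equals the subclone centroid total — the candidate
#' exposure is reduced step by step. At each candidate, `nProfiles`
#' multinomial background profiles of size \eqn{e_p} are drawn from the
#' background signature \eqn{\bar P_p} and compared channel-by-channel
#' against the subclone boundaries; the first (largest) candidate with at
#' least `acceptMin` accepted profiles is returned as the final background
#' exposure. If no candidate is ever accepted the function returns 0 with a
#' warning.
#'
#' Under the default `boundaryRule = "upper"` a profile is accepted when no
#' channel count exceeds its upper boundary: the background may not exceed
#' the subclone spectrum anywhere, while undershooting is expected wherever
#' the knockout process contributes. The strict two-sided rule
#' (`boundaryRule = "both"`: every channel inside `[lower, upper]`) is also
#' available, but degenerates to 0 whenever the knockout signature occupies
#' channels in which the background has essentially no mass — background
#' profiles can never reach the lower bounds of knockout-dominated channels
#' (see the package vignette).
#'
#' The profiles drawn for a candidate exposure depend only on `seed` and the
#' candidate value (a per-candidate substream), so `search = "coarse"` — a
#' geometric descent followed by unit-step refinement over the last
#' bracket, intended for large totals — returns the same exposure as pure
#' unit stepping.
#'
#' @param backgroundProfile [SignatureProfile-class] (or weight vector)
#'   \eqn{\bar P_p}.
#' @param centroidTotal Subclone centroid total (starting exposure).
#' @param boundaries A `"ChannelBoundaries"` object from
#'   [subcloneChannelBoundaries()].
#' @param nProfiles Bootstrap background profiles drawn per candidate.
#' @param acceptMin Accepted profiles required to stop.
#' @param step Decrement per iteration; must be positive.
#' @param seed Optional seed.
#' @param search `"unit"` (decrement by `step` as printed) or `"coarse"`.
#' @param boundaryRule `"upper"` (envelope, default) or `"both"`
#'   (strict two-sided).
#' @return Integer exposure \eqn{e_p} with attributes `iterations`
#'   (candidates evaluated) and `acceptanceFraction` (accepted share of the
#'   final candidate's profiles).
#' @export
estimateBackgroundExposure <- function(backgroundProfile, centroidTotal,
                                       boundaries, nProfiles = 100L,
                                       acceptMin = 5L, step = 1L,
                                       seed = NULL,
                                       search = c("unit", "coarse"),
                                       boundaryRule = c("upper", "both")) {
  search <- match.arg(search)
  boundaryRule <- match.arg(boundaryRule)
  if (step <= 0) stop("step must be positive")
  prob <- asWeights(backgroundProfile)
  lower <- boundaries$lower
  upper <- boundaries$upper
  if (length(prob) != length(upper)) {
    stop("profile and boundaries disagree on channel count")
  }
  start <- as.integer(round(centroidTotal))
  if (start <= 0) stop("centroidTotal must be positive")
  baseSeed <- if (is.null(seed)) sample.int(2147483646L, 1L)
              else as.integer(seed)
  K <- length(prob)
  iterations <- 0L
  evaluate <- function(e) {
    iterations <<- iterations + 1L
    withSeed(deriveSeed(baseSeed, e), {
      profiles <- stats::rmultinom(nProfiles, e, prob)
      ok <- colSums(profiles <= upper) == K
      if (boundaryRule == "both") {
        ok <- ok & colSums(profiles >= lower) == K
      }
      sum(ok)
    })
  }
  finish <- function(e, nAccept) {
    structure(as.integer(e),
              iterations = iterations,
              acceptanceFraction = nAccept / nProfiles)
  }
  scan <- function(from, to) {
    e <- from
    while (e >= to) {
      nAccept <- evaluate(e)
      if (nAccept >= acceptMin) return(finish(e, nAccept))
      e <- e - as.integer(step)
    }
    NULL
  }
  if (search == "unit") {
    hit <- scan(start, 1L)
    if (!is.null(hit)) return(hit)
  } else {
    prev <- NULL
    e <- start
    while (e >= 1L) {
      nAccept <- evaluate(e)
      if (nAccept >= acceptMin) {
        # refine: the acceptance boundary lies in (e, prev); rescan it at
        # unit resolution so the result matches pure unit stepping
        if (!is.null(prev) && prev - step > e) {
          hit <- scan(prev - as.integer(step), e + 1L)
          if (!is.null(hit)) return(hit)
        }
        return(finish(e, nAccept))
      }
      prev <- e
      e <- e - max(as.integer(step), as.integer(round(0.02 * e)))
    }
    # coarse descent exhausted without acceptance: confirm at unit steps
    if (!is.null(prev)) {
      hit <- scan(prev - as.integer(step), 1L)
      if (!is.null(hit)) return(hit)
    }
  }
  warning("no candidate background exposure satisfied the boundary ",
          "criterion; returning 0")
  finish(0L, 0L)
}

#' Extract the knockout signature
#'
#' Step 3 of the workflow: with the background exposure \eqn{e_p} fixed, the
#' knockout signature is the residual of the subclone centroid,
#' \eqn{P_{ko} \approx (\bar M_s - e_p \bar P_p) / e_{ko}}. Negative
#' residual channels (where the background subtraction overshoots) are
#' clipped to zero and the result renormalised to unit sum. The knockout
#' exposure is \eqn{e_{ko} = } centroid total \eqn{- e_p}, exactly.
#'
#' @param subclones [MutationCatalog] (or counts matrix) of the knockout's
#'   subclones.
#' @param backgroundProfile [SignatureProfile-class] \eqn{\bar P_p}.
#' @param backgroundExposure The estimated \eqn{e_p} (see
#'   [estimateBackgroundExposure()]); must not exceed the centroid total,
#'   and must leave a positive knockout exposure.
#' @return An [ExtractionResult-class].
#' @export
extractSignature <- function(subclones, backgroundProfile,
                             backgroundExposure) {
  counts <- asCountsMatrix(subclones)
  prob <- asWeights(backgroundProfile)
  centroidTotal <- round(mean(colSums(counts)))
  centroidCounts <- rowMeans(counts)
  # keep the centroid on the exposure scale used by the estimator
  centroidCounts <- centroidCounts * centroidTotal / sum(centroidCounts)
  eP <- as.integer(backgroundExposure)
  if (eP > centroidTotal) {
    stop("backgroundExposure exceeds the centroid total")
  }
  eKO <- centroidTotal - eP
  if (eKO == 0) {
    stop("no knockout exposure; extraction undefined ",
         "(the knockout call should have gated this)")
  }
  residual <- centroidCounts - eP * prob
  residual[residual < 0] <- 0
  if (sum(residual) <= 0) {
    stop("residual spectrum is empty after background subtraction")
  }
  mutationClass <- if (is(subclones, "MutationCatalog")) {
    mutationClass(subclones)
  } else {
    classFromChannelCount(nrow(counts))
  }
  iterations <- attr(backgroundExposure, "iterations")
  acceptance <- attr(backgroundExposure, "acceptanceFraction")
  new("ExtractionResult",
      backgroundExposure = as.numeric(eP),
      knockoutExposure = as.numeric(eKO),
      centroidTotal = as.numeric(centroidTotal),
      signature = SignatureProfile(residual / sum(residual), mutationClass),
      iterations = if (is.null(iterations)) 0L else as.integer(iterations),
      acceptanceFraction = if (is.null(acceptance)) NA_real_
                           else acceptance)
}

#' Full extraction convenience wrapper
#'
#' Runs [subcloneChannelBoundaries()], [estimateBackgroundExposure()] and
#' [extractSignature()] in sequence for one knockout.
#'
#' @param subclones [MutationCatalog] of the knockout's subclones.
#' @param parental [MutationCatalog] of the parental clones (pooled into
#'   \eqn{\bar P_p} via [parentalMeanProfile()]).
#' @param nBoot,ciLevel,pooling Passed to [subcloneChannelBoundaries()].
#' @param nProfiles,acceptMin,step,search,boundaryRule Passed to
#'   [estimateBackgroundExposure()].
#' @param seed Optional seed controlling both stages.
#' @return An [ExtractionResult-class].
#' @export
extractKnockoutSignature <- function(subclones, parental, nBoot = 10000L,
                                     ciLevel = 0.99, nProfiles = 100L,
                                     acceptMin = 5L, step = 1L,
                                     seed = NULL,
                                     search = c("unit", "coarse"),
                                     boundaryRule = c("upper", "both"),
                                     pooling = c("centroid",
                                                 "per-subclone")) {
  background <- parentalMeanProfile(parental)
  boundaries <- subcloneChannelBoundaries(
    subclones, nBoot = nBoot, ciLevel = ciLevel,
    seed = if (is.null(seed)) NULL else deriveSeed(seed, 1L),
    pooling = match.arg(pooling)
  )
  eP <- estimateBackgroundExposure(
    background, boundaries$centroidTotal, boundaries,
    nProfiles = nProfiles, acceptMin = acceptMin, step = step,
    seed = if (is.null(seed)) NULL else deriveSeed(seed, 2L),
    search = match.arg(search), boundaryRule = match.arg(boundaryRule)
  )
  extractSignature(subclones, background, eP)
}

#' Knockout mutations per cell division
#'
#' Converts a knockout exposure (a per-subclone average, since the exposure
#' is estimated on the subclone centroid) into a rate per cell division.
#' The clones in this experimental design are cultured for about one month,
#' i.e. roughly 36 divisions at a ~20 h doubling time.
#'
#' @param knockoutExposure \eqn{e_{ko}} (mutations attributed to the
#'   knockout per subclone).
#' @param divisions Number of cell divisions over the culture period
#'   (default 36).
#' @return Mutations per division.
#' @examples
#' mutationsPerDivision(360, 36)  # 10
#' @export
mutationsPerDivision <- function(knockoutExposure, divisions = 36) {
  if (divisions <= 0) stop("divisions must be positive")
  knockoutExposure / divisions
}
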