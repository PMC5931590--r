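#' MutationCatalog: per-sample channel counts for one mutation class
#'
#' A `MutationCatalog` holds the channel-count vectors of a set of samples
#' (parental clones and/or subclones) for one mutation class. It extends
#' [SummarizedExperiment::SummarizedExperiment] with a `"counts"` assay whose
#' rows are the class's channels in canonical order (see [channelLabels()])
#' and whose column metadata records each sample's `role`
#' (\code{"parental"} or \code{"subclone"}) and `knockout` label.
#'
#' @param counts Non-negative integer matrix, channels x samples. Rows must
#'   be in canonical channel order; rownames are set (and checked) against
#'   [channelLabels()].
#' @param mutationClass One of [mutationClasses()].
#' @param role Character vector (recycled): \code{"parental"} or
#'   \code{"subclone"}.
#' @param knockout Character vector (recycled) naming the knockout each
#'   sample belongs to; `NA` for wild-type/parental backgrounds.
#' @param x A `MutationCatalog`.
#' @return `MutationCatalog()` returns a validated object. `channelCounts()`
#'   returns the counts matrix, `sampleTotals()` its column sums,
#'   `sampleRoles()` and `knockoutLabels()` the per-sample metadata,
#'   `mutationClass()` the class name.
#' @examples
#' m <- matrix(rpois(16, 5), nrow = 8,
#'             dimnames = list(channelLabels("indel"), c("P1", "S1")))
#' cat <- MutationCatalog(m, "indel", role = c("parental", "subclone"))
#' sampleTotals(cat)
#' @aliases MutationCatalog
#' @export MutationCatalog
#' @exportClass MutationCatalog
setClass("MutationCatalog",
  contains = "SummarizedExperiment",
  representation(mutationClass = "character")
)

MutationCatalog <- function(counts, mutationClass,
                            role = "subclone", knockout = NA_character_) {
  mutationClass <- matchMutationClass(mutationClass)
  labels <- channelLabels(mutationClass)
  if (is.null(dim(counts))) {
    counts <- matrix(counts, ncol = 1L)
  }
  counts <- as.matrix(counts)
  if (nrow(counts) != length(labels)) {
    stop("counts must have ", length(labels), " rows for class '",
         mutationClass, "', got ", nrow(counts))
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- labels
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  }
  role <- rep_len(as.character(role), ncol(counts))
  knockout <- rep_len(as.character(knockout), ncol(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(role = role, knockout = knockout,
                                   row.names = colnames(counts))
  )
  new("MutationCatalog", se, mutationClass = mutationClass)
}

setValidity("MutationCatalog", function(object) {
  msg <- character(0)
  if (length(object@mutationClass) != 1L ||
      !object@mutationClass %in% mutationClasses()) {
    return("mutationClass must be one of substitution/indel/rearrangement")
  }
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'counts' is missing")
  }
  counts <- SummarizedExperiment::assay(object, "counts")
  labels <- channelLabels(object@mutationClass)
  if (!identical(rownames(counts), labels)) {
    msg <- c(msg, "rownames must equal the canonical channel labels, in order")
  }
  if (any(!isWholeNumber(counts)) || any(counts < 0)) {
    msg <- c(msg, "counts must be non-negative whole numbers")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("role", "knockout") %in% colnames(cd))) {
    msg <- c(msg, "colData must have 'role' and 'knockout' columns")
  } else if (!all(cd$role %in% c("parental", "subclone"))) {
    msg <- c(msg, "role must be 'parental' or 'subclone'")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname MutationCatalog-class
#' @export
setMethod("mutationClass", "MutationCatalog", function(x) x@mutationClass)

#' @rdname MutationCatalog-class
#' @export
setMethod("channelCounts", "MutationCatalog", function(x) {
  SummarizedExperiment::assay(x, "counts")
})

#' @rdname MutationCatalog-class
#' @export
setMethod("sampleRoles", "MutationCatalog", function(x) {
  stats::setNames(SummarizedExperiment::colData(x)$role, colnames(x))
})

#' @rdname MutationCatalog-class
#' @export
setMethod("knockoutLabels", "MutationCatalog", function(x) {
  stats::setNames(SummarizedExperiment::colData(x)$knockout, colnames(x))
})

#' @rdname MutationCatalog-class
#' @export
setMethod("sampleTotals", "MutationCatalog", function(x) {
  colSums(channelCounts(x))
})

setMethod("show", "MutationCatalog", function(object) {
  cat("MutationCatalog:", object@mutationClass,
      sprintf("(%d channels x %d samples)\n", nrow(object), ncol(object)))
  roles <- table(sampleRoles(object))
  cat("  roles:", paste(names(roles), roles, sep = "=", collapse = ", "), "\n")
  tot <- sampleTotals(object)
  cat("  totals:", paste(utils::head(paste0(names(tot), "=", tot), 8L),
                         collapse = ", "),
      if (length(tot) > 8L) "...\n" else "\n")
})

#' SignatureProfile: a non-negative, unit-sum channel weight vector
#'
#' Represents a mutational signature (or any spectrum) over the channels of
#' one mutation class. Weights are non-negative and sum to one (within 1e-9);
#' the constructor renormalises its input.
#'
#' @param weights Non-negative numeric vector of length
#'   `channelCount(mutationClass)`, in canonical channel order (names, if
#'   present, are checked).
#' @param mutationClass One of [mutationClasses()].
#' @param x A `SignatureProfile`.
#' @return `SignatureProfile()` returns a validated object;
#'   `profileWeights()` its named weight vector; `mutationClass()` the class.
#' @examples
#' p <- SignatureProfile(rep(1, 8), "indel")
#' sum(profileWeights(p))
#' @aliases SignatureProfile
#' @export SignatureProfile
#' @exportClass SignatureProfile
setClass("SignatureProfile",
  representation(mutationClass = "character", weights = "numeric")
)

SignatureProfile <- function(weights, mutationClass) {
  mutationClass <- matchMutationClass(mutationClass)
  labels <- channelLabels(mutationClass)
  if (length(weights) != length(labels)) {
    stop("weights must have length ", length(labels), " for class '",
         mutationClass, "'")
  }
  if (!is.null(names(weights)) && !identical(names(weights), labels)) {
    stop("weight names do not match the canonical channel labels")
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be finite and non-negative")
  }
  if (sum(weights) <= 0) stop("weights must not all be zero")
  w <- weights / sum(weights)
  names(w) <- labels
  new("SignatureProfile", mutationClass = mutationClass, weights = w)
}

setValidity("SignatureProfile", function(object) {
  labels <- channelLabels(object@mutationClass)
  w <- object@weights
  if (!identical(names(w), labels)) {
    return("weights must be named by the canonical channel labels")
  }
  if (any(w < 0)) return("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) return("weights must sum to 1 within 1e-9")
  TRUE
})

#' @rdname SignatureProfile-class
#' @export
setMethod("profileWeights", "SignatureProfile", function(x) x@weights)

#' @rdname SignatureProfile-class
#' @export
setMethod("mutationClass", "SignatureProfile", function(x) x@mutationClass)

setMethod("show", "SignatureProfile", function(object) {
  w <- sort(object@weights, decreasing = TRUE)
  cat("SignatureProfile:", object@mutationClass, "\n  top channels:",
      paste(utils::head(paste0(names(w), "=", signif(w, 3)), 5L),
            collapse = ", "), "\n")
})

#' ShiftTestResult: outcome of the bootstrap spectrum-shift test
#'
#' Holds the observed parental-to-subclone centroid distance `dPS`, the
#' empirical upper-alpha thresholds of the parental (`dPCThreshold`) and
#' subclone (`dSCThreshold`) bootstrap centroid-distance distributions, the
#' full distributions, and the shift decision
#' (`dPS > dPCThreshold && dPS > dSCThreshold`, strict).
#'
#' @param x A `ShiftTestResult`.
#' @seealso [spectrumShiftTest()]
#' @aliases ShiftTestResult
#' @exportClass ShiftTestResult
setClass("ShiftTestResult",
  representation(
    dPS = "numeric",
    dPCThreshold = "numeric",
    dSCThreshold = "numeric",
    alpha = "numeric",
    shifted = "logical",
    dPCDistribution = "numeric",
    dSCDistribution = "numeric"
  )
)

setValidity("ShiftTestResult", function(object) {
  if (object@dPCThreshold < 0 || object@dSCThreshold < 0) {
    return("thresholds must be non-negative")
  }
  expect <- object@dPS > object@dPCThreshold && object@dPS > object@dSCThreshold
  if (!identical(object@shifted, expect)) {
    return("shifted flag inconsistent with thresholds")
  }
  TRUE
})

#' @rdname ShiftTestResult-class
#' @export
setMethod("isShifted", "ShiftTestResult", function(x) x@shifted)

setMethod("show", "ShiftTestResult", function(object) {
  cat(sprintf(
    "ShiftTestResult: d_ps = %.4g vs d_pc_%s = %.4g, d_sc_%s = %.4g -> %s\n",
    object@dPS, format(object@alpha), object@dPCThreshold,
    format(object@alpha), object@dSCThreshold,
    if (object@shifted) "SHIFTED" else "not shifted"
  ))
})

#' CountTestResult: outcome of the bootstrap count-elevation test
#'
#' Holds the observed aggregate de novo mutation count of a knockout's
#' subclones, summary quantiles of the bootstrap baseline-aggregate
#' distribution, and the add-one bootstrap p-value
#' \eqn{p = (1 + \#\{aggregate \ge observed\}) / (1 + n_{boot})}.
#'
#' @param x A `CountTestResult`.
#' @seealso [countElevationTest()]
#' @aliases CountTestResult
#' @exportClass CountTestResult
setClass("CountTestResult",
  representation(
    observed = "numeric",
    pValue = "numeric",
    nBoot = "integer",
    nTarget = "integer",
    baselineQuantiles = "numeric"
  )
)

setValidity("CountTestResult", function(object) {
  if (object@pValue < 0 || object@pValue > 1) return("pValue must be in [0, 1]")
  TRUE
})

#' @rdname CountTestResult-class
#' @export
setMethod("pValue", "CountTestResult", function(x) x@pValue)

setMethod("show", "CountTestResult", function(object) {
  cat(sprintf(
    "CountTestResult: observed aggregate = %g over %d subclones, p = %.4g\n",
    object@observed, object@nTarget, object@pValue
  ))
})

#' KnockoutCall: combined decision for one knockout and mutation class
#'
#' A knockout is called to have a mutational signature for a class only when
#' its spectrum is shifted AND its count-elevation p-value is strictly below
#' alpha. A shift without count elevation (or the converse) yields
#' `hasSignature = FALSE` with the reason recorded.
#'
#' @param x A `KnockoutCall`.
#' @seealso [callKnockout()]
#' @aliases KnockoutCall
#' @exportClass KnockoutCall
setClass("KnockoutCall",
  representation(
    knockout = "character",
    mutationClass = "character",
    shifted = "logical",
    countPValue = "numeric",
    alpha = "numeric",
    hasSignature = "logical",
    reason = "character"
  )
)

setValidity("KnockoutCall", function(object) {
  expect <- object@shifted && object@countPValue < object@alpha
  if (!identical(object@hasSignature, expect)) {
    return("hasSignature must equal shifted AND countPValue < alpha")
  }
  TRUE
})

#' @rdname KnockoutCall-class
#' @export
setMethod("hasSignature", "KnockoutCall", function(x) x@hasSignature)

#' @rdname KnockoutCall-class
#' @export
setMethod("isShifted", "KnockoutCall", function(x) x@shifted)

#' @rdname KnockoutCall-class
#' @export
setMethod("pValue", "KnockoutCall", function(x) x@countPValue)

#' @rdname KnockoutCall-class
#' @export
setMethod("mutationClass", "KnockoutCall", function(x) x@mutationClass)

setMethod("show", "KnockoutCall", function(object) {
  cat(sprintf(
    "KnockoutCall: %s [%s] shifted=%s, count p=%.4g, alpha=%g -> %s (%s)\n",
    object@knockout, object@mutationClass, object@shifted,
    object@countPValue, object@alpha,
    if (object@hasSignature) "SIGNATURE" else "no signature", object@reason
  ))
})

#' ExtractionResult: background/knockout exposures and extracted signature
#'
#' Holds the estimated background exposure \eqn{e_p}, the knockout exposure
#' \eqn{e_{ko} = } centroid total \eqn{- e_p} (the identity holds exactly),
#' the extracted knockout signature, and diagnostics of the iterative
#' exposure search (candidate iterations used, acceptance fraction at stop).
#'
#' @param x An `ExtractionResult`.
#' @seealso [extractSignature()], [estimateBackgroundExposure()]
#' @aliases ExtractionResult
#' @exportClass ExtractionResult
setClass("ExtractionResult",
  representation(
    backgroundExposure = "numeric",
    knockoutExposure = "numeric",
    centroidTotal = "numeric",
    signature = "SignatureProfile",
    iterations = "integer",
    acceptanceFraction = "numeric"
  )
)

setValidity("ExtractionResult", function(object) {
  if (object@knockoutExposure < 0) return("knockoutExposure must be >= 0")
  if (object@backgroundExposure + object@knockoutExposure !=
      object@centroidTotal) {
    return("backgroundExposure + knockoutExposure must equal centroidTotal")
  }
  TRUE
})

#' @rdname ExtractionResult-class
#' @export
setMethod("backgroundExposure", "ExtractionResult",
          function(x) x@backgroundExposure)

#' @rdname ExtractionResult-class
#' @export
setMethod("knockoutExposure", "ExtractionResult", function(x) x@knockoutExposure)

#' @rdname ExtractionResult-class
#' @export
setMethod("extractedSignature", "ExtractionResult", function(x) x@signature)

setMethod("show", "ExtractionResult", function(object) {
  cat(sprintf(
    "ExtractionResult: e_p = %g, e_ko = %g (centroid total %g), %d iterations\n",
    object@backgroundExposure, object@knockoutExposure,
    object@centroidTotal, object@iterations
  ))
  show(object@signature)
})
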