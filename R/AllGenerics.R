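#' @rdname MutationCatalog-class
#' @export
setGeneric("mutationClass", function(x) standardGeneric("mutationClass"))

#' @rdname MutationCatalog-class
#' @export
setGeneric("channelCounts", function(x) standardGeneric("channelCounts"))

#' @rdname MutationCatalog-class
#' @export
setGeneric("sampleRoles", function(x) standardGeneric("sampleRoles"))

#' @rdname MutationCatalog-class
#' @export
setGeneric("knockoutLabels", function(x) standardGeneric("knockoutLabels"))

#' @rdname MutationCatalog-class
#' @export
setGeneric("sampleTotals", function(x) standardGeneric("sampleTotals"))

#' @rdname SignatureProfile-class
#' @export
setGeneric("profileWeights", function(x) standardGeneric("profileWeights"))

#' @rdname ShiftTestResult-class
#' @export
setGeneric("isShifted", function(x) standardGeneric("isShifted"))

#' @rdname CountTestResult-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname KnockoutCall-class
#' @export
setGeneric("hasSignature", function(x) standardGeneric("hasSignature"))

#' @rdname ExtractionResult-class
#' @export
setGeneric("backgroundExposure", function(x) standardGeneric("backgroundExposure"))

#' @rdname ExtractionResult-class
#' @export
setGeneric("knockoutExposure", function(x) standardGeneric("knockoutExposure"))

#' @rdname ExtractionResult-class
#' @export
setGeneric("extractedSignature", function(x) standardGeneric("extractedSignature"))
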