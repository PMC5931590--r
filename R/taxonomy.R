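#' Mutation channel taxonomies
#'
#' Three fixed channel taxonomies are used throughout the package, one per
#' mutation class:
#' \describe{
#'   \item{substitution}{96 channels: 6 pyrimidine substitution types
#'     (C>A, C>G, C>T, T>A, T>C, T>G) times 4 possible 5' flanking bases
#'     times 4 possible 3' flanking bases, written e.g. \code{"T[C>A]T"}.
#'     Purine-reference mutations are reverse complemented before labelling.}
#'   \item{indel}{8 channels: 1 bp insertion; >=2 bp insertion; 2 bp and
#'     >=3 bp microhomology-mediated deletions; 1 bp and >=2 bp
#'     repeat-mediated deletions; other deletions; complex indels.}
#'   \item{rearrangement}{10 channels: deletions, inversions and tandem
#'     duplications each split into 1-10 kb, 10 kb-1 Mb and >1 Mb size bins,
#'     plus translocations.}
#' }
#'
#' The label vectors returned here are the canonical channel order used in
#' every catalog, signature and output file written by this package.
#'
#' @param mutationClass One of \code{"substitution"}, \code{"indel"},
#'   \code{"rearrangement"}.
#' @return `channelLabels()` returns a character vector of channel labels in
#'   canonical order; `channelCount()` its length (96, 8 or 10);
#'   `mutationClasses()` the three class names.
#' @examples
#' channelCount("indel")
#' head(channelLabels("substitution"))
#' @export
channelLabels <- function(mutationClass) {
  mutationClass <- matchMutationClass(mutationClass)
  switch(mutationClass,
    substitution = .substitutionChannels,
    indel = .indelChannels,
    rearrangement = .rearrangementChannels
  )
}

#' @rdname channelLabels
#' @export
channelCount <- function(mutationClass) {
  length(channelLabels(mutationClass))
}

#' @rdname channelLabels
#' @export
mutationClasses <- function() c("substitution", "indel", "rearrangement")

matchMutationClass <- function(mutationClass) {
  match.arg(mutationClass, mutationClasses())
}

.substitutionTypes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.bases <- c("A", "C", "G", "T")

.substitutionChannels <- local({
  out <- character(0)
  for (type in .substitutionTypes) {
    for (five in .bases) {
      for (three in .bases) {
        out <- c(out, paste0(five, "[", type, "]", three))
      }
    }
  }
  out
})

.indelChannels <- c(
  "1bp_insertion",
  "2bp+_insertion",
  "2bp_mh_deletion",
  "3bp+_mh_deletion",
  "1bp_repeat_deletion",
  "2bp+_repeat_deletion",
  "other_deletion",
  "complex"
)

.svClasses <- c("deletion", "inversion", "tandem-duplication", "translocation")
.svBins <- c("1-10kb", "10kb-1Mb", ">1Mb")

.rearrangementChannels <- c(
  paste("deletion", .svBins, sep = "_"),
  paste("inversion", .svBins, sep = "_"),
  paste("tandem-duplication", .svBins, sep = "_"),
  "translocation"
)
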