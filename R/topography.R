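#' Assign substitutions to transcriptional or replicative strands
#'
#' Every substitution is first flipped to its pyrimidine representation
#' (see [classifySubstitutions()]); annotation labels are given on the +
#' strand of the reference, so the strand call is adjusted accordingly —
#' e.g. a G>C mutation inside a + strand gene is the pyrimidine C>G on the
#' - strand, whose template is the + strand, making it \emph{transcribed}.
#' Concretely: in transcription mode a record whose pyrimidine
#' representation lies on the same strand as the gene is
#' \code{"untranscribed"} (the template strand carries the complement), and
#' \code{"transcribed"} otherwise. In replication mode the track's
#' leading/lagging orientation (declared relative to the + strand) is kept
#' for pyrimidine-on-plus records and swapped for flipped records. Records
#' outside any annotated interval, or under conflicting overlapping
#' annotations, are \code{"unassigned"}.
#'
#' @param records Substitution record `data.frame` (`chrom`, `pos`, `ref`,
#'   `alt`); an optional `sample` column is carried through.
#' @param track A [GenomicRanges::GRanges] with a `label` metadata column
#'   (see [readDomainTrack()]): `"+"`/`"-"` in transcription mode,
#'   `"leading"`/`"lagging"` in replication mode.
#' @param mode `"transcription"` or `"replication"`.
#' @return The input `data.frame` with added columns `pyrType` (one of the
#'   six pyrimidine substitution types, e.g. `"C>T"`) and `strandLabel`.
#' @export
assignStrand <- function(records, track,
                         mode = c("transcription", "replication")) {
  mode <- match.arg(mode)
  vocab <- if (mode == "transcription") c("+", "-")
           else c("leading", "lagging")
  label <- as.character(S4Vectors::mcols(track)$label)
  if (is.null(label) || !all(label %in% vocab)) {
    stop("track labels must all be in {",
         paste(vocab, collapse = ", "), "} for mode '", mode, "'")
  }
  n <- nrow(records)
  ref <- toupper(records$ref)
  alt <- toupper(records$alt)
  flip <- ref %in% c("A", "G")
  pyrRef <- ifelse(flip, complementBase(ref), ref)
  pyrAlt <- ifelse(flip, complementBase(alt), alt)
  records$pyrType <- paste0(pyrRef, ">", pyrAlt)
  strandLabel <- rep("unassigned", n)
  if (n > 0L) {
    sites <- GenomicRanges::GRanges(
      records$chrom, IRanges::IRanges(records$pos, records$pos))
    hits <- GenomicRanges::findOverlaps(sites, track)
    hitLabels <- split(label[S4Vectors::subjectHits(hits)],
                       S4Vectors::queryHits(hits))
    for (q in names(hitLabels)) {
      uniq <- unique(hitLabels[[q]])
      if (length(uniq) != 1L) next  # conflicting annotations: unassigned
      i <- as.integer(q)
      if (mode == "transcription") {
        pyrStrand <- if (flip[i]) "-" else "+"
        strandLabel[i] <- if (pyrStrand == uniq) "untranscribed"
                          else "transcribed"
      } else {
        strandLabel[i] <- if (!flip[i]) uniq
                          else setdiff(vocab, uniq)
      }
    }
  }
  records$strandLabel <- strandLabel
  records
}

#' Strand asymmetry of mutation classes across subclones
#'
#' For each of the six pyrimidine substitution types, counts assigned
#' mutations on the two strands per subclone and tests the per-subclone
#' pairs with a two-sided paired t-test. The fold change is the ratio of
#' strand means: lagging/leading in replication mode,
#' transcribed/untranscribed in transcription mode. A strand with zero
#' counts in every subclone leaves the fold undefined (reported `NA` with
#' `pValue = NA`).
#'
#' @param assignments Output of [assignStrand()] with a `sample` column;
#'   at least 2 subclones are required for the t-test.
#' @param mode `"transcription"` or `"replication"` (must match the
#'   assignments).
#' @return A `data.frame` with one row per mutation type: per-strand mean
#'   counts, `fold` and `pValue`.
#' @export
strandAsymmetryTest <- function(assignments,
                                mode = c("transcription", "replication")) {
  mode <- match.arg(mode)
  if (!"sample" %in% colnames(assignments)) {
    stop("assignments must carry a 'sample' column")
  }
  samples <- unique(assignments$sample)
  if (length(samples) < 2L) {
    stop("at least 2 subclones are required for the paired t-test")
  }
  strands <- if (mode == "replication") c("leading", "lagging")
             else c("untranscribed", "transcribed")
  numerator <- strands[2L]  # lagging / transcribed on top
  out <- lapply(.substitutionTypes, function(type) {
    sub <- assignments[assignments$pyrType == type &
                         assignments$strandLabel %in% strands, ,
                       drop = FALSE]
    c1 <- vapply(samples, function(s) {
      sum(sub$sample == s & sub$strandLabel == strands[1L])
    }, 0)
    c2 <- vapply(samples, function(s) {
      sum(sub$sample == s & sub$strandLabel == strands[2L])
    }, 0)
    fold <- if (mean(c1) > 0 && mean(c2) > 0) mean(c2) / mean(c1)
            else NA_real_
    d <- c2 - c1
    p <- if (is.na(fold)) {
      NA_real_
    } else if (all(d == 0)) {
      1  # identical strand counts in every subclone: no evidence at all
    } else if (stats::var(d) == 0) {
      NA_real_  # constant nonzero difference: t statistic undefined
    } else {
      stats::t.test(c2, c1, paired = TRUE)$p.value
    }
    df <- data.frame(type = type, m1 = mean(c1), m2 = mean(c2),
                     fold = fold, pValue = p, nSamples = length(samples),
                     stringsAsFactors = FALSE)
    names(df)[2:3] <- paste0("mean", toupper(substr(strands, 1, 1)),
                             substr(strands, 2, nchar(strands)))
    df
  })
  out <- do.call(rbind, out)
  attr(out, "numerator") <- numerator
  out
}

#' Mutation density across replication-timing deciles
#'
#' Counts mutations per replication-timing decile (deciles 1-10, early to
#' late), divides by the genomic size of each decile, and rescales so the
#' mean density over the ten deciles is 1 — the size-corrected, normalised
#' density profile.
#'
#' @param records Record `data.frame` with `chrom` and `pos` columns.
#' @param track A [GenomicRanges::GRanges] timing track with labels
#'   `"1"`..`"10"` (see [readDomainTrack()]); every decile must be present
#'   with positive genomic length.
#' @return A `data.frame` with columns `decile`, `count`, `length` and
#'   `density` (mean 1 within 1e-9).
#' @export
timingDensity <- function(records, track) {
  label <- as.character(S4Vectors::mcols(track)$label)
  deciles <- as.character(1:10)
  if (!all(deciles %in% label)) {
    stop("timing track must cover deciles 1-10; missing: ",
         paste(setdiff(deciles, label), collapse = ", "))
  }
  lengths <- vapply(deciles, function(d) {
    sum(GenomicRanges::width(track[label == d]))
  }, 0)
  if (any(lengths <= 0)) stop("decile with zero genomic length")
  sites <- GenomicRanges::GRanges(
    records$chrom, IRanges::IRanges(records$pos, records$pos))
  hits <- GenomicRanges::findOverlaps(sites, track)
  hitLabel <- label[S4Vectors::subjectHits(hits)]
  counts <- vapply(deciles, function(d) sum(hitLabel == d), 0)
  if (sum(counts) == 0) stop("no records overlap the timing track")
  density <- counts / lengths
  density <- density / mean(density)
  data.frame(decile = 1:10, count = counts, length = lengths,
             density = density, row.names = NULL)
}
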