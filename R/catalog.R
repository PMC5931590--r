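#' Classify substitutions into 96 trinucleotide channels
#'
#' Every substitution is represented in pyrimidine context: when the
#' reference base is a purine (A/G), the mutation and its trinucleotide
#' context are reverse complemented before labelling, so a G>T at plus-strand
#' context AGA becomes \code{"T[C>A]T"}. Classifying a substitution and its
#' reverse-complement representation therefore yields the same channel.
#'
#' @param records Substitution record `data.frame` (`chrom`, `pos`, `ref`,
#'   `alt`).
#' @param reference A [Biostrings::DNAStringSet] (see [readReference()]).
#' @param naOnError If `TRUE`, records whose context contains N (or whose
#'   flanks fall outside the contig) yield `NA` instead of an error; used by
#'   [buildCatalog()], which excludes them and logs them in its reject
#'   report.
#' @return Character vector of channel labels (one per record).
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "AAGAA"))
#' classifySubstitutions(
#'   data.frame(chrom = "chr1", pos = 3, ref = "G", alt = "T"), ref)
#' @export
classifySubstitutions <- function(records, reference, naOnError = FALSE) {
  n <- nrow(records)
  if (n == 0L) return(character(0))
  out <- rep(NA_character_, n)
  reasons <- rep(NA_character_, n)
  for (chrom in unique(records$chrom)) {
    idx <- which(records$chrom == chrom)
    if (!chrom %in% names(reference)) {
      if (naOnError) {
        reasons[idx] <- "unknown contig"
        next
      }
      stop("unknown contig: ", chrom)
    }
    seqStr <- as.character(reference[[chrom]])
    len <- nchar(seqStr)
    pos <- records$pos[idx]
    offEdge <- pos < 2L | pos > len - 1L
    if (any(offEdge) && !naOnError) {
      stop("flanking bases unavailable for position(s) ",
           paste(pos[offEdge], collapse = ", "), " on ", chrom)
    }
    reasons[idx[offEdge]] <- "flank outside contig"
    ok <- idx[!offEdge]
    if (!length(ok)) next
    ctx <- toupper(substring(seqStr, records$pos[ok] - 1L,
                             records$pos[ok] + 1L))
    ref <- toupper(records$ref[ok])
    alt <- toupper(records$alt[ok])
    mid <- substr(ctx, 2L, 2L)
    mismatch <- mid != ref
    if (any(mismatch & mid %in% .bases) && !naOnError) {
      stop("REF does not match the reference base at position(s) ",
           paste(records$pos[ok][mismatch & mid %in% .bases],
                 collapse = ", "), " on ", chrom)
    }
    hasN <- grepl("N", ctx, fixed = TRUE)
    reasons[ok[hasN]] <- "N in trinucleotide context"
    reasons[ok[mismatch & !hasN]] <- "REF mismatch with reference"
    use <- !hasN & !mismatch
    if (!any(use)) next
    ctxU <- ctx[use]
    refU <- ref[use]
    altU <- alt[use]
    flip <- refU %in% c("A", "G")
    ctxU[flip] <- revcomp(ctxU[flip])
    refU[flip] <- complementBase(refU[flip])
    altU[flip] <- complementBase(altU[flip])
    out[ok[use]] <- paste0(substr(ctxU, 1L, 1L), "[", refU, ">", altU, "]",
                           substr(ctxU, 3L, 3L))
  }
  if (!naOnError && anyNA(out)) {
    stop("unclassifiable substitution record(s): ",
         paste(unique(stats::na.omit(reasons)), collapse = "; "))
  }
  attr(out, "reasons") <- reasons
  out
}

#' Classify indels into 8 junction-aware channels
#'
#' Insertions are labelled by length (1 bp vs >=2 bp). Deletions are
#' left-aligned against the reference, then classified by the sequence at
#' the 3' junction of the deletion:
#' \itemize{
#'   \item \emph{repeat-mediated} when the deleted motif has at least one
#'     full additional copy immediately 3' of the deletion (split 1 bp vs
#'     >=2 bp) — the slippage pattern of repeat tracts;
#'   \item otherwise \emph{microhomology-mediated} when the 5' end of the
#'     deleted sequence shares at least 1 bp (but less than full-length
#'     identity) with the sequence immediately 3' of the deletion; only
#'     defined for deletions of >=2 bp, split 2 bp vs >=3 bp;
#'   \item otherwise \emph{other deletion} (this includes every
#'     non-repeat 1 bp deletion: no 1 bp microhomology channel exists).
#' }
#' Records where both alleles are longer than 1 bp are \emph{complex}.
#' Repeat-mediated takes precedence over microhomology, making the deletion
#' taxonomy total and deterministic.
#'
#' @param records Indel record `data.frame` (`chrom`, `pos`, `ref`, `alt`,
#'   VCF left-anchored style).
#' @param reference A [Biostrings::DNAStringSet].
#' @param scanWindow Bases of 3' context guaranteed to be scanned; must be at
#'   least twice the longest deletion (only the immediate junction copy is
#'   examined).
#' @param naOnError See [classifySubstitutions()].
#' @return Character vector of channel labels.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "TCAAG"))
#' # deletion of A where the next base is A: 1 bp repeat-mediated
#' classifyIndels(
#'   data.frame(chrom = "chr1", pos = 2, ref = "CA", alt = "C"), ref)
#' @export
classifyIndels <- function(records, reference, scanWindow = 100L,
                           naOnError = FALSE) {
  n <- nrow(records)
  if (n == 0L) return(character(0))
  out <- rep(NA_character_, n)
  reasons <- rep(NA_character_, n)
  fail <- function(i, reason) {
    if (!naOnError) stop(reason, " (record ", i, ")")
    reasons[i] <<- reason
  }
  getContig <- contigStringCache(reference)
  contigs <- names(reference)
  contigLens <- vapply(contigs, function(c) length(reference[[c]]), 0L)
  refCol <- toupper(records$ref)
  altCol <- toupper(records$alt)
  chromCol <- as.character(records$chrom)
  posCol <- as.integer(records$pos)
  nRef <- nchar(refCol)
  nAlt <- nchar(altCol)
  for (i in seq_len(n)) {
    ref <- refCol[i]
    if (nRef[i] > 1L && nAlt[i] > 1L) {
      out[i] <- "complex"
      next
    }
    if (nAlt[i] > nRef[i]) {  # insertion
      out[i] <- if (nAlt[i] - nRef[i] == 1L) "1bp_insertion"
                else "2bp+_insertion"
      next
    }
    # deletion
    chrom <- chromCol[i]
    if (!chrom %in% contigs) {
      fail(i, "unknown contig")
      next
    }
    seqStr <- getContig(chrom)
    len <- contigLens[[chrom]]
    pos <- posCol[i]
    d <- nRef[i] - 1L
    if (scanWindow < 2L * d) {
      stop("scanWindow (", scanWindow, ") must be at least twice the ",
           "deleted length (", d, ")")
    }
    if (pos < 1L || pos + d > len) {
      fail(i, "deletion outside contig")
      next
    }
    obs <- substring(seqStr, pos, pos + d)  # cache is uppercase
    if (obs != ref) {
      fail(i, "REF mismatch with reference")
      next
    }
    # left-align: shift while the base before the anchor equals the last
    # deleted base (the deletion is then representable one base left)
    while (pos > 1L &&
           substr(seqStr, pos, pos) ==
           substr(seqStr, pos + d, pos + d)) {
      pos <- pos - 1L
    }
    motif <- substring(seqStr, pos + 1L, pos + d)
    if (pos + 2L * d > len) {
      fail(i, "3' junction context outside contig")
      next
    }
    following <- substring(seqStr, pos + d + 1L, pos + 2L * d)
    if (grepl("N", paste0(motif, following), fixed = TRUE)) {
      fail(i, "N in junction context")
      next
    }
    if (following == motif) {
      out[i] <- if (d == 1L) "1bp_repeat_deletion" else "2bp+_repeat_deletion"
    } else if (d >= 2L && lcpLength(motif, following) >= 1L) {
      out[i] <- if (d == 2L) "2bp_mh_deletion" else "3bp+_mh_deletion"
    } else {
      out[i] <- "other_deletion"
    }
  }
  attr(out, "reasons") <- reasons
  out
}

lcpLength <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  k <- 0L
  while (k < n && substr(a, k + 1L, k + 1L) == substr(b, k + 1L, k + 1L)) {
    k <- k + 1L
  }
  k
}

#' Classify rearrangements into 10 size/type channels
#'
#' Translocations (inter-chromosomal records) form one channel regardless of
#' position. Intra-chromosomal records are labelled by `svclass` and the
#' span `pos2 - pos1`, binned as 1-10 kb, 10 kb-1 Mb (exclusive of 10 kb,
#' inclusive of 1 Mb) and >1 Mb. Spans below 1 kb are below typical calling
#' resolution and are rejected (routed to the reject report by
#' [buildCatalog()]) rather than force-binned.
#'
#' @param records Rearrangement record `data.frame` (see
#'   [readRearrangements()]).
#' @param naOnError See [classifySubstitutions()].
#' @return Character vector of channel labels.
#' @export
classifyRearrangements <- function(records, naOnError = FALSE) {
  n <- nrow(records)
  if (n == 0L) return(character(0))
  out <- rep(NA_character_, n)
  reasons <- rep(NA_character_, n)
  inter <- records$chrom1 != records$chrom2
  out[inter] <- "translocation"
  span <- records$pos2 - records$pos1
  tooSmall <- !inter & span < 1000
  if (any(tooSmall) && !naOnError) {
    stop("intra-chromosomal span below 1 kb (record ",
         paste(which(tooSmall), collapse = ", "),
         "): below calling resolution")
  }
  reasons[tooSmall] <- "span below 1 kb"
  use <- !inter & !tooSmall
  bin <- ifelse(span <= 10000, "1-10kb",
                ifelse(span <= 1e6, "10kb-1Mb", ">1Mb"))
  out[use] <- paste(records$svclass[use], bin[use], sep = "_")
  bad <- use & !out %in% .rearrangementChannels
  if (any(bad, na.rm = TRUE)) {
    if (!naOnError) {
      stop("unknown svclass: ",
           paste(unique(records$svclass[which(bad)]), collapse = ", "))
    }
    reasons[which(bad)] <- "unknown svclass"
    out[which(bad)] <- NA_character_
  }
  attr(out, "reasons") <- reasons
  out
}

#' Assemble per-sample channel-count catalogs
#'
#' Classifies each sample's records and counts them over the canonical
#' channels of the mutation class, producing a [MutationCatalog]
#' (the matrices \eqn{M_p} and \eqn{M_s} of the detection workflow, one
#' column per sample). When building a subclone catalog the records are
#' expected to be de novo, i.e. already filtered with [subtractParental()].
#'
#' Unclassifiable records (N in context, flanks outside the contig, spans
#' below 1 kb) are excluded from the counts and collected in the catalog's
#' reject report, so that for every sample the column sum equals the number
#' of classifiable records: `metadata(x)$rejects` is a `data.frame` with
#' columns `sample`, `row` and `reason`.
#'
#' @param recordsBySample Named list of record `data.frame`s, one per
#'   sample; empty samples are allowed and yield zero columns.
#' @param mutationClass One of [mutationClasses()].
#' @param reference A [Biostrings::DNAStringSet]; required for
#'   substitutions and indels.
#' @param role,knockout Per-sample metadata, recycled (see
#'   [MutationCatalog()]).
#' @param scanWindow Passed to [classifyIndels()].
#' @return A [MutationCatalog].
#' @export
buildCatalog <- function(recordsBySample, mutationClass, reference = NULL,
                         role = "subclone", knockout = NA_character_,
                         scanWindow = 100L) {
  mutationClass <- matchMutationClass(mutationClass)
  if (!is.list(recordsBySample) || is.data.frame(recordsBySample)) {
    recordsBySample <- list(sample1 = recordsBySample)
  }
  if (is.null(names(recordsBySample))) {
    names(recordsBySample) <- paste0("sample", seq_along(recordsBySample))
  }
  if (mutationClass != "rearrangement" && is.null(reference)) {
    stop("a reference sequence is required for ", mutationClass, " catalogs")
  }
  labels <- channelLabels(mutationClass)
  rejects <- list()
  counts <- vapply(names(recordsBySample), function(sampleId) {
    records <- recordsBySample[[sampleId]]
    checkRecordShape(records, mutationClass)
    if (nrow(records) == 0L) {
      return(stats::setNames(integer(length(labels)), labels))
    }
    ch <- switch(mutationClass,
      substitution = classifySubstitutions(records, reference,
                                           naOnError = TRUE),
      indel = classifyIndels(records, reference, scanWindow = scanWindow,
                             naOnError = TRUE),
      rearrangement = classifyRearrangements(records, naOnError = TRUE)
    )
    bad <- which(is.na(ch))
    if (length(bad)) {
      rejects[[sampleId]] <<- data.frame(
        sample = sampleId, row = bad,
        reason = attr(ch, "reasons")[bad]
      )
    }
    table(factor(ch, levels = labels))
  }, stats::setNames(integer(length(labels)), labels))
  counts <- matrix(as.integer(counts), nrow = length(labels),
                   dimnames = list(labels, names(recordsBySample)))
  catalog <- MutationCatalog(counts, mutationClass, role = role,
                             knockout = knockout)
  rejects <- if (length(rejects)) do.call(rbind, unname(rejects))
             else data.frame(sample = character(0), row = integer(0),
                             reason = character(0))
  rownames(rejects) <- NULL
  S4Vectors::metadata(catalog)$rejects <- rejects
  catalog
}

checkRecordShape <- function(records, mutationClass) {
  if (!is.data.frame(records)) stop("records must be a data.frame")
  if (mutationClass == "rearrangement") {
    if (!all(c("chrom1", "pos1", "chrom2", "pos2", "svclass") %in%
             colnames(records))) {
      stop("records are not rearrangements: mixed mutation classes?")
    }
    return(invisible(TRUE))
  }
  if (!all(c("chrom", "pos", "ref", "alt") %in% colnames(records))) {
    stop("records lack chrom/pos/ref/alt columns: mixed mutation classes?")
  }
  if (nrow(records)) {
    long <- nchar(records$ref) > 1L | nchar(records$alt) > 1L
    if (mutationClass == "substitution" && any(long)) {
      stop("multi-base alleles in a substitution catalog: ",
           "mixed mutation classes")
    }
    if (mutationClass == "indel" && !all(long)) {
      stop("single-base records in an indel catalog: mixed mutation classes")
    }
  }
  invisible(TRUE)
}

#' Read and write catalog TSV files
#'
#' A catalog file is tab-delimited with channels as rows (first column
#' `channel`, canonical order) and samples as columns; two comment lines
#' (`#role:`, `#knockout:`) carry the per-sample metadata.
#'
#' @param catalog A [MutationCatalog].
#' @param path File path.
#' @return `readCatalog()` returns a [MutationCatalog]; `writeCatalog()`
#'   returns `path` invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#class: ", mutationClass(catalog)),
    paste0("#role: ", paste(sampleRoles(catalog), collapse = "\t")),
    paste0("#knockout: ", paste(knockoutLabels(catalog), collapse = "\t"))
  ), con)
  df <- data.frame(channel = rownames(catalog), channelCounts(catalog),
                   check.names = FALSE)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}

#' @rdname writeCatalog
#' @export
readCatalog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  getMeta <- function(key) {
    ln <- meta[startsWith(meta, paste0("#", key, ":"))]
    if (!length(ln)) return(NULL)
    strsplit(sub(paste0("^#", key, ":\\s*"), "", ln[1L]), "\t")[[1L]]
  }
  mutationClass <- getMeta("class")
  if (is.null(mutationClass)) stop("missing '#class:' line in ", path)
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  labels <- channelLabels(mutationClass)
  if (!identical(as.character(tab$channel), labels)) {
    stop("channel column does not match the canonical ", mutationClass,
         " taxonomy in ", path)
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- labels
  role <- getMeta("role")
  knockout <- getMeta("knockout")
  knockout[knockout == "NA"] <- NA_character_
  MutationCatalog(m, mutationClass,
                  role = if (is.null(role)) "subclone" else role,
                  knockout = if (is.null(knockout)) NA_character_
                             else knockout)
}
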