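#' Read somatic variant records
#'
#' Readers for the three mutation classes. Substitutions and indels are read
#' from VCF 4.x bodies (`dialect = "vcf"`: columns CHROM, POS, ID, REF, ALT,
#' header lines starting with `#` ignored) or from headered TSV files
#' (`dialect = "tsv"`: columns `chrom`, `pos`, `ref`, `alt`).
#' Rearrangements are read from BEDPE-like breakpoint tables with columns
#' `chrom1`, `pos1`, `chrom2`, `pos2` and optionally `svclass`.
#'
#' All coordinates are 1-based inclusive. Malformed rows are rejected with an
#' error naming the offending line: a substitution row whose REF or ALT is
#' not a single A/C/G/T base belongs to the indel reader's domain and vice
#' versa. Rearrangement validation enforces `svclass == "translocation"`
#' exactly when `chrom1 != chrom2`, and `pos2 > pos1` for intra-chromosomal
#' records; inter-chromosomal rows without an `svclass` column become
#' translocations, while unlabelled intra-chromosomal rows are an error.
#'
#' @param path Path to an existing file.
#' @param dialect `"vcf"` or `"tsv"`.
#' @return A `data.frame` of records sorted by position: columns
#'   `chrom`, `pos`, `ref`, `alt` for substitutions and indels, or `chrom1`,
#'   `pos1`, `chrom2`, `pos2`, `svclass` for rearrangements.
#' @examples
#' f <- tempfile(fileext = ".vcf")
#' writeLines(c("##fileformat=VCFv4.2", "chr1\t100\t.\tC\tA"), f)
#' readSubstitutions(f)
#' @export
readSubstitutions <- function(path, dialect = c("vcf", "tsv")) {
  dialect <- match.arg(dialect)
  rows <- readVariantRows(path, dialect)
  validateAllele <- function(x) grepl("^[ACGT]+$", x)
  with(rows, {
    bad <- !validateAllele(ref) | !validateAllele(alt)
    if (any(bad)) {
      stop("invalid REF/ALT allele at line ",
           paste(line[bad], collapse = ", "), " of ", path)
    }
    long <- nchar(ref) != 1L | nchar(alt) != 1L
    if (any(long)) {
      stop("multi-base REF/ALT at line ", paste(line[long], collapse = ", "),
           " of ", path, ": these rows belong to the indel reader")
    }
    same <- ref == alt
    if (any(same)) {
      stop("REF equals ALT at line ", paste(line[same], collapse = ", "),
           " of ", path)
    }
  })
  out <- rows[order(rows$chrom, rows$pos), c("chrom", "pos", "ref", "alt")]
  rownames(out) <- NULL
  out
}

#' @rdname readSubstitutions
#' @export
readIndels <- function(path, dialect = c("vcf", "tsv")) {
  dialect <- match.arg(dialect)
  rows <- readVariantRows(path, dialect)
  with(rows, {
    bad <- !grepl("^[ACGT]+$", ref) | !grepl("^[ACGT]+$", alt)
    if (any(bad)) {
      stop("invalid REF/ALT allele at line ",
           paste(line[bad], collapse = ", "), " of ", path)
    }
    short <- nchar(ref) == 1L & nchar(alt) == 1L
    if (any(short)) {
      stop("single-base REF and ALT at line ",
           paste(line[short], collapse = ", "), " of ", path,
           ": these rows belong to the substitution reader")
    }
    anchored <- substr(ref, 1L, 1L) == substr(alt, 1L, 1L)
    simple <- nchar(ref) == 1L | nchar(alt) == 1L
    if (any(simple & !anchored)) {
      stop("simple indel without a shared anchor base at line ",
           paste(line[simple & !anchored], collapse = ", "), " of ", path)
    }
  })
  out <- rows[order(rows$chrom, rows$pos), c("chrom", "pos", "ref", "alt")]
  rownames(out) <- NULL
  out
}

#' @rdname readSubstitutions
#' @export
readRearrangements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chrom1", "pos1", "chrom2", "pos2")
  if (!all(need %in% colnames(tab))) {
    stop("rearrangement file must have columns ",
         paste(need, collapse = ", "), " (and optionally svclass)")
  }
  line <- seq_len(nrow(tab)) + 1L  # header is line 1
  if (nrow(tab) == 0L) {
    return(data.frame(chrom1 = character(0), pos1 = integer(0),
                      chrom2 = character(0), pos2 = integer(0),
                      svclass = character(0)))
  }
  tab$pos1 <- as.integer(tab$pos1)
  tab$pos2 <- as.integer(tab$pos2)
  if (any(is.na(tab$pos1) | is.na(tab$pos2))) {
    stop("non-integer breakpoint position at line ",
         paste(line[is.na(tab$pos1) | is.na(tab$pos2)], collapse = ", "),
         " of ", path)
  }
  inter <- tab$chrom1 != tab$chrom2
  if (!"svclass" %in% colnames(tab)) {
    tab$svclass <- NA_character_
    tab$svclass[inter] <- "translocation"
    if (any(!inter)) {
      stop("intra-chromosomal rows without an svclass column at line ",
           paste(line[!inter], collapse = ", "), " of ", path)
    }
  }
  unknown <- !tab$svclass %in% .svClasses
  if (any(unknown)) {
    stop("unknown svclass '", paste(unique(tab$svclass[unknown]),
                                    collapse = "', '"),
         "' at line ", paste(line[unknown], collapse = ", "), " of ", path)
  }
  misTrans <- xor(inter, tab$svclass == "translocation")
  if (any(misTrans)) {
    stop("svclass must be 'translocation' exactly for inter-chromosomal ",
         "rows; violated at line ", paste(line[misTrans], collapse = ", "),
         " of ", path)
  }
  misOrder <- !inter & tab$pos2 <= tab$pos1
  if (any(misOrder)) {
    stop("intra-chromosomal records must have pos2 > pos1; violated at line ",
         paste(line[misOrder], collapse = ", "), " of ", path)
  }
  out <- tab[order(tab$chrom1, tab$pos1, tab$chrom2, tab$pos2),
             c("chrom1", "pos1", "chrom2", "pos2", "svclass")]
  rownames(out) <- NULL
  out
}

# Shared line-based VCF/TSV body parser; returns chrom/pos/ref/alt plus the
# 1-based file line number of each row (for error messages).
readVariantRows <- function(path, dialect) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  if (dialect == "vcf") {
    keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
    lines <- lines[keep]
    lineno <- lineno[keep]
    if (length(lines) == 0L) {
      return(data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        line = integer(0)))
    }
    fields <- strsplit(lines, "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 5L)) {
      stop("expected at least 5 VCF columns at line ",
           paste(lineno[nf < 5L], collapse = ", "), " of ", path)
    }
    out <- data.frame(
      chrom = vapply(fields, `[`, "", 1L),
      pos = suppressWarnings(as.integer(vapply(fields, `[`, "", 2L))),
      ref = toupper(vapply(fields, `[`, "", 4L)),
      alt = toupper(vapply(fields, `[`, "", 5L)),
      line = lineno
    )
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% colnames(tab))) {
      stop("TSV dialect requires columns ", paste(need, collapse = ", "))
    }
    out <- data.frame(
      chrom = tab$chrom,
      pos = suppressWarnings(as.integer(tab$pos)),
      ref = toupper(tab$ref),
      alt = toupper(tab$alt),
      line = seq_len(nrow(tab)) + 1L
    )
  }
  bad <- is.na(out$pos) | out$pos < 1L
  if (any(bad)) {
    stop("invalid position at line ", paste(out$line[bad], collapse = ", "),
         " of ", path)
  }
  out
}

#' Write variant records
#'
#' Inverse of the readers in [readSubstitutions()]: substitutions and indels
#' are written as minimal VCF 4.2 (or headered TSV), rearrangements as a
#' BEDPE-like TSV with an `svclass` column. Writing then reading a record
#' set reproduces it exactly.
#'
#' @param records A record `data.frame` as returned by the readers.
#' @param path Output path.
#' @param dialect `"vcf"` or `"tsv"` (substitutions/indels only).
#' @return `path`, invisibly.
#' @export
writeSubstitutions <- function(records, path, dialect = c("vcf", "tsv")) {
  writeSmallVariants(records, path, match.arg(dialect))
}

#' @rdname writeSubstitutions
#' @export
writeIndels <- function(records, path, dialect = c("vcf", "tsv")) {
  writeSmallVariants(records, path, match.arg(dialect))
}

#' @rdname writeSubstitutions
#' @export
writeRearrangements <- function(records, path) {
  utils::write.table(
    records[, c("chrom1", "pos1", "chrom2", "pos2", "svclass")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

writeSmallVariants <- function(records, path, dialect) {
  if (dialect == "vcf") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "##fileformat=VCFv4.2",
      paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                          "FILTER", "INFO"), collapse = "\t"))
    ), con)
    if (nrow(records)) {
      writeLines(paste(records$chrom, records$pos, ".", records$ref,
                       records$alt, ".", ".", ".", sep = "\t"), con)
    }
  } else {
    utils::write.table(records[, c("chrom", "pos", "ref", "alt")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Derive de novo mutations by parental subtraction
#'
#' Removes from a subclone's record set every mutation already present in the
#' parental set. Substitutions and indels match on exact
#' `(chrom, pos, ref, alt)`; rearrangements match when both breakpoints lie
#' within `tolerance` base pairs (same chromosome pair) and the `svclass`
#' agrees. The same operation filters parental clones against the bulk
#' population: pass the bulk set as `parental`. The operation is idempotent.
#'
#' @param records Subclone record `data.frame`.
#' @param parental Parental (or bulk) record `data.frame` of the same
#'   mutation class.
#' @param tolerance Breakpoint matching tolerance in bp for rearrangements
#'   (default 500, the typical breakpoint imprecision of split-read callers);
#'   ignored for substitutions and indels.
#' @return The subclone records with parental matches removed.
#' @examples
#' sub <- data.frame(chrom = "chr1", pos = c(1, 2, 3), ref = "C", alt = "A")
#' par <- data.frame(chrom = "chr1", pos = 2, ref = "C", alt = "A")
#' subtractParental(sub, par)
#' @export
subtractParental <- function(records, parental, tolerance = 500) {
  isRearr <- function(x) "chrom1" %in% colnames(x)
  if (isRearr(records) != isRearr(parental)) {
    stop("cannot mix mutation classes: one record set is rearrangements, ",
         "the other is not")
  }
  if (nrow(records) == 0L || nrow(parental) == 0L) {
    return(records)
  }
  if (!isRearr(records)) {
    key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = "\r")
    out <- records[!key(records) %in% key(parental), , drop = FALSE]
  } else {
    if (tolerance < 0) stop("tolerance must be >= 0")
    matched <- vapply(seq_len(nrow(records)), function(i) {
      r <- records[i, ]
      hit <- parental$chrom1 == r$chrom1 & parental$chrom2 == r$chrom2 &
        parental$svclass == r$svclass &
        abs(parental$pos1 - r$pos1) <= tolerance &
        abs(parental$pos2 - r$pos2) <= tolerance
      any(hit)
    }, NA)
    out <- records[!matched, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read a reference sequence
#'
#' Loads a FASTA file into a [Biostrings::DNAStringSet]; contig names are
#' truncated at the first whitespace. `referenceFetch()` returns the
#' uppercase bases of a 1-based inclusive interval.
#'
#' @param path Path to a FASTA file.
#' @param reference A `DNAStringSet`.
#' @param chrom Contig name.
#' @param start,end 1-based inclusive coordinates.
#' @return `readReference()`: a `DNAStringSet`. `referenceFetch()`: a single
#'   uppercase character string of length `end - start + 1`.
#' @export
readReference <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' @rdname readReference
#' @export
referenceFetch <- function(reference, chrom, start, end) {
  if (!chrom %in% names(reference)) stop("unknown contig: ", chrom)
  len <- length(reference[[chrom]])
  if (start < 1 || end > len || end < start) {
    stop("interval [", start, ", ", end, "] outside contig ", chrom,
         " (length ", len, ")")
  }
  toupper(as.character(reference[[chrom]][start:end]))
}

#' Read an annotation track
#'
#' Reads a BED4 file (column 4 carrying the label) into a
#' [GenomicRanges::GRanges] with a `label` metadata column, converting from
#' BED's 0-based half-open convention to 1-based inclusive coordinates.
#' Labels are validated against the declared vocabulary: gene strand
#' (`"+"`/`"-"`), replication orientation (`"leading"`/`"lagging"`, given
#' relative to the reference + strand), or replication-timing deciles
#' (`"1"`..`"10"`).
#'
#' @param path Path to a BED4 file.
#' @param vocabulary `"strand"`, `"replication"` or `"timing"`, or a
#'   character vector of allowed labels.
#' @return A `GRanges` with a `label` metadata column.
#' @export
readDomainTrack <- function(path, vocabulary = c("strand", "replication",
                                                 "timing")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (length(vocabulary) == 1L &&
      vocabulary %in% c("strand", "replication", "timing")) {
    vocabulary <- switch(vocabulary,
      strand = c("+", "-"),
      replication = c("leading", "lagging"),
      timing = as.character(1:10)
    )
  }
  gr <- rtracklayer::import(path, format = "BED")
  label <- as.character(S4Vectors::mcols(gr)$name)
  if (is.null(label) || any(is.na(label))) {
    stop("BED4 column 4 (label) is required in ", path)
  }
  if (!all(label %in% vocabulary)) {
    stop("labels outside the declared vocabulary in ", path, ": ",
         paste(setdiff(unique(label), vocabulary), collapse = ", "))
  }
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(label = label)
  gr
}

#' Read and write signature catalogs
#'
#' A signature catalog is a tab-delimited channel-by-signature matrix: the
#' first column holds channel labels, the header row signature names. On
#' loading, the channel order is harmonised to this package's canonical
#' order ([channelLabels()]) and each column is renormalised to unit sum; a
#' channel label set that does not exactly match the canonical taxonomy is
#' an error naming the discrepant labels.
#'
#' @param path Path to a tab-delimited catalog.
#' @param mutationClass One of [mutationClasses()].
#' @param catalog Channels-by-signatures numeric matrix with canonical
#'   rownames.
#' @return `readSignatureCatalog()`: a numeric matrix (channels x
#'   signatures, canonical row order, columns summing to 1) with attribute
#'   `mutationClass`.
#' @export
readSignatureCatalog <- function(path, mutationClass) {
  mutationClass <- matchMutationClass(mutationClass)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  labels <- channelLabels(mutationClass)
  chan <- as.character(tab[[1L]])
  missing <- setdiff(labels, chan)
  extra <- setdiff(chan, labels)
  if (length(missing) || length(extra)) {
    stop("channel labels do not match the canonical ", mutationClass,
         " taxonomy",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ",
                                   paste(extra, collapse = ", ")))
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0)) {
    stop("signature weights must be finite and non-negative")
  }
  rownames(m) <- chan
  m <- m[labels, , drop = FALSE]
  tot <- colSums(m)
  if (any(tot <= 0)) {
    stop("signature column(s) with zero total weight: ",
         paste(colnames(m)[tot <= 0], collapse = ", "))
  }
  m <- sweep(m, 2L, tot, "/")
  attr(m, "mutationClass") <- mutationClass
  m
}

#' @rdname readSignatureCatalog
#' @export
writeSignatureCatalog <- function(catalog, path) {
  df <- data.frame(channel = rownames(catalog), catalog,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
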