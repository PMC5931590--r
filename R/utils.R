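# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. A NULL seed evaluates in the session stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single non-missing number or NULL")
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic derived seed, kept inside 32-bit integer range.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + as.numeric(offset) * 1009) %% 2147483646) + 1L
}

# Reverse complement of plain character DNA strings (vectorised).
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), "")
}

complementBase <- function(x) chartr("ACGTN", "TGCAN", x)

# Columns of `m` rescaled to unit sum. Errors on all-zero columns.
normalizeColumns <- function(m, what = "sample") {
  tot <- colSums(m)
  if (any(tot <= 0)) {
    stop("cannot normalize ", what, " with zero total counts (columns: ",
         paste(which(tot <= 0), collapse = ", "), ")")
  }
  sweep(m, 2L, tot, "/")
}

isWholeNumber <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

# Per-contig character cache: converting a DNAStringSet contig to a plain
# string is costly, so classifiers working record-by-record reuse it.
contigStringCache <- function(reference) {
  cache <- new.env(parent = emptyenv())
  function(chrom) {
    if (!chrom %in% names(reference)) stop("unknown contig: ", chrom)
    if (is.null(cache[[chrom]])) {
      cache[[chrom]] <- toupper(as.character(reference[[chrom]]))
    }
    cache[[chrom]]
  }
}

# Counts matrix out of a MutationCatalog or a plain matrix.
asCountsMatrix <- function(x) {
  if (is(x, "MutationCatalog")) {
    return(channelCounts(x))
  }
  if (is.matrix(x)) {
    return(x)
  }
  if (is.numeric(x)) {
    return(matrix(x, ncol = 1L, dimnames = list(names(x), "sample1")))
  }
  stop("expected a MutationCatalog, a counts matrix or a counts vector")
}

# Weight vector out of a SignatureProfile or numeric vector (normalised).
asWeights <- function(x) {
  w <- if (is(x, "SignatureProfile")) profileWeights(x) else x
  if (!is.numeric(w) || any(!is.finite(w)) || any(w < 0)) {
    stop("profile weights must be finite and non-negative")
  }
  if (sum(w) <= 0) stop("profile weights must not all be zero")
  w / sum(w)
}
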