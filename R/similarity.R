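#' Cosine similarity between two spectra
#'
#' \eqn{\cos(u, v) = u \cdot v / (\|u\| \|v\|)}; for non-negative inputs the
#' value lies in [0, 1], reaching 1 only for proportional vectors. The
#' measure is symmetric and invariant to positive rescaling of either
#' argument.
#'
#' @param u,v Numeric vectors of equal length, neither all-zero.
#' @return A scalar.
#' @examples
#' cosineSimilarity(c(1, 1, 0), c(1, 0, 1))  # 0.5
#' @export
cosineSimilarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero vectors")
  sum(u * v) / (nu * nv)
}

#' Compare a signature against a reference catalog
#'
#' Computes the cosine similarity of a query signature to every signature in
#' a reference catalog (e.g. the published human-cancer substitution or
#' rearrangement signature sets) and ranks the matches. All cosines are
#' reported, not just the best match, since runner-up similarities are often
#' informative (several mismatch-repair-deficiency signatures resemble each
#' other).
#'
#' @param signature A [SignatureProfile-class] or weight vector; channel
#'   order must match the catalog's (both are harmonised to canonical order
#'   at load time).
#' @param catalog Channels-by-signatures matrix (see
#'   [readSignatureCatalog()]).
#' @return A `data.frame` with columns `signature` and `cosine`, sorted by
#'   decreasing cosine; ties keep the catalog's column order.
#' @export
compareToCatalog <- function(signature, catalog) {
  w <- if (is(signature, "SignatureProfile")) profileWeights(signature)
       else signature
  if (length(w) != nrow(catalog)) {
    stop("signature has ", length(w), " channels but the catalog has ",
         nrow(catalog))
  }
  if (!is.null(names(w)) && !is.null(rownames(catalog)) &&
      !identical(names(w), rownames(catalog))) {
    stop("channel order mismatch between signature and catalog")
  }
  cosines <- vapply(seq_len(ncol(catalog)), function(j) {
    cosineSimilarity(w, catalog[, j])
  }, 0)
  out <- data.frame(
    signature = colnames(catalog),
    cosine = cosines,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$cosine), , drop = FALSE]  # stable: ties keep order
  rownames(out) <- NULL
  out
}
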