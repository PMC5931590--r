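# Independent oracle for the 96-channel substitution classifier: built on
# Biostrings reverse complementation, separate from the package's own
# string-level implementation.
oracleSubstitutionLabel <- function(ctx, ref, alt) {
  stopifnot(substr(ctx, 2, 2) == ref)
  if (ref %in% c("A", "G")) {
    ctx <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(ctx)))
    ref <- as.character(
      Biostrings::complement(Biostrings::DNAString(ref)))
    alt <- as.character(
      Biostrings::complement(Biostrings::DNAString(alt)))
  }
  paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3))
}


# Independent scripted oracle for deletion classification, written on
# character vectors rather than the package's string scanning.
oracleDeletionLabel <- function(chars, pos, d) {
  while (pos > 1 && chars[pos] == chars[pos + d]) pos <- pos - 1
  motif <- chars[(pos + 1):(pos + d)]
  after <- chars[(pos + d + 1):(pos + 2 * d)]
  if (all(after == motif)) {
    return(if (d == 1) "1bp_repeat_deletion" else "2bp+_repeat_deletion")
  }
  h <- 0
  for (k in seq_len(d)) {
    if (motif[k] == after[k]) h <- h + 1 else break
  }
  if (d >= 2 && h >= 1) {
    return(if (d == 2) "2bp_mh_deletion" else "3bp+_mh_deletion")
  }
  "other_deletion"
}

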