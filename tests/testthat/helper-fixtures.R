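# Shared fixtures, built in code and cached for the duration of a test run.

# The default toy genome (1.2 Mb + 0.3 Mb contigs) is expensive enough to
# build that the files sharing it reuse one instance.
testGenome <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- toyGenome(seed = 42L)
    cached
  }
})

# A reduced bootstrap configuration for fast shift tests in unit tests.
fastBoot <- function(seed = NULL, alpha = 0.01) {
  bootstrapConfig(nRepsPerParental = 500L, nRepsPerSubclone = 500L,
                  nDistanceSamples = 1000L, alpha = alpha, seed = seed)
}

# The reduced sizes prescribed for the large null calibration runs.
calibrationBoot <- function(seed = NULL) {
  bootstrapConfig(nRepsPerParental = 1000L, nRepsPerSubclone = 1000L,
                  nDistanceSamples = 2000L, alpha = 0.01, seed = seed)
}

# Tiny literal reference for hand-checked classifier cases.
literalReference <- function(...) {
  Biostrings::DNAStringSet(c(...))
}

# Write a minimal VCF body and return its path.
writeTempVcf <- function(rows) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               rows), path)
  path
}
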