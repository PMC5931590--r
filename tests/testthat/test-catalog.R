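test_that("substitution classifier matches the enumeration oracle on all 192 cases", {
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(five = bases, ref = bases, three = bases,
                        alt = bases, stringsAsFactors = FALSE)
  combos <- combos[combos$alt != combos$ref, ]
  combos <- combos[!duplicated(combos[c("five", "ref", "three", "alt")]), ]
  expect_identical(nrow(combos), 192L)

  got <- character(nrow(combos))
  want <- character(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    ctx <- paste0(combos$five[i], combos$ref[i], combos$three[i])
    ref <- literalReference(chrT = paste0("T", ctx, "T"))
    rec <- data.frame(chrom = "chrT", pos = 3L, ref = combos$ref[i],
                      alt = combos$alt[i])
    got[i] <- classifySubstitutions(rec, ref)
    want[i] <- oracleSubstitutionLabel(ctx, combos$ref[i], combos$alt[i])
  }
  expect_identical(got, want)
  # the 192 stranded combinations collapse onto the 96 channels, each hit
  # exactly twice
  expect_identical(sort(unique(got)), sort(channelLabels("substitution")))
  expect_true(all(table(got) == 2L))
})

test_that("substitution classification is strand-invariant and errors on N", {
  # G>T at plus-strand context AGA is T[C>A]T after the pyrimidine flip
  ref <- literalReference(chr1 = "TAGAT")
  expect_identical(
    as.character(classifySubstitutions(
      data.frame(chrom = "chr1", pos = 3L, ref = "G", alt = "T"), ref)),
    "T[C>A]T")
  # already-pyrimidine case
  ref2 <- literalReference(chr1 = "TACGT")
  expect_identical(
    as.character(classifySubstitutions(
      data.frame(chrom = "chr1", pos = 3L, ref = "C", alt = "T"), ref2)),
    "A[C>T]G")
  refN <- literalReference(chr1 = "TNCGT")
  rec <- data.frame(chrom = "chr1", pos = 3L, ref = "C", alt = "T")
  expect_error(classifySubstitutions(rec, refN), "N in trinucleotide")
  expect_true(is.na(classifySubstitutions(rec, refN, naOnError = TRUE)))
})

test_that("indel classifier honours the stated junction rules", {
  # deletion of A where the next base is A: 1 bp repeat-mediated
  ref <- literalReference(chr1 = "TCAAG")
  expect_identical(
    as.character(classifyIndels(
      data.frame(chrom = "chr1", pos = 2L, ref = "CA", alt = "C"), ref)),
    "1bp_repeat_deletion")
  # deletion of CAG followed by CAT: 2 bp junction homology, >=3 bp class
  ref <- literalReference(chr1 = "TTCAGCATTT")
  expect_identical(
    as.character(classifyIndels(
      data.frame(chrom = "chr1", pos = 2L, ref = "TCAG", alt = "T"), ref)),
    "3bp+_mh_deletion")
  # had the deletion been shiftable onto a repeat tract, repeat-mediated
  # wins: deleting CAG from TGCAGCATTT left-aligns onto the GCAGCA tract
  refShift <- literalReference(chr1 = "TGCAGCATTT")
  expect_identical(
    as.character(classifyIndels(
      data.frame(chrom = "chr1", pos = 2L, ref = "GCAG", alt = "G"),
      refShift)),
    "2bp+_repeat_deletion")
  # deletion of GT followed by AC: zero homology
  ref <- literalReference(chr1 = "TCGTACTT")
  expect_identical(
    as.character(classifyIndels(
      data.frame(chrom = "chr1", pos = 2L, ref = "CGT", alt = "C"), ref)),
    "other_deletion")
  # insertions by length; complex when both alleles are long
  ref <- literalReference(chr1 = "TTTTTTTT")
  recs <- data.frame(chrom = "chr1", pos = 2L,
                     ref = c("T", "T", "TTT"),
                     alt = c("TA", "TAG", "TGG"))
  expect_identical(as.character(classifyIndels(recs, ref)),
                   c("1bp_insertion", "2bp+_insertion", "complex"))
})

test_that("indel classifier agrees with the scripted oracle on 50 constructed deletions", {
  set.seed(404)
  seq <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
               collapse = "")
  chars <- strsplit(seq, "")[[1]]
  ref <- literalReference(chrO = seq)
  n <- 50L
  pos <- sample(100:2800, n)
  d <- sample(1:4, n, replace = TRUE)
  recs <- data.frame(
    chrom = "chrO", pos = pos,
    ref = vapply(seq_len(n), function(i) {
      paste(chars[pos[i]:(pos[i] + d[i])], collapse = "")
    }, ""),
    alt = chars[pos]
  )
  got <- as.character(classifyIndels(recs, ref))
  want <- vapply(seq_len(n), function(i) {
    oracleDeletionLabel(chars, pos[i], d[i])
  }, "")
  expect_identical(got, want)
})

test_that("rearrangement classifier agrees with a binning oracle on 30 cases", {
  set.seed(7)
  spans <- c(1000L, 9999L, 10000L, 10001L, 999999L, 1000000L, 1000001L,
             sample(1000:2000000, 20))
  sv <- sample(c("deletion", "inversion", "tandem-duplication"),
               length(spans), replace = TRUE)
  intra <- data.frame(chrom1 = "chr1", pos1 = 10L, chrom2 = "chr1",
                      pos2 = 10L + spans, svclass = sv)
  trans <- data.frame(chrom1 = "chr1", pos1 = c(1L, 5e6L, 100L),
                      chrom2 = c("chr2", "chrX", "chr9"),
                      pos2 = c(5000L, 10L, 1L),
                      svclass = "translocation")
  recs <- rbind(intra, trans)
  expect_identical(nrow(recs), 30L)
  got <- classifyRearrangements(recs)
  binOracle <- function(span) {
    if (span <= 10000) "1-10kb" else if (span <= 1e6) "10kb-1Mb" else ">1Mb"
  }
  want <- c(paste(sv, vapply(spans, binOracle, ""), sep = "_"),
            rep("translocation", 3L))
  expect_identical(as.character(got), want)
  # spans below the smallest bin are rejected, not force-binned
  tiny <- data.frame(chrom1 = "chr1", pos1 = 10L, chrom2 = "chr1",
                     pos2 = 500L, svclass = "deletion")
  expect_error(classifyRearrangements(tiny), "below 1 kb")
  expect_true(is.na(classifyRearrangements(tiny, naOnError = TRUE)))
})

test_that("deletion taxonomy is total: every deletion gets exactly one label", {
  set.seed(11)
  seq <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")
  ref <- literalReference(chrP = seq)
  pos <- sample(50:1900, 200, replace = TRUE)
  d <- sample(1:5, 200, replace = TRUE)
  chars <- strsplit(seq, "")[[1]]
  recs <- data.frame(
    chrom = "chrP", pos = pos,
    ref = vapply(seq_along(pos), function(i) {
      paste(chars[pos[i]:(pos[i] + d[i])], collapse = "")
    }, ""),
    alt = chars[pos]
  )
  labels <- classifyIndels(recs, ref)
  delChannels <- c("1bp_repeat_deletion", "2bp+_repeat_deletion",
                   "2bp_mh_deletion", "3bp+_mh_deletion", "other_deletion")
  expect_true(all(labels %in% delChannels))
  # determinism
  expect_identical(as.character(classifyIndels(recs, ref)),
                   as.character(labels))
})

test_that("buildCatalog counts classifiable records and logs the rest", {
  ref <- literalReference(chr1 = "TAGATNCGT")
  # three copies of the same G>T (T[C>A]T after flip), one N-context reject
  recs <- data.frame(chrom = "chr1", pos = c(3L, 3L, 3L, 7L),
                     ref = c("G", "G", "G", "C"),
                     alt = c("T", "T", "T", "A"))
  cat <- buildCatalog(list(s1 = recs), "substitution", reference = ref)
  counts <- channelCounts(cat)[, "s1"]
  expect_identical(unname(counts["T[C>A]T"]), 3L)
  expect_identical(sum(counts), 3L)
  rejects <- S4Vectors::metadata(cat)$rejects
  expect_identical(nrow(rejects), 1L)
  expect_identical(rejects$row, 4L)
  # conservation: records = counted + rejected
  expect_identical(nrow(recs), sum(counts) + nrow(rejects))

  # empty sample gives a zero column
  cat2 <- buildCatalog(list(s1 = recs, empty = recs[0, ]), "substitution",
                       reference = ref)
  expect_identical(sum(channelCounts(cat2)[, "empty"]), 0L)

  # mixed classes are rejected
  expect_error(
    buildCatalog(list(s1 = data.frame(chrom = "chr1", pos = 3L,
                                      ref = "GA", alt = "G")),
                 "substitution", reference = ref),
    "mixed")
})

test_that("catalog proportions of simulated records match the generating profile", {
  # multinomial goodness of fit between drawn channel counts and truth
  tg <- testGenome()
  cfg <- simulationConfig("indel", nParental = 1L, nSubclones = 1L,
                          backgroundMean = 600, seed = 77L)
  sim <- simulateVariantRecords(cfg, tg)
  counts <- rowSums(sim$channelCounts)
  p <- profileWeights(backgroundIndelProfile())
  gof <- suppressWarnings(chisq.test(counts, p = p))
  expect_gt(gof$p.value, 1e-4)
})
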