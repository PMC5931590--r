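test_that("substitution reader maps VCF rows and rejects malformed ones", {
  path <- writeTempVcf(c("chr1\t100\t.\tC\tA", "chr1\t50\t.\tT\tG"))
  recs <- readSubstitutions(path)
  expect_identical(recs,
                   data.frame(chrom = "chr1", pos = c(50L, 100L),
                              ref = c("T", "C"), alt = c("G", "A")))

  empty <- writeTempVcf(character(0))
  expect_identical(nrow(readSubstitutions(empty)), 0L)

  # a multi-base REF belongs to the indel reader; the error names the line
  mixed <- writeTempVcf(c("chr1\t10\t.\tCT\tC"))
  expect_error(readSubstitutions(mixed), "line 3.*indel reader")
  same <- writeTempVcf(c("chr1\t10\t.\tC\tC"))
  expect_error(readSubstitutions(same), "REF equals ALT at line 3")
  expect_error(readSubstitutions(tempfile()), "not found")
})

test_that("indel reader distinguishes deletions, insertions and complex", {
  path <- writeTempVcf(c("chr1\t200\t.\tCA\tC",
                         "chr1\t200\t.\tC\tCAG",
                         "chr1\t200\t.\tCAT\tCGG"))
  recs <- readIndels(path)
  expect_identical(recs$ref, c("CA", "C", "CAT"))
  expect_identical(recs$alt, c("C", "CAG", "CGG"))
  # a pure substitution row is out of this reader's domain
  sub <- writeTempVcf("chr1\t10\t.\tC\tA")
  expect_error(readIndels(sub), "substitution reader")
})

test_that("rearrangement reader enforces the svclass/chromosome contract", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom1\tpos1\tchrom2\tpos2",
               "chr1\t1000\tchr2\t5000"), path)
  recs <- readRearrangements(path)
  expect_identical(recs$svclass, "translocation")

  writeLines(c("chrom1\tpos1\tchrom2\tpos2\tsvclass",
               "chr1\t1000\tchr1\t900\tdeletion"), path)
  expect_error(readRearrangements(path), "pos2 > pos1.*line 2")

  writeLines(c("chrom1\tpos1\tchrom2\tpos2\tsvclass",
               "chr3\t10\tchr3\t100000\ttandem-duplication"), path)
  ok <- readRearrangements(path)
  expect_identical(ok$pos2 - ok$pos1, 99990L)

  writeLines(c("chrom1\tpos1\tchrom2\tpos2\tsvclass",
               "chr1\t10\tchr1\t100000\tbreak"), path)
  expect_error(readRearrangements(path), "unknown svclass")
  writeLines(c("chrom1\tpos1\tchrom2\tpos2",
               "chr1\t10\tchr1\t100000"), path)
  expect_error(readRearrangements(path), "without an svclass")
  writeLines(c("chrom1\tpos1\tchrom2\tpos2\tsvclass",
               "chr1\t10\tchr1\t100000\ttranslocation"), path)
  expect_error(readRearrangements(path), "translocation")
})

test_that("record writers and readers round-trip exactly", {
  recs <- data.frame(chrom = c("chr1", "chr2"), pos = c(11L, 7L),
                     ref = c("C", "T"), alt = c("A", "G"))
  for (dialect in c("vcf", "tsv")) {
    path <- tempfile()
    writeSubstitutions(recs, path, dialect)
    expect_identical(readSubstitutions(path, dialect),
                     recs[order(recs$chrom, recs$pos), ])
  }
  indels <- data.frame(chrom = "chr1", pos = c(5L, 9L),
                       ref = c("CA", "C"), alt = c("C", "CTT"))
  path <- tempfile()
  writeIndels(indels, path)
  expect_identical(readIndels(path), indels)

  rearr <- data.frame(chrom1 = "chr1", pos1 = 1000L, chrom2 = "chr1",
                      pos2 = 500000L, svclass = "inversion")
  path <- tempfile()
  writeRearrangements(rearr, path)
  expect_identical(readRearrangements(path), rearr)
})

test_that("parental subtraction is an exact set difference for point records", {
  sub <- data.frame(chrom = "chr1", pos = c(1L, 2L, 3L),
                    ref = "C", alt = "A")
  par <- data.frame(chrom = "chr1", pos = 2L, ref = "C", alt = "A")
  expect_identical(subtractParental(sub, par)$pos, c(1L, 3L))
  expect_identical(nrow(subtractParental(sub, sub)), 0L)
  # idempotence
  once <- subtractParental(sub, par)
  expect_identical(subtractParental(once, par), once)
  # class mixing is an error
  rearr <- data.frame(chrom1 = "chr1", pos1 = 1L, chrom2 = "chr2",
                      pos2 = 2L, svclass = "translocation")
  expect_error(subtractParental(sub, rearr), "mix")
})

test_that("rearrangement subtraction respects the breakpoint tolerance", {
  sub <- data.frame(chrom1 = "chr1", pos1 = c(10050L, 20500L),
                    chrom2 = "chr1", pos2 = c(60050L, 70500L),
                    svclass = "deletion")
  par <- data.frame(chrom1 = "chr1", pos1 = c(10000L, 20000L),
                    chrom2 = "chr1", pos2 = c(60000L, 70000L),
                    svclass = "deletion")
  # offsets 50 bp and 500 bp against tolerance 100: only the first matches
  kept <- subtractParental(sub, par, tolerance = 100)
  expect_identical(kept$pos1, 20500L)
  # svclass must agree even within tolerance
  par2 <- par; par2$svclass <- "inversion"
  expect_identical(nrow(subtractParental(sub, par2, tolerance = 1000)), 2L)
})

test_that("signature catalog loader harmonises channels and renormalises", {
  labels <- channelLabels("indel")
  m <- matrix(c(rep(0.12, 8), rep(0.125, 8)), ncol = 2,
              dimnames = list(labels, c("SigA", "SigB")))
  path <- tempfile()
  # shuffle rows: loader must restore canonical order
  shuffled <- m[sample(8), , drop = FALSE]
  utils::write.table(data.frame(channel = rownames(shuffled), shuffled),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat <- readSignatureCatalog(path, "indel")
  expect_identical(rownames(cat), labels)
  expect_equal(colSums(cat), c(SigA = 1, SigB = 1), tolerance = 1e-12)
  # column that sums to 0.96 on disk is renormalised to exactly 1
  expect_equal(unname(cat[, "SigA"]), rep(1 / 8, 8), tolerance = 1e-12)

  # missing channel is an error naming the label
  utils::write.table(data.frame(channel = labels[-3], m[-3, ]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSignatureCatalog(path, "indel"), labels[3], fixed = TRUE)
})

test_that("reference fetch returns 1-based inclusive uppercase intervals", {
  ref <- literalReference(chr1 = "acgtACGT")
  expect_identical(referenceFetch(ref, "chr1", 2, 5), "CGTA")
  expect_identical(nchar(referenceFetch(ref, "chr1", 1, 8)), 8L)
  expect_error(referenceFetch(ref, "chr1", 0, 3), "outside")
  expect_error(referenceFetch(ref, "chrX", 1, 2), "unknown contig")
})

test_that("domain track loader validates vocabulary and converts coordinates", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\t+", "chr1\t100\t200\t-"), path)
  gr <- readDomainTrack(path, "strand")
  expect_identical(GenomicRanges::start(gr), c(1L, 101L))
  expect_identical(S4Vectors::mcols(gr)$label, c("+", "-"))
  writeLines("chr1\t0\t100\tforward", path)
  expect_error(readDomainTrack(path, "strand"), "vocabulary")
})
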