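#' Built-in spectra for simulation
#'
#' `defaultBackgroundProfile()` returns the pervasive culture background
#' substitution spectrum observed in clone-based mutagenesis systems: a
#' distinctive C>A/G>T pattern with its tallest peaks at the TCT, GCA, GCT
#' and ACA trinucleotide contexts (in decreasing order), over 50\% of its
#' mass on C>A channels overall, and a small flat remainder elsewhere.
#' `backgroundIndelProfile()` and `backgroundRearrangementProfile()` give
#' matching culture backgrounds for the other classes (indels dominated by
#' 1 bp repeat-mediated deletions; rearrangements by small deletions and
#' tandem duplications).
#'
#' `knockoutProfile()` returns stylised knockout signatures used as
#' simulation ground truth: a mismatch-repair-deficiency-like substitution
#' spectrum (C>T and T>C dominated) and poly-tract 1 bp deletion indel
#' spectrum (`"mmr"`); an exonuclease-loss-like rearrangement spectrum
#' dominated by 10 kb-1 Mb tandem duplications (`"tdup"`); and a
#' crosslink-repair-loss-like profile of microhomology-mediated deletions
#' and short deletions/duplications (`"hrd"`).
#'
#' @param mutationClass One of [mutationClasses()];
#'   `defaultBackgroundProfile()` accepts only `"substitution"`.
#' @param kind Knockout archetype: `"mmr"`, `"tdup"` or `"hrd"`.
#' @return A [SignatureProfile-class].
#' @examples
#' p <- defaultBackgroundProfile()
#' sum(profileWeights(p)[grepl("C>A", names(profileWeights(p)))])  # > 0.5
#' @export
defaultBackgroundProfile <- function(mutationClass = "substitution") {
  if (!identical(mutationClass, "substitution")) {
    stop("defaultBackgroundProfile is defined for the substitution ",
         "taxonomy only; see backgroundIndelProfile()/",
         "backgroundRearrangementProfile()")
  }
  labels <- channelLabels("substitution")
  w <- stats::setNames(rep(0.31 / 80, 96), labels)
  caChannels <- labels[grepl("C>A", labels, fixed = TRUE)]
  w[caChannels] <- 0.025
  w["T[C>A]T"] <- 0.12
  w["G[C>A]A"] <- 0.10
  w["G[C>A]T"] <- 0.09
  w["A[C>A]A"] <- 0.08
  SignatureProfile(w / sum(w), "substitution")
}

#' @rdname defaultBackgroundProfile
#' @export
backgroundIndelProfile <- function() {
  SignatureProfile(
    c(0.15, 0.05, 0.05, 0.08, 0.40, 0.10, 0.12, 0.05), "indel")
}

#' @rdname defaultBackgroundProfile
#' @export
backgroundRearrangementProfile <- function() {
  SignatureProfile(
    c(0.25, 0.15, 0.05, 0.10, 0.05, 0.05, 0.15, 0.10, 0.05, 0.05),
    "rearrangement")
}

#' @rdname defaultBackgroundProfile
#' @export
knockoutProfile <- function(kind = c("mmr", "tdup", "hrd"),
                            mutationClass = "substitution") {
  kind <- match.arg(kind)
  mutationClass <- matchMutationClass(mutationClass)
  labels <- channelLabels(mutationClass)
  if (mutationClass == "substitution") {
    if (kind != "mmr") {
      stop("substitution archetype available for kind = 'mmr' only")
    }
    w <- stats::setNames(rep(0, 96), labels)
    w[grepl("C>T", labels, fixed = TRUE)] <- 0.6 / 16
    w[grepl("T>C", labels, fixed = TRUE)] <- 0.4 / 16
  } else if (mutationClass == "indel") {
    w <- switch(kind,
      mmr = c(0.05, 0.01, 0.01, 0.02, 0.75, 0.10, 0.05, 0.01),
      hrd = c(0.05, 0.02, 0.10, 0.60, 0.08, 0.05, 0.08, 0.02),
      stop("indel archetype available for kinds 'mmr' and 'hrd'")
    )
  } else {
    w <- switch(kind,
      tdup = c(0.05, 0.05, 0.02, 0.05, 0.03, 0.02, 0.08, 0.60, 0.05, 0.05),
      hrd = c(0.30, 0.10, 0.02, 0.10, 0.08, 0.05, 0.15, 0.05, 0.10, 0.05),
      stop("rearrangement archetype available for kinds 'tdup' and 'hrd'")
    )
  }
  SignatureProfile(w, mutationClass)
}

#' Configuration of a synthetic clone/subclone experiment
#'
#' Describes one simulated knockout experiment for one mutation class: a
#' parental clone set and a subclone set sharing the culture background
#' spectrum, with an optional knockout signature mixed into the subclones at
#' exposure `knockoutExposure` mutations per subclone
#' (0 for null scenarios).
#'
#' Per-sample background totals follow a zero-truncated negative binomial
#' with mean `backgroundMean` and size `dispersion`; the default size of 46
#' gives a coefficient of variation of about 0.15 at the substitution scale
#' (mean 1200) and is Poisson-dominated at the low rearrangement scale,
#' mimicking the between-sample variability of clone experiments. Class
#' defaults for `backgroundMean` are 1200 substitutions, 60 indels and 6
#' rearrangements per sample.
#'
#' @param mutationClass One of [mutationClasses()].
#' @param background Background [SignatureProfile-class]; class default
#'   when `NULL`.
#' @param knockout Knockout [SignatureProfile-class]; class-appropriate
#'   archetype (see [knockoutProfile()]) when `NULL` and
#'   `knockoutExposure > 0`.
#' @param backgroundMean Mean background mutations per sample.
#' @param dispersion Negative binomial size parameter.
#' @param knockoutExposure Knockout mutations added to each subclone.
#' @param nParental,nSubclones Sample counts (defaults 9 parental clones,
#'   7 subclones, the layout of the experimental design emulated here).
#' @param knockoutName Label recorded on subclones.
#' @param seed Optional seed.
#' @return A validated list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(mutationClass = "substitution",
                             background = NULL,
                             knockout = NULL,
                             backgroundMean = NULL,
                             dispersion = 46,
                             knockoutExposure = 0,
                             nParental = 9L,
                             nSubclones = 7L,
                             knockoutName = "KO",
                             seed = NULL) {
  mutationClass <- matchMutationClass(mutationClass)
  if (is.null(background)) {
    background <- switch(mutationClass,
      substitution = defaultBackgroundProfile(),
      indel = backgroundIndelProfile(),
      rearrangement = backgroundRearrangementProfile()
    )
  }
  if (is.null(backgroundMean)) {
    backgroundMean <- switch(mutationClass,
      substitution = 1200, indel = 60, rearrangement = 6)
  }
  if (knockoutExposure > 0 && is.null(knockout)) {
    knockout <- switch(mutationClass,
      substitution = knockoutProfile("mmr", "substitution"),
      indel = knockoutProfile("mmr", "indel"),
      rearrangement = knockoutProfile("tdup", "rearrangement")
    )
  }
  stopifnot(is(background, "SignatureProfile"),
            mutationClass(background) == mutationClass)
  if (!is.null(knockout)) {
    stopifnot(is(knockout, "SignatureProfile"),
              mutationClass(knockout) == mutationClass)
  }
  if (backgroundMean <= 0) stop("backgroundMean must be positive")
  if (dispersion <= 0) stop("dispersion (negative binomial size) must be positive")
  if (knockoutExposure < 0) stop("knockoutExposure must be >= 0")
  if (nParental < 1L || nSubclones < 1L) stop("sample counts must be >= 1")
  structure(
    list(mutationClass = mutationClass, background = background,
         knockout = knockout, backgroundMean = backgroundMean,
         dispersion = dispersion, knockoutExposure = knockoutExposure,
         nParental = as.integer(nParental),
         nSubclones = as.integer(nSubclones),
         knockoutName = knockoutName,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "SimulationConfig"
  )
}

# Zero-truncated negative binomial totals: every sequenced clone carries at
# least one mutation of each class in this design.
ztNegBinomial <- function(n, mu, size) {
  out <- stats::rnbinom(n, mu = mu, size = size)
  while (any(out == 0L)) {
    out[out == 0L] <- stats::rnbinom(sum(out == 0L), mu = mu, size = size)
  }
  out
}

#' Simulate clone/subclone channel-count catalogs with known truth
#'
#' Draws per-sample background totals from the configured count model, then
#' channel counts as multinomials from the background profile; each subclone
#' additionally receives an independent multinomial of size
#' `knockoutExposure` from the knockout profile. The generating profiles
#' and realised per-sample exposures are returned as the simulation truth.
#'
#' @param config A [simulationConfig()].
#' @return A list: `parental` and `subclones` ([MutationCatalog]s) and
#'   `truth` (config plus realised `parentalTotals`,
#'   `subcloneBackgroundTotals` and `subcloneKnockoutExposure`).
#' @export
simulateCatalogs <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  withSeed(config$seed, {
    bg <- profileWeights(config$background)
    parentalTotals <- ztNegBinomial(config$nParental, config$backgroundMean,
                                    config$dispersion)
    parentalCounts <- vapply(parentalTotals, function(t) {
      stats::rmultinom(1L, t, bg)[, 1L]
    }, integer(length(bg)))
    subBgTotals <- ztNegBinomial(config$nSubclones, config$backgroundMean,
                                 config$dispersion)
    subCounts <- vapply(subBgTotals, function(t) {
      stats::rmultinom(1L, t, bg)[, 1L]
    }, integer(length(bg)))
    if (config$knockoutExposure > 0) {
      ko <- profileWeights(config$knockout)
      subCounts <- subCounts + stats::rmultinom(
        config$nSubclones, config$knockoutExposure, ko)
    }
    labels <- channelLabels(config$mutationClass)
    dimnames(parentalCounts) <- list(
      labels, paste0("parental", seq_len(config$nParental)))
    dimnames(subCounts) <- list(
      labels, paste0(config$knockoutName, "_sub",
                     seq_len(config$nSubclones)))
    list(
      parental = MutationCatalog(parentalCounts, config$mutationClass,
                                 role = "parental"),
      subclones = MutationCatalog(subCounts, config$mutationClass,
                                  role = "subclone",
                                  knockout = config$knockoutName),
      truth = list(
        config = config,
        parentalTotals = parentalTotals,
        subcloneBackgroundTotals = subBgTotals,
        subcloneKnockoutExposure = rep(config$knockoutExposure,
                                       config$nSubclones)
      )
    )
  })
}

#' Deterministic toy genome with annotations
#'
#' Builds a small synthetic reference for record-level simulation and
#' topography tests: random-base contigs with planted poly-A and AG-repeat
#' tracts (guaranteeing sites for the repeat-mediated deletion channels),
#' protein-coding-gene annotations covering ~10\% of the main contig (half
#' on each strand), an alternating leading/lagging replication-orientation
#' track, and ten equal-size replication-timing deciles. Everything is
#' deterministic given the seed.
#'
#' @param seed Integer seed.
#' @param lengths Named contig lengths; the first contig carries the
#'   annotations. The default main contig is 1.2 Mb so that every
#'   rearrangement size bin (including >1 Mb) has valid spans.
#' @return A list of class `"ToyGenome"`: `genome`
#'   ([Biostrings::DNAStringSet]), `genes`, `replication` and `timing`
#'   ([GenomicRanges::GRanges] with `label` columns).
#' @export
toyGenome <- function(seed = 1L,
                      lengths = c(chrS1 = 1200000L, chrS2 = 300000L)) {
  withSeed(seed, {
    contigs <- lapply(lengths, function(len) {
      paste(sample(.bases, len, replace = TRUE), collapse = "")
    })
    main <- names(lengths)[1L]
    mainLen <- lengths[[1L]]
    # plant repeat tracts every 10 kb on the main contig
    s <- contigs[[main]]
    tractStarts <- seq(5000L, mainLen - 100L, by = 10000L)
    for (p in tractStarts) {
      substr(s, p, p + 11L) <- "AAAAAAAAAAAA"
      substr(s, p + 30L, p + 41L) <- "AGAGAGAGAGAG"
    }
    contigs[[main]] <- s
    genome <- Biostrings::DNAStringSet(unlist(contigs))
    names(genome) <- names(lengths)
    # genes: 60 x 2 kb = 120 kb = 10% of the main contig, alternate strands
    geneStarts <- seq(1000L, by = 20000L, length.out = 60L)
    genes <- GenomicRanges::GRanges(
      main, IRanges::IRanges(geneStarts, width = 2000L),
      label = rep(c("+", "-"), length.out = 60L))
    # replication orientation: alternating 50 kb leading/lagging blocks
    repStarts <- seq(1L, mainLen, by = 50000L)
    replication <- GenomicRanges::GRanges(
      main, IRanges::IRanges(repStarts,
                             width = pmin(50000L, mainLen - repStarts + 1L)),
      label = rep(c("leading", "lagging"),
                  length.out = length(repStarts)))
    # timing deciles: ten equal consecutive blocks
    decWidth <- mainLen %/% 10L
    timing <- GenomicRanges::GRanges(
      main, IRanges::IRanges(seq(1L, by = decWidth, length.out = 10L),
                             width = decWidth),
      label = as.character(1:10))
    structure(list(genome = genome, genes = genes,
                   replication = replication, timing = timing),
              class = "ToyGenome")
  })
}

# Per-channel eligible-site index on a toy genome. Channels are mapped to
# concrete anchor positions whose local sequence guarantees that a record
# built there classifies back to the channel.
substitutionSiteIndex <- function(genome) {
  index <- list()
  for (chrom in names(genome)) {
    s <- as.character(genome[[chrom]])
    len <- nchar(s)
    tri <- substring(s, seq_len(len - 2L), seq_len(len - 2L) + 2L)
    byTri <- split(seq_len(len - 2L) + 1L, tri)
    for (channel in channelLabels("substitution")) {
      five <- substr(channel, 1L, 1L)
      ref <- substr(channel, 3L, 3L)
      alt <- substr(channel, 5L, 5L)
      three <- substr(channel, 7L, 7L)
      fwd <- paste0(five, ref, three)
      rev <- revcomp(fwd)
      entry <- index[[channel]]
      if (is.null(entry)) {
        entry <- data.frame(chrom = character(0), pos = integer(0),
                            flipped = logical(0))
      }
      addSites <- function(positions, flipped) {
        if (!length(positions)) return(NULL)
        data.frame(chrom = chrom, pos = positions, flipped = flipped)
      }
      entry <- rbind(entry,
                     addSites(byTri[[fwd]], FALSE),
                     addSites(byTri[[rev]], TRUE))
      index[[channel]] <- entry
    }
  }
  index
}

# Candidate indel anchors per channel, validated through the classifier.
indelSiteIndex <- function(genome, maxPerChannel = 3000L) {
  labels <- channelLabels("indel")
  index <- stats::setNames(vector("list", length(labels)), labels)
  for (chrom in names(genome)) {
    s <- as.character(genome[[chrom]])
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    len <- length(ch)
    i <- seq_len(len - 8L)  # anchor positions with room for context
    b0 <- ch[i]; b1 <- ch[i + 1L]; b2 <- ch[i + 2L]; b3 <- ch[i + 3L]
    b4 <- ch[i + 4L]; b5 <- ch[i + 5L]; b6 <- ch[i + 6L]
    candidates <- list(
      "1bp_insertion" = i,
      "2bp+_insertion" = i,
      # deletion sites must be left-aligned: anchor differs from the base
      # closing the deleted motif
      "1bp_repeat_deletion" = i[b1 == b2 & b0 != b1],
      "2bp+_repeat_deletion" = i[b1 == b3 & b2 == b4 & b0 != b2],
      "2bp_mh_deletion" = i[b3 == b1 & b4 != b2 & b0 != b2],
      "3bp+_mh_deletion" = i[b4 == b1 & (b5 != b2 | b6 != b3) & b0 != b3],
      "other_deletion" = i[b2 != b1 & b0 != b1],
      "complex" = i
    )
    for (channel in labels) {
      pos <- candidates[[channel]]
      if (!length(pos)) next
      if (length(pos) > maxPerChannel) {  # evenly spaced subset
        pos <- pos[unique(round(seq(1L, length(pos),
                                    length.out = maxPerChannel)))]
      }
      df <- data.frame(chrom = chrom, pos = pos)
      index[[channel]] <- rbind(index[[channel]], df)
    }
  }
  # validate through the classifier so the round trip is exact by
  # construction
  for (channel in labels) {
    entry <- index[[channel]]
    if (is.null(entry) || !nrow(entry)) {
      stop("no eligible site for indel channel ", channel)
    }
    records <- indelRecordAt(entry, channel, genome, fixedAlt = TRUE)
    got <- classifyIndels(records, genome, naOnError = TRUE)
    index[[channel]] <- entry[!is.na(got) & got == channel, , drop = FALSE]
    if (!nrow(index[[channel]])) {
      stop("no eligible site for indel channel ", channel)
    }
  }
  index
}

# Build concrete indel records at the given anchors for one channel.
indelRecordAt <- function(sites, channel, genome, fixedAlt = FALSE) {
  n <- nrow(sites)
  getContig <- contigStringCache(genome)
  fetch <- function(i, width) {
    substring(getContig(sites$chrom[i]), sites$pos[i], sites$pos[i] + width)
  }
  newBase <- function(i, avoid) {
    if (fixedAlt) return(setdiff(.bases, avoid)[1L])
    sample(setdiff(.bases, avoid), 1L)
  }
  ref <- character(n)
  alt <- character(n)
  for (i in seq_len(n)) {
    anchor <- fetch(i, 0L)
    switch(channel,
      "1bp_insertion" = {
        ref[i] <- anchor
        alt[i] <- paste0(anchor, newBase(i, character(0)))
      },
      "2bp+_insertion" = {
        ref[i] <- anchor
        alt[i] <- paste0(anchor, newBase(i, character(0)),
                         newBase(i, character(0)))
      },
      "1bp_repeat_deletion" = ,
      "other_deletion" = {
        ref[i] <- fetch(i, 1L)
        alt[i] <- anchor
      },
      "2bp_mh_deletion" = ,
      "2bp+_repeat_deletion" = {
        ref[i] <- fetch(i, 2L)
        alt[i] <- anchor
      },
      "3bp+_mh_deletion" = {
        ref[i] <- fetch(i, 3L)
        alt[i] <- anchor
      },
      "complex" = {
        two <- fetch(i, 1L)
        deleted <- substr(two, 2L, 2L)
        ref[i] <- two
        alt[i] <- paste0(anchor, newBase(i, deleted))
      }
    )
  }
  data.frame(chrom = sites$chrom, pos = sites$pos, ref = ref, alt = alt)
}

#' Simulate variant records on a toy genome
#'
#' Record-level counterpart of [simulateCatalogs()]: channel counts are
#' drawn exactly as there, then each mutation is materialised at a genomic
#' site whose local sequence guarantees that the emitted record classifies
#' back to the drawn channel — so `buildCatalog()` on the simulated records
#' reproduces the simulated channel counts exactly. A channel with positive
#' weight but no eligible site in the toy genome is an error naming the
#' channel.
#'
#' @param config A [simulationConfig()].
#' @param genome A [toyGenome()] (or compatible list with a `genome`
#'   `DNAStringSet`).
#' @param outdir Optional directory: per-sample VCF (substitutions, indels)
#'   or BEDPE-like TSV (rearrangements) files, the reference FASTA,
#'   annotation BED tracks and a JSON truth file are written there.
#' @return A list: `records` (named list of per-sample record
#'   `data.frame`s), `channelCounts` (drawn counts matrix, channels x
#'   samples), `roles`, `truth`, and `files` (when `outdir` is given).
#' @export
simulateVariantRecords <- function(config, genome = toyGenome(),
                                   outdir = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  ref <- genome$genome
  withSeed(config$seed, {
    bg <- profileWeights(config$background)
    labels <- channelLabels(config$mutationClass)
    nSamples <- config$nParental + config$nSubclones
    sampleIds <- c(paste0("parental", seq_len(config$nParental)),
                   paste0(config$knockoutName, "_sub",
                          seq_len(config$nSubclones)))
    roles <- rep(c("parental", "subclone"),
                 c(config$nParental, config$nSubclones))
    totals <- ztNegBinomial(nSamples, config$backgroundMean,
                            config$dispersion)
    counts <- vapply(totals, function(t) {
      stats::rmultinom(1L, t, bg)[, 1L]
    }, integer(length(bg)))
    if (config$knockoutExposure > 0) {
      ko <- profileWeights(config$knockout)
      counts[, roles == "subclone"] <-
        counts[, roles == "subclone", drop = FALSE] +
        stats::rmultinom(config$nSubclones, config$knockoutExposure, ko)
    }
    dimnames(counts) <- list(labels, sampleIds)
    activeChannels <- labels[rowSums(counts) > 0]
    siteIndex <- switch(config$mutationClass,
      substitution = substitutionSiteIndex(ref),
      indel = indelSiteIndex(ref),
      rearrangement = NULL
    )
    if (!is.null(siteIndex)) {
      empty <- activeChannels[vapply(activeChannels, function(chnl) {
        is.null(siteIndex[[chnl]]) || nrow(siteIndex[[chnl]]) == 0L
      }, NA)]
      if (length(empty)) {
        stop("no eligible site in the toy genome for channel(s): ",
             paste(empty, collapse = ", "))
      }
    }
    records <- lapply(seq_len(nSamples), function(j) {
      drawSampleRecords(counts[, j], config$mutationClass, ref, siteIndex)
    })
    names(records) <- sampleIds
    out <- list(records = records, channelCounts = counts, roles = roles,
                truth = list(config = config, totals = totals))
    if (!is.null(outdir)) {
      out$files <- writeSimulatedData(out, config, genome, outdir)
    }
    out
  })
}

drawSampleRecords <- function(channelCounts, mutationClass, ref, siteIndex) {
  parts <- list()
  for (channel in names(channelCounts)) {
    n <- channelCounts[[channel]]
    if (n == 0L) next
    if (mutationClass == "substitution") {
      sites <- siteIndex[[channel]]
      pick <- sites[sample.int(nrow(sites), n,
                               replace = n > nrow(sites)), , drop = FALSE]
      alt <- substr(channel, 5L, 5L)
      refPyr <- substr(channel, 3L, 3L)
      altVec <- ifelse(pick$flipped, complementBase(alt), alt)
      refVec <- ifelse(pick$flipped, complementBase(refPyr), refPyr)
      parts[[channel]] <- data.frame(chrom = pick$chrom, pos = pick$pos,
                                     ref = refVec, alt = altVec)
    } else if (mutationClass == "indel") {
      sites <- siteIndex[[channel]]
      pick <- sites[sample.int(nrow(sites), n,
                               replace = n > nrow(sites)), , drop = FALSE]
      parts[[channel]] <- indelRecordAt(pick, channel, ref)
    } else {
      parts[[channel]] <- rearrangementRecordsFor(channel, n, ref)
    }
  }
  if (!length(parts)) {
    if (mutationClass == "rearrangement") {
      return(data.frame(chrom1 = character(0), pos1 = integer(0),
                        chrom2 = character(0), pos2 = integer(0),
                        svclass = character(0)))
    }
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0)))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

rearrangementRecordsFor <- function(channel, n, ref) {
  contigs <- names(ref)
  lens <- vapply(contigs, function(c) length(ref[[c]]), 0L)
  if (channel == "translocation") {
    if (length(contigs) < 2L) {
      stop("no eligible site in the toy genome for channel(s): ",
           "translocation (needs at least two contigs)")
    }
    return(data.frame(
      chrom1 = contigs[1L],
      pos1 = sample.int(lens[1L], n, replace = TRUE),
      chrom2 = contigs[2L],
      pos2 = sample.int(lens[2L], n, replace = TRUE),
      svclass = "translocation"
    ))
  }
  svclass <- sub("_[^_]+$", "", channel)
  bin <- sub("^.*_", "", channel)
  main <- contigs[1L]
  mainLen <- lens[1L]
  range <- switch(bin,
    "1-10kb" = c(1000L, 10000L),
    "10kb-1Mb" = c(10001L, 1000000L),
    ">1Mb" = c(1000001L, mainLen - 1L)
  )
  if (range[2L] < range[1L]) {
    stop("no eligible site in the toy genome for channel(s): ", channel,
         " (contig too short for the span bin)")
  }
  span <- sample.int(range[2L] - range[1L] + 1L, n, replace = TRUE) +
    range[1L] - 1L
  pos1 <- vapply(span, function(sp) {
    sample.int(mainLen - sp, 1L)
  }, 0L)
  data.frame(chrom1 = main, pos1 = pos1, chrom2 = main, pos2 = pos1 + span,
             svclass = svclass)
}

writeSimulatedData <- function(sim, config, genome, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (sampleId in names(sim$records)) {
    records <- sim$records[[sampleId]]
    if (config$mutationClass == "rearrangement") {
      path <- file.path(outdir, paste0(sampleId, ".bedpe.tsv"))
      writeRearrangements(records, path)
    } else {
      path <- file.path(outdir, paste0(sampleId, ".vcf"))
      writeSmallVariants(records, path, "vcf")
    }
    files[[sampleId]] <- path
  }
  fastaPath <- file.path(outdir, "reference.fa")
  Biostrings::writeXStringSet(genome$genome, fastaPath)
  files$reference <- fastaPath
  for (trackName in c("genes", "replication", "timing")) {
    gr <- genome[[trackName]]
    path <- file.path(outdir, paste0(trackName, ".bed"))
    exportGr <- gr
    S4Vectors::mcols(exportGr) <- S4Vectors::DataFrame(
      name = S4Vectors::mcols(gr)$label)
    rtracklayer::export(exportGr, path, format = "BED")
    files[[trackName]] <- path
  }
  truthPath <- file.path(outdir, "truth.json")
  jsonlite::write_json(
    list(mutationClass = config$mutationClass,
         backgroundMean = config$backgroundMean,
         knockoutExposure = config$knockoutExposure,
         totals = sim$truth$totals,
         channelCounts = as.data.frame(sim$channelCounts)),
    truthPath, auto_unbox = TRUE, digits = NA)
  files$truth <- truthPath
  files
}

#' Simulate replication-strand-biased substitutions
#'
#' Generates per-subclone substitution records on a toy genome whose
#' effective replication-strand assignment (after the pyrimidine flip) is
#' lagging-biased by the given fold: per subclone, leading-strand mutation
#' counts are Poisson(`meanPerStrand`) and lagging-strand counts
#' Poisson(`fold * meanPerStrand`). All records are of one pyrimidine
#' mutation type. Used to validate [strandAsymmetryTest()] against known
#' asymmetry.
#'
#' @param genome A [toyGenome()].
#' @param nSubclones Number of subclones.
#' @param meanPerStrand Mean leading-strand mutations per subclone.
#' @param fold Lagging/leading fold change.
#' @param pyrType Pyrimidine mutation type, e.g. `"C>T"`.
#' @param seed Optional seed.
#' @return A record `data.frame` with a `sample` column, ready for
#'   [assignStrand()].
#' @export
simulateStrandBiasedSubstitutions <- function(genome, nSubclones = 7L,
                                              meanPerStrand = 500,
                                              fold = 1.4,
                                              pyrType = "C>T",
                                              seed = NULL) {
  ref <- substr(pyrType, 1L, 1L)
  alt <- substr(pyrType, 3L, 3L)
  track <- genome$replication
  label <- as.character(S4Vectors::mcols(track)$label)
  main <- names(genome$genome)[1L]
  s <- as.character(genome$genome[[main]])
  # candidate sites: pyrimidine ref on + strand keeps the track label,
  # purine (complement) ref swaps it
  pools <- list(leading = NULL, lagging = NULL)
  starts <- GenomicRanges::start(track)
  ends <- GenomicRanges::end(track)
  for (k in seq_along(label)) {
    block <- substring(s, starts[k], ends[k])
    offs <- which(strsplit(block, "", fixed = TRUE)[[1L]] %in%
                    c(ref, complementBase(ref)))
    pos <- starts[k] + offs - 1L
    pos <- pos[pos > 1L & pos < nchar(s)]
    base <- substring(s, pos, pos)
    effective <- ifelse(base == ref, label[k],
                        setdiff(c("leading", "lagging"), label[k]))
    for (lab in c("leading", "lagging")) {
      pools[[lab]] <- c(pools[[lab]], pos[effective == lab])
    }
  }
  withSeed(seed, {
    out <- lapply(seq_len(nSubclones), function(j) {
      nLead <- stats::rpois(1L, meanPerStrand)
      nLag <- stats::rpois(1L, fold * meanPerStrand)
      pos <- c(sample(pools$leading, nLead),
               sample(pools$lagging, nLag))
      base <- substring(s, pos, pos)
      data.frame(
        chrom = main, pos = pos, ref = base,
        alt = ifelse(base == ref, alt, complementBase(alt)),
        sample = paste0("sub", j)
      )
    })
    do.call(rbind, out)
  })
}
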