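#' Pipeline configuration
#'
#' Settings shared by a full [runPipeline()] analysis. The `seed` propagates
#' deterministic sub-seeds to every stage, so a rerun with identical inputs
#' and configuration reproduces the report bit-identically.
#'
#' @param bootstrap A [bootstrapConfig()] (its `seed` field is ignored; the
#'   pipeline seed governs).
#' @param alpha Significance level for both the shift and count calls.
#' @param countBoot Bootstrap aggregates for [countElevationTest()].
#' @param divisions Cell divisions over the culture period, for
#'   [mutationsPerDivision()].
#' @param extractionBoot,ciLevel,nProfiles,acceptMin,step,search,boundaryRule
#'   Extraction settings (see [extractKnockoutSignature()]).
#' @param seed Integer seed.
#' @return A list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(bootstrap = bootstrapConfig(),
                           alpha = 0.01,
                           countBoot = 10000L,
                           divisions = 36,
                           extractionBoot = 10000L,
                           ciLevel = 0.99,
                           nProfiles = 100L,
                           acceptMin = 5L,
                           step = 1L,
                           search = "unit",
                           boundaryRule = "upper",
                           seed = 1L) {
  structure(
    list(bootstrap = bootstrap, alpha = alpha,
         countBoot = as.integer(countBoot), divisions = divisions,
         extractionBoot = as.integer(extractionBoot), ciLevel = ciLevel,
         nProfiles = as.integer(nProfiles), acceptMin = as.integer(acceptMin),
         step = as.integer(step), search = search,
         boundaryRule = boundaryRule, seed = as.integer(seed)),
    class = "PipelineConfig"
  )
}

#' Run the full knockout-signature workflow
#'
#' Orchestrates the three-step analysis per mutation class, in the order
#' the method requires:
#' \enumerate{
#'   \item the spectrum-shift test runs for ALL knockouts first (sharing one
#'     pooled parental bootstrap null per class), so that the knockouts
#'     without a shift define the Step 2 baseline;
#'   \item the count-elevation test runs for every knockout against that
#'     baseline;
#'   \item signature extraction runs only for knockouts called to have a
#'     signature (`shifted` and count p < alpha), followed by
#'     cosine-similarity comparison against an optional reference catalog.
#' }
#' Baselines are per mutation class: a knockout can be non-shifted for one
#' class while shifted for another. If a class has no non-shifted knockout,
#' Step 2 for that class is recorded as an error in the report (the other
#' classes are still analysed).
#'
#' @param catalogs Named list (by mutation class) of [MutationCatalog]s;
#'   each must contain the parental clones (`role == "parental"`) and all
#'   knockouts' subclones (`role == "subclone"`, with `knockout` labels).
#' @param config A [pipelineConfig()].
#' @param referenceCatalogs Optional named list (by mutation class) of
#'   reference signature matrices (see [readSignatureCatalog()]).
#' @return A list of class `"RunReport"`: per class, the parental
#'   threshold, per-knockout shift/count/call/extraction/similarity
#'   results, and the baseline knockout set; plus the config echo and
#'   package version.
#' @export
runPipeline <- function(catalogs, config = pipelineConfig(),
                        referenceCatalogs = list()) {
  stopifnot(is.list(catalogs), length(catalogs) > 0)
  report <- list(classes = list(), config = config,
                 version = as.character(utils::packageVersion("knockoutSigs")))
  for (ci in seq_along(catalogs)) {
    catalog <- catalogs[[ci]]
    stopifnot(is(catalog, "MutationCatalog"))
    className <- mutationClass(catalog)
    classSeed <- deriveSeed(config$seed, ci * 1000L)
    roles <- sampleRoles(catalog)
    parental <- catalog[, roles == "parental"]
    subAll <- catalog[, roles == "subclone"]
    knockouts <- unique(knockoutLabels(subAll))
    knockouts <- knockouts[!is.na(knockouts)]
    if (ncol(parental) < 2L || !length(knockouts)) {
      stop("class '", className, "' needs >= 2 parental samples and at ",
           "least one labelled knockout")
    }
    boot <- config$bootstrap
    boot$seed <- NULL
    classReport <- list(mutationClass = className)

    # Step 1: spectrum shift for every knockout, shared parental null
    parentalNull <- withSeed(deriveSeed(classSeed, 1L),
                             parentalBootstrapNull(parental, boot))
    classReport$dPCThreshold <- parentalNull$threshold
    shifts <- list()
    for (ki in seq_along(knockouts)) {
      ko <- knockouts[ki]
      subKo <- subAll[, knockoutLabels(subAll) == ko]
      boot$seed <- deriveSeed(classSeed, 100L + ki)
      shifts[[ko]] <- spectrumShiftTest(parental, subKo, boot,
                                        parentalNull = parentalNull)
    }

    # Step 2: count elevation against the non-shifted baseline
    nonShifted <- knockouts[!vapply(shifts, isShifted, NA)]
    classReport$baselineKnockouts <- nonShifted
    baseline <- if (length(nonShifted)) {
      unlist(lapply(nonShifted, function(ko) {
        sampleTotals(subAll[, knockoutLabels(subAll) == ko])
      }))
    } else {
      numeric(0)
    }
    knockoutReports <- list()
    for (ki in seq_along(knockouts)) {
      ko <- knockouts[ki]
      subKo <- subAll[, knockoutLabels(subAll) == ko]
      entry <- list(knockout = ko, shift = shifts[[ko]])
      if (!length(baseline)) {
        entry$error <- paste(
          "no knockout without a spectrum shift is available for this",
          "class; cannot form a baseline count distribution")
        entry$call <- NULL
      } else {
        count <- countElevationTest(
          sampleTotals(subKo), baseline, nBoot = config$countBoot,
          seed = deriveSeed(classSeed, 200L + ki))
        entry$count <- count
        entry$call <- callKnockout(shifts[[ko]], count,
                                   alpha = config$alpha, knockout = ko,
                                   mutationClass = className)
        # Step 3: extraction (and similarity) for called knockouts only
        if (hasSignature(entry$call)) {
          extraction <- extractKnockoutSignature(
            subKo, parental,
            nBoot = config$extractionBoot, ciLevel = config$ciLevel,
            nProfiles = config$nProfiles, acceptMin = config$acceptMin,
            step = config$step, seed = deriveSeed(classSeed, 300L + ki),
            search = config$search, boundaryRule = config$boundaryRule)
          entry$extraction <- extraction
          entry$ratePerDivision <- mutationsPerDivision(
            knockoutExposure(extraction), config$divisions)
          refCat <- referenceCatalogs[[className]]
          if (!is.null(refCat)) {
            entry$similarity <- compareToCatalog(
              extractedSignature(extraction), refCat)
          }
        }
      }
      knockoutReports[[ko]] <- entry
    }
    classReport$knockouts <- knockoutReports
    report$classes[[className]] <- classReport
  }
  structure(report, class = "RunReport")
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport (knockoutSigs", x$version, ")\n")
  for (classReport in x$classes) {
    cat("--", classReport$mutationClass, "--\n")
    for (entry in classReport$knockouts) {
      if (!is.null(entry$error)) {
        cat(sprintf("  %s: %s\n", entry$knockout, entry$error))
        next
      }
      call <- entry$call
      cat(sprintf("  %s: shifted=%s, count p=%.4g -> %s\n",
                  entry$knockout, isShifted(entry$shift),
                  pValue(entry$count),
                  if (hasSignature(call)) "SIGNATURE" else "no signature"))
      if (!is.null(entry$extraction)) {
        cat(sprintf("    e_p=%g, e_ko=%g (%.3g per division)\n",
                    backgroundExposure(entry$extraction),
                    knockoutExposure(entry$extraction),
                    entry$ratePerDivision))
      }
    }
  }
  invisible(x)
}

#' Write a machine-readable run report
#'
#' Serialises the decisions, thresholds, exposures and extracted signatures
#' of a [runPipeline()] report to JSON.
#'
#' @param report A `"RunReport"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeRunReport <- function(report, path) {
  out <- list(version = report$version,
              seed = report$config$seed,
              alpha = report$config$alpha,
              classes = list())
  for (classReport in report$classes) {
    cls <- list(dPCThreshold = classReport$dPCThreshold,
                baselineKnockouts = as.list(classReport$baselineKnockouts),
                knockouts = list())
    for (entry in classReport$knockouts) {
      ko <- list(knockout = entry$knockout,
                 dPS = entry$shift@dPS,
                 dPCThreshold = entry$shift@dPCThreshold,
                 dSCThreshold = entry$shift@dSCThreshold,
                 shifted = isShifted(entry$shift))
      if (!is.null(entry$error)) {
        ko$error <- entry$error
      } else {
        ko$countPValue <- pValue(entry$count)
        ko$hasSignature <- hasSignature(entry$call)
        ko$reason <- entry$call@reason
        if (!is.null(entry$extraction)) {
          ko$backgroundExposure <- backgroundExposure(entry$extraction)
          ko$knockoutExposure <- knockoutExposure(entry$extraction)
          ko$ratePerDivision <- entry$ratePerDivision
          ko$signature <- as.list(
            profileWeights(extractedSignature(entry$extraction)))
          if (!is.null(entry$similarity)) {
            ko$similarity <- entry$similarity
          }
        }
      }
      cls$knockouts[[entry$knockout]] <- ko
    }
    out$classes[[classReport$mutationClass]] <- cls
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
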