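# knockoutSigs

Deciding whether a gene knockout generates a mutational signature — and
extracting that signature — from isogenic clone/subclone experiments.

## The scientific problem

In a gene-edited cell system (a knockout parental clone cultured ~1 month,
then 7 single-cell subclones, all whole-genome sequenced), the de novo
mutations of each subclone mix two processes: the culture background that
mutagenises *every* clone (~1200 substitutions, ~60 indels, ~6
rearrangements per sample, with a characteristic C>A-rich substitution
spectrum), and — possibly — a process unleashed by the knockout. The
analytical task is to decide, per knockout and per mutation class, whether
the subclones diverge from the parental clones both *qualitatively*
(spectrum) and *quantitatively* (burden), and if so to separate the
knockout signature from the background.

`knockoutSigs` implements the three-step bootstrap workflow for this
design:

1. **Spectrum shift.** Mutation catalogs (96 trinucleotide substitution
   channels, 8 junction-aware indel channels, 10 size/type rearrangement
   channels) are bootstrapped by multinomial resampling; the observed
   parental–subclone centroid distance `d_ps` (Frobenius distance of
   normalised spectra) is compared against the empirical `1 - α` quantiles
   of both bootstrap clouds' centroid-distance distributions,
   `d_pc_0.01` and `d_sc_0.01`. Shifted ⟺ `d_ps` exceeds both.
2. **Count elevation.** Subclone totals of non-shifted knockouts form a
   baseline pool; a bootstrap p-value (add-one estimator) tests whether a
   knockout's aggregate de novo burden is elevated. A knockout *has a
   signature* only when shifted **and** p < α.
3. **Extraction.** The subclone centroid is modelled as
   `M̄_s ≈ e_p·P̄_p + e_ko·P_ko`; the background exposure `e_p` is found by
   iterative comparison of bootstrapped background profiles against
   per-channel 99% boundaries of the centroid, and
   `P_ko ≈ (M̄_s − e_p·P̄_p)/e_ko` (clipped, renormalised) is the knockout
   signature, with `e_ko = ` centroid total `− e_p` exactly.

Cosine-similarity comparison against reference signature catalogs,
transcription/replication strand-asymmetry tests, replication-timing
density profiles, and a fully seeded synthetic clone/subclone generator
(catalog-level and VCF/BEDPE-record-level on a toy genome) round out the
package. See the vignette (`vignettes/knockout-signatures.Rmd`) for the
model, its conventions and known limitations.

## Worked example

Simulate one experiment with a neutral knockout and a
mismatch-repair-like knockout (3600 extra C>T/T>C substitutions per
subclone over a ~1200-substitution background), then run the full
workflow:

```r
library(knockoutSigs)

nullSim <- simulateCatalogs(simulationConfig("substitution",
  knockoutName = "NEIL1", seed = 101))
mmrSim <- simulateCatalogs(simulationConfig("substitution",
  knockoutExposure = 3600, knockoutName = "MSH6", seed = 102))

counts <- cbind(channelCounts(nullSim$parental),
                channelCounts(nullSim$subclones),
                channelCounts(mmrSim$subclones))
experiment <- MutationCatalog(counts, "substitution",
  role = rep(c("parental", "subclone"), c(9, 14)),
  knockout = rep(c(NA, "NEIL1", "MSH6"), c(9, 7, 7)))

refs <- readSignatureCatalog(system.file("extdata",
  "reference_substitution_signatures_synthetic.tsv",
  package = "knockoutSigs"), "substitution")

report <- runPipeline(list(substitution = experiment),
                      pipelineConfig(search = "coarse", seed = 7),
                      referenceCatalogs = list(substitution = refs))
report
```

```
RunReport (knockoutSigs 0.1.0 )
-- substitution --
  NEIL1: shifted=FALSE, count p=0.4974 -> no signature
  MSH6: shifted=TRUE, count p=9.999e-05 -> SIGNATURE
    e_p=1447, e_ko=3415 (94.9 per division)
```

The neutral knockout shows neither a spectrum shift nor a count elevation
(p ≈ 0.5 against the baseline it helped define). The active knockout is
shifted with a strongly elevated burden, so its signature is extracted:
3415 of the ~4860 centroid mutations are attributed to the knockout
(≈95 per cell division over 36 divisions), and the recovered spectrum is
compared against the packaged (synthetic) reference catalog:

```r
head(report$classes$substitution$knockouts$MSH6$similarity, 3)
#>   signature    cosine
#> 1  SubSig20 0.9888618
#> 2  SubSig08 0.4534827
#> 3  SubSig21 0.4444260

cosineSimilarity(
  profileWeights(extractedSignature(
    report$classes$substitution$knockouts$MSH6$extraction)),
  profileWeights(knockoutProfile("mmr")))
#> [1] 0.999
```

The best match is the reference analogue the simulation planted, and the
extracted signature matches the generating truth at cosine 0.999.

A thin command-line wrapper with `simulate`, `detect`, `extract` and
`compare` subcommands ships at `inst/scripts/kosig.R`.

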