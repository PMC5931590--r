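---
title: "Detecting and extracting knockout mutational signatures"
author: "knockoutSigs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and extracting knockout mutational signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knockoutSigs)
```

## The problem

Isogenic cell systems are the cleanest way to ask whether loss of a single
DNA-repair gene produces a mutational signature: a gene is knocked out in a
(near-haploid) cell line, the edited parental clone is expanded for about a
month (~36 divisions at a ~20 h doubling time), and several subclones are
derived through single-cell bottlenecks and whole-genome sequenced. De novo
mutations of a subclone are the subclone's calls minus the parental clone's
calls (and parental calls are themselves filtered against the bulk
population — both steps are the same `subtractParental()` operation).

The difficulty is noise: culture itself mutagenises. Every clone — edited or
not — accumulates a pervasive background of roughly 1200 substitutions, 60
indels and 6 rearrangements per sample, and the substitution background is a
structured C>A/G>T spectrum (tallest peaks at the TCT, GCA, GCT and ACA
trinucleotide contexts, in that order), not flat noise. A knockout signature
must therefore be detected *above* and *extracted from* this background.

## Mutation channels

Each mutation class is reduced to a fixed channel vector
(`channelLabels()`):

* **Substitutions (96 channels)** — 6 pyrimidine substitution types x 16
  flanking contexts, with purine-reference mutations reverse complemented
  first (`classifySubstitutions()`).
* **Indels (8 channels)** — insertions by length (1 bp, >=2 bp); deletions
  classified at their left-aligned 3' junction as repeat-mediated (a full
  additional copy of the deleted motif immediately 3'; 1 bp vs >=2 bp),
  microhomology-mediated (partial 5' identity of the deleted sequence with
  the 3' junction, >=1 bp but less than full length; 2 bp vs >=3 bp
  deletions), other deletions, and complex indels. Repeat-mediated takes
  precedence over microhomology: the paper-level taxonomy lists both
  without a decision order, and the repeat check is the stricter,
  fully-specified condition, so applying it first makes the taxonomy total
  and deterministic. Microhomology is scanned only at the 3' junction of
  the left-aligned deletion — a single documented convention rather than a
  scan over both junction orientations. A minimum of 1 bp of junction
  identity counts as microhomology; 1 bp deletions have no microhomology
  channel and fall to "other" when not repeat-mediated.
* **Rearrangements (10 channels)** — deletions, inversions and tandem
  duplications in size bins 1–10 kb, 10 kb–1 Mb and >1 Mb, plus
  translocations. Intra-chromosomal spans below 1 kb are below typical
  calling resolution and are rejected into the catalog's reject report
  rather than force-binned.

`buildCatalog()` assembles per-sample channel counts into a
`MutationCatalog` (a `SummarizedExperiment` keyed by role and knockout);
records that cannot be classified (N in context, missing flanks) are
excluded and logged, so column sums always equal the number of classifiable
records.

## Step 1 — spectrum shift

Whether a knockout changed the *shape* of the spectrum is decided in
proportion space. Every sample is bootstrapped by multinomial resampling at
its own total (`bootstrapProfiles()`), producing a cloud of normalised
replicate spectra around the parental clones and around the knockout's
subclones. The statistic is the Euclidean (Frobenius) distance
`d_ps` between the parental and subclone centroids (means of normalised
profiles); normalising first makes samples with different burdens
comparable, since this step is about shape, not count.

Thresholds come from the clouds themselves: repeatedly draw
`nDrawParental = 7` replicates from the pooled parental cloud
(all parental clones jointly — 9 clones x 7000 replicates by default, so
the parental threshold is global across knockouts), compute the distance of
their centroid to the original parental centroid, and take the empirical
`1 - alpha` quantile (floor rank) of 10,000 such distances; the same
construction per knockout with draws of `nDrawSubclone = 9` from the
subclone cloud gives the subclone threshold. The draw sizes 7 and 9 are
kept exactly as printed in the source workflow even though they look
swapped relative to the group sizes (9 parental clones, 7 subclones); both
are configurable in `bootstrapConfig()`. A spectrum is *shifted* only when
`d_ps` strictly exceeds **both** thresholds — ties are non-shifted.

## Step 2 — count elevation

Knockouts without a spectrum shift define what culture alone does to
mutation counts: their per-subclone de novo totals form the baseline pool.
For a knockout under test, `countElevationTest()` bootstraps aggregates of
`length(targetTotals)` draws (with replacement) from that pool and reports
the add-one p-value `(1 + #(aggregate >= observed)) / (1 + nBoot)` — never
exactly zero, since the true tail probability of a bootstrap null is never
known to be zero. Per-subclone totals (not per-knockout aggregates) are
resampled because the baseline distribution is built from per-sample
counts.

A knockout *has a signature* for a class only when it is shifted **and**
its count p-value is strictly below alpha (`callKnockout()`). Both
conjuncts matter in practice: a spectrum shift with count p = 0.9966 and a
count p of 0.0105 at alpha 0.01 are both negative calls. Baselines are per
class — a knockout can be shifted for substitutions yet serve as baseline
for rearrangements. No multiple-testing correction is applied across
knockouts, matching the source procedure.

## Step 3 — background subtraction

The subclone centroid is modelled as a two-component mixture
`M_s ≈ e_p * P_p + e_ko * P_ko`, with `P_p` the pooled parental spectrum
(counts pooled, then normalised — pooling weights clones by burden) and
`e_p + e_ko` equal to the centroid total. The centroid total is the
*rounded mean* of subclone totals, not their sum: the mean keeps `e_ko`
interpretable per subclone and hence per division
(`mutationsPerDivision()`).

`subcloneChannelBoundaries()` bootstraps the centroid (multinomial, size =
centroid total, probabilities = centroid proportions) and takes per-channel
99% bounds. `estimateBackgroundExposure()` then starts from "no knockout
signature" (`e_p` = centroid total) and walks down in steps of 1: at each
candidate it draws 100 multinomial background profiles of size `e_p` from
`P_p` and stops at the first candidate where at least 5 profiles fall
within the boundaries. `extractSignature()` finally takes the residual
`M_s - e_p * P_p`, clips negative channels to zero (the subtraction has no
sign constraint of its own) and renormalises to give `P_ko`, with
`e_ko = centroid total - e_p` holding exactly.

### What "falls within the boundary" means

The strict reading — every channel inside its two-sided interval — turns
out to be degenerate: wherever the knockout signature has mass in channels
in which the background has essentially none, the *lower* bounds of those
channels sit far above anything a background-only profile can reach, so no
candidate is ever accepted and the iteration runs to zero. This is not an
edge case; it is exactly the situation the method exists for (a
mismatch-repair-like C>T/T>C signature over a C>A background).

The default rule is therefore the one-sided envelope: a background profile
is accepted when **no channel exceeds its upper bound**. Overshooting
anywhere means the assumed background exposure is too large; undershooting
is expected wherever the knockout process contributes. The strict rule
remains available (`boundaryRule = "both"`) for spectra where background
and knockout fully overlap.

### Known bias of the exposure estimate

Any stop-at-first-acceptance descent halts where the background's
expected counts first slip under the 99.5% upper bounds of the binding
(largest-weight) background channel. The acceptance point therefore sits
*above* the true background exposure by roughly
`2.58 / sqrt(e_p * w_peak)` in relative terms — about +15–20% at the
default scale (background 1200, peak channel weight 0.12). Simulations in
the test suite measure a median relative error of ~+0.16. The consequences
are mild where the method is actually applied (signatures are extracted
only for called knockouts, where `e_ko` is large): the extracted signature
is essentially unaffected (clipping removes the oversubtracted background
channels; recovery cosines are >0.99 in the acceptance simulations) and
`e_ko` is underestimated by only a few percent. Users comparing absolute
background exposures across experiments should keep this upward bias in
mind.

### Reproducibility of the iterative search

The 100 profiles drawn for a candidate exposure depend only on the seed and
the candidate value (a per-candidate substream). This makes the iteration a
deterministic function of `e_p`, so `search = "coarse"` — geometric descent
(2% steps) followed by unit-step refinement over the final bracket —
returns the same exposure as pure unit stepping while evaluating far fewer
candidates; it is the recommended setting for totals in the thousands.

## Similarity and topography

`compareToCatalog()` ranks cosine similarities of an extracted signature
against a reference catalog, reporting all cosines (runner-up similarities
are informative: several mismatch-repair-deficiency references resemble
each other). The packaged reference files are **synthetic stand-ins**
(filenames end in `_synthetic.tsv`): publicly distributed human-cancer
catalogs are deliberately not bundled to avoid version drift, and the
loader (`readSignatureCatalog()`) accepts any conforming channel-by-
signature TSV.

`assignStrand()` handles the strand bookkeeping for topography analyses:
substitutions are first flipped to pyrimidine representation, and since
annotation labels are given on the + reference strand, a flipped record
swaps its transcriptional or replicative assignment. Records outside
annotations, or under conflicting overlapping gene annotations, are
"unassigned" and counted — the conservative choice for overlapping
opposite-strand genes. `strandAsymmetryTest()` compares per-subclone
counts on the two strands per pyrimidine mutation type with a two-sided
*paired* t-test (the two strand counts of one subclone form a natural
pair) and reports the fold of strand means (lagging/leading or
transcribed/untranscribed). `timingDensity()` divides per-decile mutation
counts by decile genomic size and rescales to mean 1 across the ten
replication-timing deciles.

## The synthetic data generator

`simulateCatalogs()` emulates the study design: `nParental = 9` parental
clones and `nSubclones = 7` subclones per knockout; per-sample background
totals drawn from a zero-truncated negative binomial with class means
1200/60/6 and size 46; channel counts multinomial from the background
profile; and, in subclones only, an added multinomial of size
`knockoutExposure` from the knockout profile. Size 46 gives a coefficient
of variation of ~0.15 at the substitution scale and Poisson-dominated
variation at the rearrangement scale (a negative binomial cannot be
underdispersed, so a fixed CV across scales is not attainable); totals are
zero-truncated because a spectrum requires at least one mutation.
`defaultBackgroundProfile()` encodes the culture background with the
documented C>A peak order and >50% C>A mass; `knockoutProfile()` provides
stylised mismatch-repair, tandem-duplication and
homologous-recombination-deficiency archetypes as ground truth. The
generating profiles and realised exposures are always returned, so
recovery can be checked against truth.

`simulateVariantRecords()` materialises the same draws as VCF/BEDPE
records on a deterministic toy genome (`toyGenome()`: 1.2 Mb + 0.3 Mb
contigs with planted poly-A and AG-repeat tracts, 10% gene coverage split
across strands, alternating leading/lagging blocks, ten equal timing
deciles). Each mutation is placed at a site whose local sequence
guarantees it classifies back to its drawn channel, so
`buildCatalog()` on the simulated records reproduces the drawn channel
counts *exactly* — the end-to-end identity the test suite asserts.

What the generator does **not** emulate: variant-calling artifacts and
coverage-dependent sensitivity, shared lineage structure within a clone
(mutations are drawn independently per sample), non-uniform genomic
context availability of the real genome, and inter-channel correlation
beyond the two-component mixture. Passing tests therefore validate the
statistical machinery under the stated model, not the upstream calling
pipeline.

## Problem sizes and numerical choices

The large simulation checks in the test suite use 200 null knockouts per
class (shift-test type I error <= 2 x alpha), 100 mismatch-repair-like runs
(detection power >= 95%, signature recovery cosine >= 0.95), 100 seeded
strand-asymmetry runs, and reduced bootstrap sizes (1000 replicates per
sample, 2000 distance samples) for those calibrations — sizes chosen to
make the whole suite run in minutes while keeping Monte-Carlo error well
below the margins being asserted. Full-size defaults (7000/9000 replicates,
10,000 distance samples) remain the package defaults for real analyses.

Other numerical conventions, all visible in the code and its documentation:
empirical quantiles use the floor-rank order statistic; threshold ties are
non-shifted; p-values use the add-one estimator; negative residual channels
are clipped before renormalisation; channel label strings are bit-exact and
define the canonical order of every file the package reads or writes.

## Limitations

* The background-exposure estimator is upward-biased by construction (see
  above); its step-1/step-2 gatekeeping and the extracted signature are
  robust to this, absolute `e_p` values are not.
* The mixture model is strictly one background plus one knockout component;
  deconvolution of multiple simultaneous knockout processes is out of
  scope.
* The indel taxonomy is the 8-channel scheme; extended (e.g. 83-channel)
  schemes are not implemented.
* Reference catalogs ship as synthetic analogues; comparisons against real
  published catalogs require supplying those files.
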