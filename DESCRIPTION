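Package: knockoutSigs
Title: Detection and Extraction of Mutational Signatures from Isogenic
    Knockout Clone Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decides whether a gene knockout in an isogenic clone/subclone
    experiment generates a mutational signature, and extracts that signature
    above a pervasive culture background. Implements channel taxonomies for
    substitutions (96 trinucleotide channels), indels (8 junction-aware
    channels) and rearrangements (10 size/type channels); a multinomial
    bootstrap test for mutation-spectrum shifts between parental clones and
    subclones; a bootstrap test for elevated mutation counts; quantile-based
    background-exposure estimation and signature extraction; cosine-similarity
    comparison against reference signature catalogues; transcriptional and
    replicative strand-asymmetry and replication-timing analyses; and a
    synthetic clone/subclone data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'knockoutSigs-package.R'
    'utils.R'
    'taxonomy.R'
    'AllGenerics.R'
    'AllClasses.R'
    'variant-io.R'
    'catalog.R'
    'detect.R'
    'extract.R'
    'similarity.R'
    'topography.R'
    'simulate.R'
    'pipeline.R'
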