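Package: strainpulse
Title: Strain-Mixture Polymorphism Detection in Small Symbiont Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects polymorphic sites in alignments of metagenomic or
    metatranscriptomic reads against a small reference genome (for example
    an algal chloroplast fragment) using a binomial sequencing-error model,
    classifies sites where alternative alleles outnumber the dominant one,
    aggregates per-gene polymorphism statistics across samples, builds
    majority-consensus sequences, and estimates the acceleration of the
    mutation rate against a molecular-clock background. Includes a seeded
    substrain-mixture read simulator with ground truth for validating the
    caller's size and power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    grDevices,
    graphics,
    methods
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
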