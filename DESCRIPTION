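Package: circatac
Title: Diurnal Transcriptome Rhythms and ATAC-Seq Footprint Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for diurnal regulatory genomics in
    insect brains: calls rhythmically expressed genes from time-series
    RNA-seq with a rank-based umbrella test and harmonic regression
    combined by minP, tests differential rhythmicity between wild-type
    and clock-mutant genotypes with a robust cosinor Wald test, processes
    ATAC-seq Tn5 cut-site tracks (peak calling, differential
    accessibility, genomic-feature annotation), detects transcription
    factor footprints by strand-imbalance scoring, quantifies footprint
    occupancy scores across genotype and time-of-day, and measures
    motif-class enrichment against GC- and length-matched backgrounds.
    Ships a synthetic-data generator with known ground truth so every
    stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
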