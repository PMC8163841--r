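Package: nucposlab
Title: Nucleosome Positioning Analysis for Genome-Wide In Vitro
    Reconstitution MNase-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers nucleosome-positioning information from mononucleosomal
    MNase-seq fragment data of genome-wide in vitro chromatin
    reconstitutions. Provides dyad-centered track construction from
    paired-end fragments or shifted single-end reads, two dyad callers (a
    Gaussian-smoothed greedy caller with an exclusion zone and an FFT
    low-pass caller with percentile peak detection), +1/-1 nucleosome
    annotation relative to transcription start sites, joint dyad-region
    construction with PCA and K-means clustering of normalized occupancies
    across conditions, DNA shape profiling from pentamer lookup tables, a
    DNA rigidity (A-tract) score, poly(dA)/poly(dT) hexamer coverage,
    anchor-aligned composite profiles and heatmaps, Reb1 promoter grouping,
    and a synthetic-data generator that plants sequence-linked nucleosome
    preferences so every stage of the pipeline can be verified against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
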