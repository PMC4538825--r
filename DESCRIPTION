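Package: phantomPeaks
Title: Discovery and Screening of Phantom Peaks in ChIP-seq Experiments
Version: 0.2.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Derives a catalog of loci that are reproducibly enriched in
    chromatin immunoprecipitation sequencing (ChIP-seq) both in wild-type
    samples and in antigen-null mutant controls ("Phantom Peaks", i.e.
    false positives of the immunoprecipitation step), characterizes the
    catalog (promoter localization, high-read-density-region overlap,
    expression dependence, histone-mark and transcription-factor
    co-occurrence), and screens arbitrary peak sets against the catalog
    with a reference-constrained interval-overlap permutation test.
    Includes a fixed-width peak caller over binned coverage, derivation of
    binding intervals from DamID probe scores, readers and writers for
    BED, bedGraph, fixed-step wiggle and simple gene-model/expression
    tables, and a synthetic-data generator with planted ground truth so
    every pipeline stage can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
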