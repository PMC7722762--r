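Package: sammytools
Title: Chromatin Compaction Domain Analysis for Sequential Fractionation
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of SAMMY-seq style sequential chromatin
    fractionation experiments: binned and Gaussian-smoothed fraction signal,
    broad enrichment domain calling by maximal scoring segments with a
    permutation null, interval overlap statistics with shuffle randomization
    and Fisher tests, domain border and TSS metaprofiles, genome-wide kernel
    correlation of tracks, chromatin-state-stratified transcript p-value
    aggregation by the Lancaster method, and quantification of nuclear foci
    proximity to the nuclear periphery in fluorescence images. Includes a
    synthetic-data generator that emulates the statistical structure of the
    assay so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    IRanges,
    S4Vectors,
    EBImage,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
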