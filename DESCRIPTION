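Package: spatialsynteny
Title: Spatial Proximity of Evolutionary Rearrangement Breakpoints from Hi-C Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tests whether pairs of loci that are genomically distant in one
    genome but adjacent in a second genome (evolutionary breakpoint pairs) are
    enriched in chromatin contacts, using binned Hi-C read counts. Provides
    synteny-block breakpoint detection and pairing with reciprocal/non-reciprocal
    classification and outgroup-based lineage-of-origin assignment; 1-Mb locus
    binning with assembly-gap filtering and a segmental-duplication mapping-bias
    correction of pair read counts; covariate assembly (gene density, DNaseI
    sensitivity); nested linear-model (ANCOVA) comparisons, a rank-sum test for
    inter-chromosomal pairs, and a stratified resampling null matched on genomic
    distance, gene density and chromatin state. A ground-truthed simulator of
    rearrangement histories, distance-decaying contact counts and covariate
    tracks supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
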