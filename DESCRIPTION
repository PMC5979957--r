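Package: chromloops
Title: Prediction of Intra-TAD Chromatin Interactions from ChIP-seq Peak Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts three-dimensional chromatin interactions (ChIA-PET
    loops, Hi-C loops and Hi-C proximity contacts) inside topologically
    associating domains from one-dimensional ChIP-seq peak profiles. The
    genome is tiled at a fixed resolution, each segment is described by two
    features per assay (peak height and summit-to-centre distance), unlikely
    segments are removed by a mediating-protein and key-feature filtration,
    all remaining intra-TAD segment pairs are featurized by min/max anchor
    encoding and classified with a random forest. Hi-C contact maps are
    converted to training labels through a distance-stratified percentile
    score with a three-class threshold rule. Includes readers and writers
    for narrowPeak, BED, BEDPE, chrom.sizes and sparse contact text, a
    synthetic data generator for end-to-end testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    xgboost,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
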