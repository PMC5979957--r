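#' Filtration configuration
#'
#' Settings for the segment filtration step: the mediating protein whose
#' binding gates retention (CTCF for CTCF ChIA-PET and Hi-C loops, RNAP II
#' for RNAP II ChIA-PET; `NA` for Hi-C heatmaps, where no filtration is
#' applied), the key-feature set (the assays enriched at interaction
#' anchors), and the minimum key-feature score.
#'
#' @param mediatingAssay assay name, or `NA` to skip the mediator gate.
#' @param keyFeatures character vector of assay names scored per segment.
#' @param minKeyScore non-negative integer threshold on the key-feature
#'   score; a segment is retained only if its score reaches it.
#' @return a list of class `FiltrationConfig`.
#' @seealso [defaultFiltration] for the per-interaction-type defaults.
#' @export
filtrationConfig <- function(mediatingAssay = NA_character_,
                             keyFeatures = character(),
                             minKeyScore = 1L) {
  if (length(minKeyScore) != 1L || is.na(minKeyScore) || minKeyScore < 0)
    stopf("minKeyScore must be a non-negative integer")
  structure(list(mediatingAssay = as.character(mediatingAssay),
                 keyFeatures = as.character(keyFeatures),
                 minKeyScore = as.integer(minKeyScore)),
            class = "FiltrationConfig")
}

#' Default filtration settings per interaction type
#'
#' CTCF ChIA-PET and Hi-C loop anchors are enriched for the architectural
#' factors CTCF, SA1, RAD21, SMC3 and ZNF143; RNAP II ChIA-PET anchors for
#' the histone marks H3K4me1, H3K4me3 and H3K27ac.  Hi-C heatmaps receive no
#' filtration (proximity data report most intra-TAD segment pairs, and the
#' mediating proteins are diverse).
#'
#' @param type one of "ctcf_chiapet", "hic_loops", "rnapii_chiapet",
#'   "hic_heatmap".
#' @return a `FiltrationConfig`.
#' @export
defaultFiltration <- function(type = c("ctcf_chiapet", "hic_loops",
                                       "rnapii_chiapet", "hic_heatmap")) {
  type <- match.arg(type)
  switch(type,
    ctcf_chiapet = ,
    hic_loops = filtrationConfig("CTCF",
                                 c("CTCF", "SA1", "RAD21", "SMC3", "ZNF143"), 1L),
    rnapii_chiapet = filtrationConfig("RNAPII",
                                      c("H3K4me1", "H3K4me3", "H3K27ac"), 1L),
    hic_heatmap = filtrationConfig(NA_character_, character(), 0L))
}

#' Key-feature score per segment
#'
#' The number of key-feature assays with a peak (height > 0) at the segment;
#' a threshold-free presence count in `[0, length(keyFeatures)]`.
#'
#' @param sft a [SegmentFeatureTable-class].
#' @param keyFeatures character vector of assay names; must all be assays of
#'   the table.
#' @return integer vector, one score per segment.
#' @export
keyFeatureScore <- function(sft, keyFeatures) {
  unknown <- setdiff(keyFeatures, assayNames(sft))
  if (length(unknown))
    stopf("unknown key feature(s): %s (table assays: %s)",
          paste(unknown, collapse = ", "),
          paste(assayNames(sft), collapse = ", "))
  if (!length(keyFeatures)) return(integer(length(segments(sft))))
  h <- featureMatrix(sft)[, paste0(keyFeatures, "_height"), drop = FALSE]
  as.integer(rowSums(h > 0))
}

#' Filter segments by mediating protein and key-feature score
#'
#' A segment is retained iff the mediating assay has a peak there (skipped
#' when `mediatingAssay` is `NA`) and its key-feature score reaches
#' `minKeyScore`.  With the Hi-C heatmap configuration (no mediator, empty
#' key set, threshold 0) every segment is retained.
#'
#' @param sft a [SegmentFeatureTable-class].
#' @param config a `FiltrationConfig` from [filtrationConfig].
#' @return logical vector, `TRUE` for retained segments.  A warning (not an
#'   error) is raised when nothing is retained.
#' @export
filterSegments <- function(sft, config) {
  stopifnot(inherits(config, "FiltrationConfig"))
  keep <- rep(TRUE, length(segments(sft)))
  if (!is.na(config$mediatingAssay)) {
    if (!config$mediatingAssay %in% assayNames(sft))
      stopf("mediating assay '%s' not among table assays", config$mediatingAssay)
    keep <- featureMatrix(sft)[, paste0(config$mediatingAssay, "_height")] > 0
  }
  keep <- keep & keyFeatureScore(sft, config$keyFeatures) >= config$minKeyScore
  if (!any(keep))
    warning("filtration retained no segments; downstream pairing will be empty")
  keep
}

#' Anchor coverage as a function of the key-score threshold
#'
#' Replicates the threshold-tuning loop: for every threshold from 0 to the
#' key-set size, reports how many segments survive filtration and what
#' fraction of the provided experimental interactions have both anchors
#' overlapped by at least one retained segment.
#'
#' @param sft a [SegmentFeatureTable-class].
#' @param config a `FiltrationConfig`; `minKeyScore` is swept.
#' @param interactions a [PairedRegions-class] of experimental interactions.
#' @return data.frame with columns `minKeyScore`, `retained`, `coverage`.
#' @export
thresholdScan <- function(sft, config, interactions) {
  out <- lapply(0:length(config$keyFeatures), function(th) {
    cfg <- filtrationConfig(config$mediatingAssay, config$keyFeatures, th)
    keep <- suppressWarnings(filterSegments(sft, cfg))
    segs <- segments(sft)[keep]
    covL <- overlapsAny(leftAnchors(interactions), segs, ignore.strand = TRUE)
    covR <- overlapsAny(rightAnchors(interactions), segs, ignore.strand = TRUE)
    data.frame(minKeyScore = th, retained = sum(keep),
               coverage = if (length(interactions)) mean(covL & covR) else NA_real_)
  })
  do.call(rbind, out)
}
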