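#' Segment-level feature table
#'
#' Rows are fixed-resolution genomic segments; for every assay there are two
#' feature columns: `<assay>_height` (aggregated peak height, 0 when no peak)
#' and `<assay>_summitdist` (bp distance between the selected peak summit and
#' the segment centre; sentinel = resolution when no peak, so "no peak" is
#' monotonically the weakest signal).
#'
#' @slot segments [GenomicRanges::GRanges] of the segments, carrying an
#'   integer metadata column `index` (0-based bin index within chromosome).
#' @slot features numeric matrix, one row per segment, `2 * length(assays)`
#'   columns named `<assay>_height` / `<assay>_summitdist`.
#' @slot assays character vector of assay labels.
#' @slot resolution integer segment width in bp.
#' @export
setClass("SegmentFeatureTable",
  representation(
    segments = "GRanges",
    features = "matrix",
    assays = "character",
    resolution = "integer"
  )
)

setValidity("SegmentFeatureTable", function(object) {
  msg <- character()
  if (length(object@segments) != nrow(object@features))
    msg <- c(msg, "number of segments differs from number of feature rows")
  want <- as.vector(rbind(paste0(object@assays, "_height"),
                          paste0(object@assays, "_summitdist")))
  if (!identical(colnames(object@features), want))
    msg <- c(msg, "feature columns must be <assay>_height, <assay>_summitdist per assay, in assay order")
  if (is.null(object@segments$index))
    msg <- c(msg, "segments must carry an 'index' metadata column")
  h <- object@features[, grep("_height$", colnames(object@features)), drop = FALSE]
  if (length(h) && any(h < 0)) msg <- c(msg, "heights must be non-negative")
  if (length(object@resolution) != 1L || object@resolution <= 0L)
    msg <- c(msg, "resolution must be a single positive integer")
  if (length(msg)) msg else TRUE
})

#' Paired genomic anchors (experimental interactions)
#'
#' BEDPE-semantics container for intra-chromosomal anchor pairs.  Anchors are
#' canonically ordered so the left anchor starts before the right one.
#'
#' @slot left,right [GenomicRanges::GRanges] of equal length; for every
#'   record `seqnames(left) == seqnames(right)` and
#'   `start(left) <= start(right)`.
#' @slot score numeric support per record (e.g. PET count; `NA` if absent).
#' @slot dropped integer count of inter-chromosomal records discarded on read.
#' @export
setClass("PairedRegions",
  representation(
    left = "GRanges",
    right = "GRanges",
    score = "numeric",
    dropped = "integer"
  )
)

setValidity("PairedRegions", function(object) {
  msg <- character()
  if (length(object@left) != length(object@right))
    msg <- c(msg, "left and right anchors differ in length")
  if (length(object@left) != length(object@score))
    msg <- c(msg, "score length differs from number of records")
  if (length(object@left)) {
    if (!all(as.character(seqnames(object@left)) ==
             as.character(seqnames(object@right))))
      msg <- c(msg, "records must be intra-chromosomal")
    if (!all(start(object@left) <= start(object@right)))
      msg <- c(msg, "anchors must be canonically ordered (left starts first)")
  }
  if (any(!is.na(object@score) & object@score < 0))
    msg <- c(msg, "scores must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Sparse Hi-C contact map at fixed resolution
#'
#' Upper-triangle sparse representation: one row per recorded bin pair with
#' `bin_i <= bin_j`; duplicate triples are summed on read.  After
#' [scoreContacts]/[classifyContacts] the table additionally carries
#' `distance` (bin_j - bin_i), `dscore` (distance-stratified midrank
#' percentile in \[0, 1\]; low = stronger than the distance expectation) and
#' `state` (interaction / non_interaction / no_class).
#'
#' @slot contacts data.frame with columns chrom, bin_i, bin_j, count and,
#'   once scored, distance, dscore, state.
#' @slot resolution integer bin width in bp.
#' @export
setClass("ContactMap",
  representation(
    contacts = "data.frame",
    resolution = "integer"
  )
)

setValidity("ContactMap", function(object) {
  msg <- character()
  need <- c("chrom", "bin_i", "bin_j", "count")
  if (!all(need %in% names(object@contacts)))
    msg <- c(msg, paste("contacts must have columns", paste(need, collapse = ", ")))
  else {
    if (any(object@contacts$count < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(object@contacts$bin_i > object@contacts$bin_j))
      msg <- c(msg, "bin_i must not exceed bin_j (canonical upper triangle)")
    if (any(object@contacts$bin_i < 0)) msg <- c(msg, "bin indices must be non-negative")
  }
  if (length(object@resolution) != 1L || object@resolution <= 0L)
    msg <- c(msg, "resolution must be a single positive integer")
  if (length(msg)) msg else TRUE
})

#' Fitted interaction classifier
#'
#' @slot classifier character, one of "random_forest", "svm", "xgboost".
#' @slot fit the fitted model object.
#' @slot featureNames character, feature columns the model was trained on,
#'   in training order; prediction realigns by name.
#' @slot importance named numeric, one non-negative weight per feature
#'   (MeanDecreaseGini for random forests; 0 with a flag for classifiers
#'   exposing no native importance).
#' @slot config list of training settings (seed, ntree, excludeDistance,
#'   classBalance, ...).
#' @export
setClass("LoopModel",
  representation(
    classifier = "character",
    fit = "ANY",
    featureNames = "character",
    importance = "numeric",
    config = "list"
  )
)

setValidity("LoopModel", function(object) {
  msg <- character()
  if (!identical(sort(names(object@importance)), sort(object@featureNames)))
    msg <- c(msg, "importance must be defined for every training feature")
  if (any(object@importance < 0)) msg <- c(msg, "importances must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Evaluation report for interaction predictions
#'
#' Confusion-matrix metrics at a probability cutoff plus cutoff-free AUROC
#' (probability that a randomly chosen interacting pair is ranked above a
#' randomly chosen non-interacting one) and coverage (fraction of truth
#' interactions overlapped, on both anchors, by at least one positive
#' prediction; `NA` when no truth set is supplied).
#'
#' @slot counts named numeric: TP, FP, TN, FN.
#' @slot metrics named numeric: accuracy, sensitivity, specificity, precision.
#' @slot auroc numeric in \[0, 1\].
#' @slot coverage numeric in \[0, 1\] or NA.
#' @slot cutoff probability cutoff used for the binary calls.
#' @export
setClass("EvaluationReport",
  representation(
    counts = "numeric",
    metrics = "numeric",
    auroc = "numeric",
    coverage = "numeric",
    cutoff = "numeric"
  )
)

setMethod("show", "SegmentFeatureTable", function(object) {
  cat("SegmentFeatureTable:", length(object@segments), "segments at",
      object@resolution, "bp,", length(object@assays), "assays\n")
  cat("  assays:", paste(object@assays, collapse = ", "), "\n")
})

setMethod("show", "PairedRegions", function(object) {
  cat("PairedRegions:", length(object@left), "intra-chromosomal anchor pairs")
  if (object@dropped > 0L)
    cat(" (", object@dropped, " inter-chromosomal records dropped)", sep = "")
  cat("\n")
})

setMethod("show", "ContactMap", function(object) {
  cat("ContactMap:", nrow(object@contacts), "bin pairs at",
      object@resolution, "bp resolution",
      if ("dscore" %in% names(object@contacts)) "(scored)" else "(raw)", "\n")
})

setMethod("show", "LoopModel", function(object) {
  cat("LoopModel:", object@classifier, "on",
      length(object@featureNames), "features\n")
  top <- utils::head(sort(object@importance, decreasing = TRUE), 5L)
  cat("  top importance:", paste(names(top), collapse = ", "), "\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport (cutoff ", object@cutoff, ")\n", sep = "")
  cat("  counts:  ", paste(names(object@counts), object@counts,
                           sep = "=", collapse = "  "), "\n")
  cat("  metrics: ", paste(names(object@metrics),
                           sprintf("%.3f", object@metrics),
                           sep = "=", collapse = "  "), "\n")
  cat(sprintf("  AUROC=%.3f  coverage=%s\n", object@auroc,
              ifelse(is.na(object@coverage), "NA",
                     sprintf("%.3f", object@coverage))))
})

setMethod("length", "PairedRegions", function(x) length(x@left))

#' @describeIn SegmentFeatureTable-class segment GRanges accessor
#' @param x a SegmentFeatureTable
#' @export
segments <- function(x) {
  stopifnot(is(x, "SegmentFeatureTable"))
  x@segments
}

#' @describeIn SegmentFeatureTable-class feature matrix accessor
#' @export
featureMatrix <- function(x) {
  stopifnot(is(x, "SegmentFeatureTable"))
  x@features
}

#' @describeIn SegmentFeatureTable-class assay label accessor
#' @export
assayNames <- function(x) {
  stopifnot(is(x, "SegmentFeatureTable"))
  x@assays
}

#' @describeIn SegmentFeatureTable-class resolution (bp) accessor; also works
#'   on ContactMap
#' @export
resolution <- function(x) {
  if (is(x, "SegmentFeatureTable") || is(x, "ContactMap")) return(x@resolution)
  stop("no resolution defined for class ", class(x))
}

#' @describeIn PairedRegions-class left-anchor accessor
#' @param x a PairedRegions
#' @export
leftAnchors <- function(x) { stopifnot(is(x, "PairedRegions")); x@left }

#' @describeIn PairedRegions-class right-anchor accessor
#' @export
rightAnchors <- function(x) { stopifnot(is(x, "PairedRegions")); x@right }

#' @describeIn PairedRegions-class per-record support score accessor
#' @export
interactionScores <- function(x) { stopifnot(is(x, "PairedRegions")); x@score }

#' @describeIn ContactMap-class contact table accessor
#' @param x a ContactMap
#' @export
contactTable <- function(x) { stopifnot(is(x, "ContactMap")); x@contacts }

#' @describeIn LoopModel-class per-feature importance accessor
#' @param x a LoopModel
#' @export
featureImportance <- function(x) { stopifnot(is(x, "LoopModel")); x@importance }

#' @describeIn EvaluationReport-class flatten a report to a named list
#' @param x an EvaluationReport
#' @export
reportAsList <- function(x) {
  stopifnot(is(x, "EvaluationReport"))
  c(as.list(x@counts), as.list(x@metrics),
    list(auroc = x@auroc, coverage = x@coverage, cutoff = x@cutoff))
}
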