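# model feature columns: min/max encodings of all assay features plus pair
# geometry (genomic distance, segment orders within the TAD)
modelFeatureNames <- function(pairs, excludeDistance = FALSE) {
  feats <- grep("^(max|min)_", names(pairs), value = TRUE)
  feats <- c(feats, "left_order", "right_order",
             if (!excludeDistance) "genomic_distance")
  missing <- setdiff(feats, names(pairs))
  if (length(missing))
    stopf("pair table lacks feature column(s): %s", paste(missing, collapse = ", "))
  feats
}

#' Train/test split of labeled pairs
#'
#' Splits at one of four levels: `"pair"` (random pairs — the genome-wide
#' setting; `"genome"` is an alias), `"tad"` or `"chromosome"` (whole groups
#' are assigned to one side, so no group is shared between train and test —
#' the cross-TAD and cross-chromosome settings).  Reproducible given a seed;
#' train and test are disjoint and exhaustive.
#'
#' @param pairs labeled pair data.frame.
#' @param fraction training fraction in (0, 1); default 0.8.
#' @param seed integer seed for the random selection.
#' @param level "pair", "tad", "chromosome" or "genome".
#' @return list with elements `train` and `test`.
#' @export
splitPairs <- function(pairs, fraction = 0.8, seed = NULL,
                       level = c("pair", "tad", "chromosome", "genome")) {
  level <- match.arg(level)
  if (level == "genome") level <- "pair"
  if (fraction <= 0 || fraction >= 1) stopf("fraction must be in (0, 1)")
  n <- nrow(pairs)
  if (n < 2L) stopf("need at least 2 pairs to split")
  if (!is.null(seed)) set.seed(seed)
  if (level == "pair") {
    ntrain <- max(1L, min(n - 1L, round(fraction * n)))
    idx <- sample.int(n, ntrain)
    sel <- rep(FALSE, n); sel[idx] <- TRUE
  } else {
    key <- if (level == "tad") pairs$tad_id else pairs$left_chrom
    groups <- unique(key)
    g <- length(groups)
    if (g < 2L) stopf("need at least 2 %ss to split at level '%s'", level, level)
    ntrain <- max(1L, min(g - 1L, round(fraction * g)))
    sel <- key %in% sample(groups, ntrain)
  }
  if (!any(sel) || all(sel)) stopf("degenerate split: one side is empty")
  list(train = pairs[sel, , drop = FALSE],
       test = pairs[!sel, , drop = FALSE])
}

#' Train an interaction classifier on labeled pairs
#'
#' Fits the default random forest (500 trees, `sqrt(p)` features per split)
#' or a pluggable alternative on the pair features: all `max_*`/`min_*`
#' anchor encodings, the segment orders, and (unless excluded) the genomic
#' distance.  Distance exclusion supports assessing how much of the signal
#' is epigenomic rather than positional.
#'
#' @param train labeled pair data.frame (both classes must be present).
#' @param classifier "random_forest" (default), "svm" (via e1071) or
#'   "xgboost".
#' @param ntree trees for the random forest.
#' @param excludeDistance drop `genomic_distance` from the feature set.
#' @param classBalance "none" (default: train on the full
#'   imbalanced set), "downsample" (majority class downsampled to the
#'   minority size) or "weight" (inverse-frequency class weights).
#' @param seed integer seed for the stochastic fitters.
#' @return a [LoopModel-class].
#' @export
trainModel <- function(train, classifier = c("random_forest", "svm", "xgboost"),
                       ntree = 500L, excludeDistance = FALSE,
                       classBalance = c("none", "downsample", "weight"),
                       seed = NULL) {
  classifier <- match.arg(classifier)
  classBalance <- match.arg(classBalance)
  if (!"label" %in% names(train)) stopf("training pairs carry no 'label' column")
  y <- factor(train$label, levels = c("negative", "positive"))
  tab <- table(y)
  if (any(tab == 0L))
    stopf("training set has no '%s' pairs; both classes are required",
          names(tab)[tab == 0L][1])
  feats <- modelFeatureNames(train, excludeDistance)
  x <- as.matrix(train[, feats, drop = FALSE])
  if (!is.null(seed)) set.seed(seed)
  if (classBalance == "downsample") {
    nmin <- min(tab)
    idx <- unlist(lapply(levels(y), function(l)
      sample(which(y == l), nmin)), use.names = FALSE)
    x <- x[idx, , drop = FALSE]; y <- y[idx]
  }
  wt <- if (classBalance == "weight") as.vector(sum(tab) / (2 * tab)) else NULL
  if (classifier == "random_forest") {
    fit <- randomForest(x, y, ntree = as.integer(ntree),
                        classwt = wt)
    imp <- stats::setNames(as.vector(importance(fit)[, "MeanDecreaseGini"]),
                           rownames(importance(fit)))
    imp <- pmax(imp, 0)
  } else if (classifier == "svm") {
    if (!requireNamespace("e1071", quietly = TRUE))
      stopf("classifier 'svm' needs the e1071 package")
    fit <- e1071::svm(x, y, probability = TRUE,
                      class.weights = if (!is.null(wt))
                        stats::setNames(wt, levels(y)) else NULL)
    imp <- stats::setNames(rep(0, length(feats)), feats)
    warning("svm exposes no native feature importance; importances set to 0")
  } else {
    if (!requireNamespace("xgboost", quietly = TRUE))
      stopf("classifier 'xgboost' needs the xgboost package")
    fit <- xgboost::xgboost(data = x, label = as.integer(y) - 1L,
                            nrounds = 100L, objective = "binary:logistic",
                            weight = if (!is.null(wt)) wt[as.integer(y)] else NULL,
                            verbose = 0)
    gain <- xgboost::xgb.importance(model = fit)
    imp <- stats::setNames(rep(0, length(feats)), feats)
    imp[gain$Feature] <- gain$Gain
  }
  new("LoopModel", classifier = classifier, fit = fit,
      featureNames = feats, importance = imp[feats],
      config = list(classifier = classifier, ntree = as.integer(ntree),
                    excludeDistance = excludeDistance,
                    classBalance = classBalance, seed = seed))
}

#' Predict interaction probabilities for candidate pairs
#'
#' Features are aligned to the model by column name, so a permuted pair
#' table yields identical probabilities.
#'
#' @param model a [LoopModel-class].
#' @param pairs featurized pair data.frame.
#' @return numeric vector of interaction probabilities in `[0, 1]`.
#' @export
predictPairs <- function(model, pairs) {
  if (!nrow(pairs)) return(numeric(0))
  missing <- setdiff(model@featureNames, names(pairs))
  if (length(missing))
    stopf("pair table lacks model feature(s): %s", paste(missing, collapse = ", "))
  x <- as.matrix(pairs[, model@featureNames, drop = FALSE])
  if (model@classifier == "random_forest") {
    unname(predict(model@fit, x, type = "prob")[, "positive"])
  } else if (model@classifier == "svm") {
    p <- predict(model@fit, x, probability = TRUE)
    unname(attr(p, "probabilities")[, "positive"])
  } else {
    unname(predict(model@fit, x))
  }
}

#' Evaluate predictions against labels and experimental truth
#'
#' Binary calls are made at the probability cutoff.  When a truth
#' interaction set is supplied, pairs are (re)labeled against it by the
#' anchor-overlap rule of [labelPairs] — a prediction is a true positive
#' when both its anchors overlap both anchors of some experimental
#' interaction — and coverage is the fraction of truth interactions matched
#' by at least one positive prediction.  Without truth, the pair table's
#' own `label` column is used and coverage is `NA`.  AUROC is the
#' Mann-Whitney rank statistic: the probability that a randomly chosen
#' interacting pair is ranked above a randomly chosen non-interacting one.
#'
#' @param pairs featurized pair data.frame (with `label` unless `truth`
#'   is given).
#' @param prob probabilities from [predictPairs].
#' @param truth optional [PairedRegions-class] of experimental interactions.
#' @param cutoff probability cutoff for binary calls (default 0.5).
#' @return an [EvaluationReport-class].
#' @export
evaluatePairs <- function(pairs, prob, truth = NULL, cutoff = 0.5) {
  if (nrow(pairs) != length(prob))
    stopf("length of prob (%d) differs from number of pairs (%d)",
          length(prob), nrow(pairs))
  if (!is.null(truth)) pairs <- labelPairs(pairs, truth)
  if (!"label" %in% names(pairs))
    stopf("pairs carry no labels and no truth set was supplied")
  pos <- pairs$label == "positive"
  call <- prob >= cutoff
  counts <- c(TP = sum(call & pos), FP = sum(call & !pos),
              TN = sum(!call & !pos), FN = sum(!call & pos))
  metrics <- c(
    accuracy = unname((counts["TP"] + counts["TN"]) / sum(counts)),
    sensitivity = unname(counts["TP"] / (counts["TP"] + counts["FN"])),
    specificity = unname(counts["TN"] / (counts["TN"] + counts["FP"])),
    precision = unname(counts["TP"] / (counts["TP"] + counts["FP"])))
  coverage <- NA_real_
  if (!is.null(truth) && length(truth)) {
    hitL <- findOverlaps(leftAnchors(truth),
                         bedToGRanges(pairs$left_chrom, pairs$left_start,
                                      pairs$left_end)[call],
                         ignore.strand = TRUE)
    hitR <- findOverlaps(rightAnchors(truth),
                         bedToGRanges(pairs$right_chrom, pairs$right_start,
                                      pairs$right_end)[call],
                         ignore.strand = TRUE)
    keyL <- paste(queryHits(hitL), subjectHits(hitL))
    keyR <- paste(queryHits(hitR), subjectHits(hitR))
    coverage <- length(unique(queryHits(hitL)[keyL %in% keyR])) / length(truth)
  }
  new("EvaluationReport", counts = counts, metrics = metrics,
      auroc = aurocScore(prob, pos), coverage = coverage, cutoff = cutoff)
}

#' Feature importance report with chi-square verification
#'
#' Per model feature: the classifier's importance and a chi-square test of
#' independence on the 2x2 table of feature presence (value > 0) against the
#' pair label — most meaningful for height features, where presence means a
#' peak.  Tables with an expected cell below 5 are flagged low-confidence
#' (reported, not suppressed).  Per assay: summed importance over the
#' assay's four pair columns, and the mean total peak height at the two
#' anchors (`max + min` of the height feature, i.e. left + right) in
#' positive versus negative pairs — the signal-vs-background enrichment
#' profile.
#'
#' @param model a [LoopModel-class].
#' @param pairs labeled pair data.frame (typically the training set).
#' @return list with data.frames `features` (feature, importance, chisq,
#'   p_value, low_expected) and `assays` (assay, importance,
#'   mean_sum_height_pos, mean_sum_height_neg).
#' @export
featureReport <- function(model, pairs) {
  if (!"label" %in% names(pairs)) stopf("pairs carry no 'label' column")
  y <- factor(pairs$label, levels = c("negative", "positive"))
  feats <- model@featureNames
  rows <- lapply(feats, function(f) {
    present <- factor(pairs[[f]] > 0, levels = c(FALSE, TRUE))
    tab <- table(present, y)
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
      chi <- NA_real_; p <- NA_real_; low <- TRUE
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      chi <- unname(ct$statistic); p <- unname(ct$p.value)
      low <- any(ct$expected < 5)
    }
    data.frame(feature = f, importance = unname(model@importance[f]),
               chisq = chi, p_value = p, low_expected = low,
               stringsAsFactors = FALSE)
  })
  features <- do.call(rbind, rows)
  features <- features[order(-features$importance), ]
  rownames(features) <- NULL
  heightAssays <- unique(sub("_height$", "",
                             grep("_height$", sub("^(max|min)_", "", feats),
                                  value = TRUE)))
  pos <- y == "positive"
  assays <- do.call(rbind, lapply(heightAssays, function(a) {
    cols <- intersect(paste0(c("max_", "min_"), rep(a, each = 2),
                             c("_height", "_summitdist")), feats)
    sumh <- pairs[[paste0("max_", a, "_height")]] +
      pairs[[paste0("min_", a, "_height")]]
    data.frame(assay = a, importance = sum(model@importance[cols]),
               mean_sum_height_pos = mean(sumh[pos]),
               mean_sum_height_neg = mean(sumh[!pos]),
               stringsAsFactors = FALSE)
  }))
  assays <- assays[order(-assays$importance), ]
  rownames(assays) <- NULL
  list(features = features, assays = assays)
}

#' Serialize / restore a trained model
#'
#' The file embeds a format tag, the package version, the feature list and
#' the training config, enabling cross-dataset prediction (train on one
#' cell line or dataset, predict on another).  A reloaded model yields
#' bit-identical predictions.
#'
#' @param model a [LoopModel-class].
#' @param path file path.
#' @return `loadModel` returns the [LoopModel-class].
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "LoopModel"))
  saveRDS(list(format = "chromloops-model", version = 1L,
               package = as.character(utils::packageVersion("chromloops")),
               model = model), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  checkFile(path)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "chromloops-model"))
    stopf("%s is not a chromloops model file", path)
  obj$model
}
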