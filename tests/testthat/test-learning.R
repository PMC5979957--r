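test_that("pair-level splits are disjoint, exhaustive and reproducible", {
  pairs <- separablePairs(npos = 20, nneg = 80)
  sp <- splitPairs(pairs, 0.8, seed = 42)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$test), 20)
  key <- function(df) paste(rownames(df))
  expect_length(intersect(key(sp$train), key(sp$test)), 0)
  expect_equal(sort(c(key(sp$train), key(sp$test))), sort(key(pairs)))
  sp2 <- splitPairs(pairs, 0.8, seed = 42)
  expect_identical(sp$train, sp2$train)
  expect_error(splitPairs(pairs[1, ], 0.8), "at least 2")
  expect_error(splitPairs(pairs, 1.2), "fraction")
})

test_that("group-level splits never share a TAD or chromosome", {
  b <- simulateBundle(tinyProfile(seed = 13))
  sft <- assignPeaks(binGenome(b$chromSizes, 1000), b$peaks, 1000)
  keep <- filterSegments(sft, defaultFiltration("ctcf_chiapet"))
  pairs <- labelPairs(candidatePairs(sft, keep, b$tads), b$interactions)
  sp <- splitPairs(pairs, 0.8, seed = 1, level = "tad")
  expect_length(intersect(unique(sp$train$tad_id), unique(sp$test$tad_id)), 0)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(pairs))
  # one chromosome only: chromosome-level split must refuse
  expect_error(splitPairs(pairs, 0.8, seed = 1, level = "chromosome"),
               "at least 2")
})

test_that("training requires both classes and reports the missing one", {
  pairs <- separablePairs(npos = 20, nneg = 80)
  onlyNeg <- pairs[pairs$label == "negative", ]
  expect_error(trainModel(onlyNeg, seed = 1), "positive")
})

test_that("a forest separates shifted synthetic data and fails on permuted labels", {
  pairs <- separablePairs(npos = 60, nneg = 240, shift = 5, seed = 3)
  sp <- splitPairs(pairs, 0.8, seed = 3)
  m <- trainModel(sp$train, seed = 3)
  a <- evaluatePairs(sp$test, predictPairs(m, sp$test))@auroc
  expect_gte(a, 0.95)
  # positives in the separable toy score above 0.5 even in-sample
  inProb <- predictPairs(m, sp$train[sp$train$label == "positive", ])
  expect_gte(mean(inProb > 0.5), 0.95)
  expect_gt(median(inProb), 0.8)
  # label permutation destroys the signal (median over a few permutations)
  a0 <- vapply(1:3, function(k) {
    null <- sp$train
    set.seed(k)
    null$label <- sample(null$label)
    m0 <- trainModel(null, seed = k)
    evaluatePairs(sp$test, predictPairs(m0, sp$test))@auroc
  }, numeric(1))
  expect_lt(abs(median(a0) - 0.5), 0.15)
})

test_that("prediction aligns features by name and validates their presence", {
  pairs <- separablePairs(seed = 5)
  m <- trainModel(pairs, seed = 5)
  prob <- predictPairs(m, pairs)
  expect_true(all(prob >= 0 & prob <= 1))
  shuffledCols <- pairs[, sample(names(pairs))]
  expect_identical(predictPairs(m, shuffledCols), prob)
  expect_identical(predictPairs(m, pairs[0, ]), numeric(0))
  broken <- pairs; broken$max_A_height <- NULL
  expect_error(predictPairs(m, broken), "max_A_height")
})

test_that("AUROC equals the exhaustive rank comparison", {
  # 4-pair toy: probabilities 0.9+, 0.4+, 0.6-, 0.2-
  pairs <- data.frame(label = c("positive", "positive", "negative", "negative"))
  rep4 <- evaluatePairs(pairs, c(0.9, 0.4, 0.6, 0.2))
  expect_equal(rep4@auroc, 0.75)
  expect_equal(rep4@auroc, bruteAUROC(c(0.9, 0.4, 0.6, 0.2), c(TRUE, TRUE, FALSE, FALSE)))
  # random toys up to 200 pairs, with ties
  set.seed(17)
  for (trial in 1:5) {
    n <- sample(20:200, 1)
    prob <- round(runif(n), 2)
    lab <- runif(n) < 0.3
    got <- evaluatePairs(data.frame(label = ifelse(lab, "positive", "negative")),
                         prob)@auroc
    expect_equal(got, bruteAUROC(prob, lab), info = paste("trial", trial))
  }
  # perfect ranking
  expect_equal(evaluatePairs(data.frame(label = c("positive", "negative")),
                             c(0.9, 0.1))@auroc, 1.0)
  # independent library cross-check on one of the random toys
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(18)
    prob <- runif(120); lab <- runif(120) < 0.4
    got <- evaluatePairs(data.frame(label = ifelse(lab, "positive", "negative")),
                         prob)@auroc
    ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(
      lab, prob, levels = c(FALSE, TRUE), direction = "<"))))
    expect_equal(got, ref)
  }
})

test_that("confusion-matrix identities hold exactly", {
  lab <- rep(c("positive", "positive", "negative", "negative"), c(8, 2, 85, 5))
  prob <- rep(c(0.9, 0.1, 0.1, 0.9), c(8, 2, 85, 5))
  rep <- evaluatePairs(data.frame(label = lab), prob)
  expect_equal(unname(rep@counts), c(8, 5, 85, 2))  # TP FP TN FN
  expect_equal(unname(rep@metrics["sensitivity"]), 0.8)
  expect_equal(unname(rep@metrics["specificity"]), 85 / 90, tolerance = 1e-3)
  expect_equal(unname(rep@metrics["accuracy"]), 93 / 100)
  expect_equal(unname(rep@metrics["precision"]), 8 / 13)
})

test_that("coverage counts truth interactions matched by positive calls", {
  sft <- toySft(list(A = rep(1, 12)))
  tads <- toyTads(0, 12000)
  pairs <- candidatePairs(sft, rep(TRUE, 12), tads)
  truth <- pairedRegions("chr1", c(1000, 3000), c(2000, 4000),
                         c(9000, 7000), c(10000, 8000))
  # call exactly the pair matching the first truth interaction
  prob <- ifelse(pairs$left_index == 1 & pairs$right_index == 9, 0.9, 0.1)
  rep <- evaluatePairs(pairs, prob, truth = truth)
  expect_equal(rep@coverage, 0.5)
  expect_equal(unname(rep@counts["TP"]), 1)
  # no truth -> coverage NA but metrics still computed from labels
  rep2 <- evaluatePairs(labelPairs(pairs, truth), prob)
  expect_true(is.na(rep2@coverage))
  expect_equal(rep2@auroc, evaluatePairs(pairs, prob, truth = truth)@auroc)
})

test_that("chi-square in the feature report matches the closed form", {
  # presence-vs-label table [[30,10],[10,30]] -> chi-square 20
  n <- 80
  lab <- rep(c("negative", "positive"), each = 40)
  val <- c(rep(0, 30), rep(1, 10), rep(0, 10), rep(1, 30))
  pairs <- data.frame(max_A_height = val, min_A_height = val,
                      label = lab)
  model <- new("LoopModel", classifier = "random_forest", fit = NULL,
               featureNames = c("max_A_height", "min_A_height"),
               importance = c(max_A_height = 1, min_A_height = 0.5),
               config = list())
  fr <- featureReport(model, pairs)
  expect_equal(fr$features$chisq[fr$features$feature == "max_A_height"], 20)
  expect_equal(fr$features$chisq[1], bruteChisq(30, 10, 10, 30))
  # independence -> statistic 0
  balanced <- pairs
  balanced$max_A_height <- rep(c(0, 1), 40)
  balanced$min_A_height <- rep(c(0, 1), 40)
  fr0 <- featureReport(model, balanced)
  expect_equal(fr0$features$chisq, c(0, 0))
  # enrichment summary: positives carry more total anchor height
  expect_gt(fr$assays$mean_sum_height_pos, fr$assays$mean_sum_height_neg)
})

test_that("a serialized model reloads to bit-identical predictions", {
  pairs <- separablePairs(seed = 8)
  sp <- splitPairs(pairs, 0.8, seed = 8)
  m <- trainModel(sp$train, seed = 8)
  path <- file.path(withr::local_tempdir(), "model.rds")
  saveModel(m, path)
  m2 <- loadModel(path)
  expect_identical(predictPairs(m2, sp$test), predictPairs(m, sp$test))
  expect_identical(featureImportance(m2), featureImportance(m))
  junk <- file.path(withr::local_tempdir(), "junk.rds")
  saveRDS(list(a = 1), junk)
  expect_error(loadModel(junk), "not a chromloops model")
})

test_that("distance exclusion removes the distance feature but keeps orders", {
  pairs <- separablePairs(seed = 4)
  m <- trainModel(pairs, excludeDistance = TRUE, seed = 4)
  expect_false("genomic_distance" %in% m@featureNames)
  expect_true(all(c("left_order", "right_order") %in% m@featureNames))
  mFull <- trainModel(pairs, seed = 4)
  expect_true("genomic_distance" %in% mFull@featureNames)
})

test_that("class balancing options fit and predict", {
  pairs <- separablePairs(npos = 30, nneg = 120, seed = 6)
  for (cb in c("downsample", "weight")) {
    m <- trainModel(pairs, classBalance = cb, seed = 6)
    expect_s4_class(m, "LoopModel")
    expect_true(all(predictPairs(m, pairs) >= 0))
  }
})
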