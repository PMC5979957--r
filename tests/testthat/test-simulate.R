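test_that("fixtures encode the intended enrichment structure", {
  ctcf <- makeFixture("ctcf_like")
  expect_equal(ctcf$assays$assay[ctcf$assays$role == "mediator"], "CTCF")
  enriched <- ctcf$assays$assay[ctcf$assays$anchorPresence >
                                  ctcf$assays$backgroundPresence]
  expect_setequal(enriched, c("CTCF", "SA1", "RAD21", "SMC3", "ZNF143"))
  rnap <- makeFixture("rnapii_like")
  expect_equal(rnap$assays$assay[rnap$assays$role == "mediator"], "RNAPII")
  expect_true(all(c("H3K4me1", "H3K4me3", "H3K27ac") %in%
                    rnap$assays$assay[rnap$assays$anchorPresence >
                                        rnap$assays$backgroundPresence]))
  # null: anchor and background peak distributions are identical
  nul <- makeFixture("null")
  expect_equal(nul$assays$anchorPresence, nul$assays$backgroundPresence)
  expect_equal(nul$assays$anchorMeanlog, nul$assays$backgroundMeanlog)
  expect_error(makeFixture("bogus"), "ctcf_like.*rnapii_like.*hic_like.*null")
})

test_that("the same seed reproduces a byte-identical bundle", {
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  simulateBundle(tinyProfile(seed = 21), dir = d1)
  simulateBundle(tinyProfile(seed = 21), dir = d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]),
                     info = basename(f1[i]))
  # a different seed changes the data
  d3 <- file.path(withr::local_tempdir(), "c")
  simulateBundle(tinyProfile(seed = 22), dir = d3)
  expect_false(identical(readLines(file.path(d1, "interactions.bedpe")),
                         readLines(file.path(d3, "interactions.bedpe"))))
})

test_that("labeling the generator's own pair universe recovers the planted loops", {
  b <- simulateBundle(tinyProfile(seed = 19))
  sft <- assignPeaks(binGenome(b$chromSizes, 1000), b$peaks, 1000)
  pairs <- labelPairs(
    candidatePairs(sft, rep(TRUE, length(segments(sft))), b$tads),
    b$interactions)
  pos <- pairs[pairs$label == "positive", ]
  wantL <- start(leftAnchors(b$interactions)) - 1L
  wantR <- start(rightAnchors(b$interactions)) - 1L
  expect_equal(sort(paste(pos$left_start, pos$right_start)),
               sort(paste(wantL, wantR)))
})

test_that("the realized positive fraction lands on the profile's target", {
  prof <- simProfile(positiveFraction = 0.05, seed = 23)  # 2 x 5 Mb toy
  b <- simulateBundle(prof)
  sft <- assignPeaks(binGenome(b$chromSizes, 1000), b$peaks, 1000)
  keep <- filterSegments(sft, defaultFiltration("ctcf_chiapet"))
  pairs <- labelPairs(candidatePairs(sft, keep, b$tads), b$interactions)
  frac <- sum(pairs$label == "positive") / sum(pairs$label == "negative")
  expect_lte(abs(frac - 0.05), 0.02)
})

test_that("infeasible positive fractions fail with the feasible bound", {
  prof <- tinyProfile(seed = 2)
  prof$positiveFraction <- 1e-5  # needs more retained segments than exist
  expect_error(simulateBundle(prof), "feasible")
})

test_that("all truth interactions are intra-TAD and anchors carry the mediator", {
  b <- simulateBundle(tinyProfile(seed = 29))
  l <- leftAnchors(b$interactions); r <- rightAnchors(b$interactions)
  within <- function(gr) {
    hits <- findOverlaps(gr, b$tads, type = "within")
    length(unique(queryHits(hits))) == length(gr)
  }
  expect_true(within(l)); expect_true(within(r))
  ctcf <- b$peaks[b$peaks$assay == "CTCF"]
  expect_true(all(overlapsAny(b$anchors, ctcf)))
})

test_that("without a loop boost, looped and background contacts are exchangeable", {
  prof <- makeFixture("hic_like", seed = 37)
  prof$loopBoost <- 1
  b <- simulateBundle(prof)
  sc <- contactTable(scoreContacts(b$contacts, tads = b$tads))
  loopBins <- paste(as.character(seqnames(leftAnchors(b$interactions))),
                    (start(leftAnchors(b$interactions)) - 1L) %/% 5000,
                    (start(rightAnchors(b$interactions)) - 1L) %/% 5000)
  isLoop <- paste(sc$chrom, sc$bin_i, sc$bin_j) %in% loopBins
  expect_gt(sum(isLoop), 10)
  # dscores of loop bin pairs should look like any other bin pair
  p <- suppressWarnings(wilcox.test(sc$dscore[isLoop], sc$dscore[!isLoop]))$p.value
  expect_gt(p, 0.01)
  # with the default boost the same test rejects decisively
  b2 <- simulateBundle(makeFixture("hic_like", seed = 37))
  sc2 <- contactTable(scoreContacts(b2$contacts, tads = b2$tads))
  isLoop2 <- paste(sc2$chrom, sc2$bin_i, sc2$bin_j) %in% loopBins
  p2 <- suppressWarnings(wilcox.test(sc2$dscore[isLoop2], sc2$dscore[!isLoop2]))$p.value
  expect_lt(p2, 1e-4)
})

test_that("contact counts decay with distance on average", {
  b <- simulateBundle(makeFixture("hic_like", seed = 41))
  df <- contactTable(b$contacts)
  d <- df$bin_j - df$bin_i
  near <- mean(df$count[d <= 3]); far <- mean(df$count[d >= 15])
  expect_gt(near, 3 * far)
})
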