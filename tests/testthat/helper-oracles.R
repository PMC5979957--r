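# Independent brute-force oracles and tiny object builders used across the
# suite.  These deliberately avoid the package's own code paths.

# per-base oracle for peak -> segment aggregation: walks every peak and
# segment as plain data.frames
bruteAggregate <- function(segDf, peakDf, res, mode) {
  n <- nrow(segDf)
  height <- numeric(n)
  sdist <- rep(res, n)
  for (s in seq_len(n)) {
    sigs <- numeric(0); dists <- numeric(0)
    center <- segDf$start[s] + (segDf$end[s] - segDf$start[s]) %/% 2
    for (p in seq_len(nrow(peakDf))) {
      if (peakDf$end[p] <= segDf$start[s] || peakDf$start[p] >= segDf$end[s])
        next  # 0-based half-open, no overlap
      summit <- if (peakDf$summit[p] >= 0) peakDf$start[p] + peakDf$summit[p]
                else peakDf$start[p] + (peakDf$end[p] - peakDf$start[p]) %/% 2
      sigs <- c(sigs, peakDf$signal[p])
      dists <- c(dists, min(abs(summit - center), res))
    }
    if (!length(sigs)) next
    if (mode == "max") {
      height[s] <- max(sigs)
      sdist[s] <- min(dists[sigs == max(sigs)])
    } else {
      height[s] <- sum(sigs)
      sdist[s] <- min(dists)
    }
  }
  list(height = height, sdist = sdist)
}

# exhaustive positive-negative rank comparison
bruteAUROC <- function(prob, positive) {
  p <- prob[positive]; n <- prob[!positive]
  tot <- 0
  for (a in p) for (b in n) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(p) * length(n))
}

# closed-form 2x2 chi-square: n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
bruteChisq <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# midrank percentile over an explicit full population (including zeros)
bruteDscore <- function(value, population) {
  (sum(population > value) + 0.5 * (sum(population == value) - 1)) /
    length(population)
}

# minimal feature table built by hand: heights supplied per assay as a list
# of numeric vectors, summit distances default to the sentinel
toySft <- function(heights, res = 1000L, chrom = "chr1", sdist = NULL) {
  assays <- names(heights)
  n <- length(heights[[1]])
  segs <- binGenome(stats::setNames(n * res, chrom), res)
  feat <- matrix(0, n, 2L * length(assays))
  colnames(feat) <- as.vector(rbind(paste0(assays, "_height"),
                                    paste0(assays, "_summitdist")))
  for (a in assays) {
    feat[, paste0(a, "_height")] <- heights[[a]]
    feat[, paste0(a, "_summitdist")] <-
      if (is.null(sdist)) ifelse(heights[[a]] > 0, 0, res) else sdist[[a]]
  }
  new("SegmentFeatureTable", segments = segs, features = feat,
      assays = assays, resolution = as.integer(res))
}

# one-TAD GRanges covering [start, end) on chrom
toyTads <- function(starts, ends, chrom = "chr1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts + 1L, ends),
                         tad_id = sprintf("tad_%04d", seq_along(starts)))
}

# linearly separable pair table: positives' anchor heights shifted by
# `shift` standard deviations
separablePairs <- function(npos = 40, nneg = 160, shift = 5, seed = 1) {
  set.seed(seed)
  n <- npos + nneg
  lab <- rep(c("positive", "negative"), c(npos, nneg))
  mu <- ifelse(lab == "positive", shift, 0)
  df <- data.frame(tad_id = "tad_0001",
                   left_chrom = "chr1", left_start = 0L, left_end = 1000L,
                   left_index = 0L, right_chrom = "chr1",
                   right_start = 2000L, right_end = 3000L, right_index = 2L,
                   left_order = 0L, right_order = 2L,
                   max_A_height = rnorm(n, mu + 1), min_A_height = rnorm(n, mu),
                   max_A_summitdist = runif(n, 0, 1000),
                   min_A_summitdist = runif(n, 0, 1000),
                   genomic_distance = sample(1:50, n, replace = TRUE) * 1000,
                   stringsAsFactors = FALSE)
  df$label <- lab
  df
}

# small simulation profile for fast unit tests (1 chromosome, ~4 TADs)
tinyProfile <- function(seed = 1, ...) {
  simProfile(chromLengths = c(chr1 = 1.5e6), resolution = 1000L,
             tadLengthRange = c(2.5e5, 3.5e5), loopsPerTad = 2L,
             seed = seed, ...)
}
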