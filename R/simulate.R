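#' Simulation profile for synthetic pipeline inputs
#'
#' Describes a synthetic genome with TADs, per-assay ChIP-seq peak tracks
#' with elevated peak presence and height at loop anchors, intra-TAD truth
#' loops at a controlled positive:negative pair ratio, and a Hi-C contact
#' map with power-law distance decay plus loop enrichment.
#'
#' The `assays` table has one row per assay with columns `assay`, `role`
#' ("mediator", "key_tf", "histone" or "noise"), `anchorPresence` /
#' `backgroundPresence` (peak probability at anchor vs other segments),
#' `anchorMeanlog` / `backgroundMeanlog` / `sdlog` (log-normal peak-height
#' parameters).  For the mediating assay, the number of background
#' mediator-positive segments per TAD is derived from `positiveFraction`:
#' with L planted loops and retained-segment count n, the realized
#' positive:negative ratio is `L / (choose(n, 2) - L)`, so n is chosen as
#' the smallest count with `L / choose(n, 2) <= positiveFraction`.
#'
#' @param chromLengths named chromosome lengths (bp).
#' @param resolution segment resolution (bp) for peaks and truth loops.
#' @param contactResolution bin size (bp) of the simulated contact map.
#' @param tadLengthRange min/max TAD length (bp).
#' @param tadGap gap between consecutive TADs (bp).
#' @param loopsPerTad number of truth loops planted in each TAD; loops have
#'   pairwise-disjoint anchor segments.
#' @param maxLoopSpan maximum anchor-to-anchor span of a planted loop (bp;
#'   `Inf` for uniform pair sampling).  Real loops are short-range relative
#'   to their TAD, which also makes genomic distance an informative feature.
#' @param positiveFraction target positive:negative pair ratio after
#'   mediator filtration, in (0, 0.5); the pipeline's operating band is
#'   0.01-0.1.
#' @param assays assay table (see Details).
#' @param decayAlpha contact distance-decay exponent.
#' @param countScale expected contact count at distance 1.
#' @param loopBoost multiplicative contact enrichment at truth-loop bins.
#' @param seed integer seed; the whole bundle is reproducible from it.
#' @return a list of class `SimProfile`.
#' @seealso [makeFixture] for ready-made profiles, [simulateBundle] to run.
#' @export
simProfile <- function(chromLengths = c(chr1 = 5e6, chr2 = 5e6),
                       resolution = 1000L, contactResolution = 5000L,
                       tadLengthRange = c(3e5, 5e5), tadGap = 2e4,
                       loopsPerTad = 2L, maxLoopSpan = 1.5e5,
                       positiveFraction = 0.05,
                       assays = defaultAssayTable("ctcf_like"),
                       decayAlpha = 1.0, countScale = 60, loopBoost = 4,
                       seed = 1L) {
  need <- c("assay", "role", "anchorPresence", "backgroundPresence",
            "anchorMeanlog", "backgroundMeanlog", "sdlog")
  if (!is.data.frame(assays) || !all(need %in% names(assays)))
    stopf("assays must be a data.frame with columns %s", paste(need, collapse = ", "))
  pr <- c(assays$anchorPresence, assays$backgroundPresence)
  if (any(pr < 0 | pr > 1)) stopf("presence probabilities must lie in [0, 1]")
  enriched <- assays$anchorPresence > assays$backgroundPresence
  if (any(enriched & assays$anchorMeanlog < assays$backgroundMeanlog))
    stopf("enriched assays must have anchor height mean >= background mean")
  if (positiveFraction <= 0 || positiveFraction >= 0.5)
    stopf("positiveFraction must lie in (0, 0.5)")
  if (sum(assays$role == "mediator") > 1L)
    stopf("at most one mediator assay")
  if (resolution <= 0 || contactResolution <= 0)
    stopf("resolutions must be positive")
  structure(list(chromLengths = chromLengths,
                 resolution = as.integer(resolution),
                 contactResolution = as.integer(contactResolution),
                 tadLengthRange = tadLengthRange, tadGap = tadGap,
                 loopsPerTad = as.integer(loopsPerTad),
                 maxLoopSpan = maxLoopSpan,
                 positiveFraction = positiveFraction, assays = assays,
                 decayAlpha = decayAlpha, countScale = countScale,
                 loopBoost = loopBoost, seed = as.integer(seed)),
            class = "SimProfile")
}

defaultAssayTable <- function(kind) {
  row <- function(assay, role, ap, bp, am, bm) {
    data.frame(assay = assay, role = role, anchorPresence = ap,
               backgroundPresence = bp, anchorMeanlog = am,
               backgroundMeanlog = bm, sdlog = 0.5,
               stringsAsFactors = FALSE)
  }
  switch(kind,
    ctcf_like = rbind(
      row("CTCF", "mediator", 1.0, 0.005, 2.2, 1.0),
      row("SA1", "key_tf", 0.9, 0.05, 2.0, 1.0),
      row("RAD21", "key_tf", 0.9, 0.05, 2.0, 1.0),
      row("SMC3", "key_tf", 0.9, 0.05, 2.0, 1.0),
      row("ZNF143", "key_tf", 0.9, 0.05, 2.0, 1.0),
      row("H3K4me1", "noise", 0.1, 0.1, 1.0, 1.0),
      row("H3K27ac", "noise", 0.1, 0.1, 1.0, 1.0),
      row("H3K36me3", "noise", 0.1, 0.1, 1.0, 1.0)),
    rnapii_like = rbind(
      row("RNAPII", "mediator", 1.0, 0.005, 2.2, 1.0),
      row("H3K4me1", "histone", 0.9, 0.05, 2.0, 1.0),
      row("H3K4me3", "histone", 0.9, 0.05, 2.0, 1.0),
      row("H3K27ac", "histone", 0.9, 0.05, 2.0, 1.0),
      row("CTCF", "noise", 0.1, 0.1, 1.0, 1.0),
      row("H3K27me3", "noise", 0.1, 0.1, 1.0, 1.0)),
    null = rbind(
      row("CTCF", "noise", 0.1, 0.1, 1.0, 1.0),
      row("SA1", "noise", 0.1, 0.1, 1.0, 1.0),
      row("RAD21", "noise", 0.1, 0.1, 1.0, 1.0),
      row("H3K4me1", "noise", 0.1, 0.1, 1.0, 1.0),
      row("H3K27ac", "noise", 0.1, 0.1, 1.0, 1.0)),
    stopf("unknown assay table kind: %s", kind))
}

#' Ready-made simulation fixtures
#'
#' * `ctcf_like` — architectural loops: CTCF mediator, the anchor-enriched
#'   factors SA1/RAD21/SMC3/ZNF143, histone marks as unenriched noise;
#'   1 kb segments on 2 x 5 Mb chromosomes.
#' * `rnapii_like` — transcriptional loops: RNAPII mediator with
#'   anchor-enriched H3K4me1/H3K4me3/H3K27ac.
#' * `hic_like` — heatmap route: same enrichment structure as `ctcf_like`
#'   but 5 kb segments matching the contact-map resolution, for the
#'   distance-score/threshold labelling path (no filtration).
#' * `null` — no enrichment anywhere: anchor and background peak
#'   distributions are identical, so classifiers should not beat chance
#'   once genomic distance is excluded.
#'
#' @param name fixture name.
#' @param seed integer seed stored in the profile.
#' @return a `SimProfile`.
#' @export
makeFixture <- function(name = c("ctcf_like", "rnapii_like", "hic_like", "null"),
                        seed = 1L) {
  if (!is.character(name) || !name[1] %in% c("ctcf_like", "rnapii_like",
                                             "hic_like", "null"))
    stopf("unknown fixture '%s'; available: ctcf_like, rnapii_like, hic_like, null",
          name[1])
  name <- match.arg(name)
  switch(name,
    ctcf_like = simProfile(seed = seed),
    rnapii_like = simProfile(assays = defaultAssayTable("rnapii_like"),
                             seed = seed),
    hic_like = simProfile(chromLengths = c(chr1 = 2e6, chr2 = 2e6),
                          resolution = 5000L, contactResolution = 5000L,
                          tadLengthRange = c(1.5e5, 2.5e5),
                          loopsPerTad = 3L, maxLoopSpan = 1e5,
                          positiveFraction = 0.05, seed = seed),
    null = simProfile(chromLengths = c(chr1 = 2e6, chr2 = 2e6),
                      resolution = 5000L, contactResolution = 5000L,
                      tadLengthRange = c(1.5e5, 2e5), loopsPerTad = 10L,
                      maxLoopSpan = Inf, positiveFraction = 0.05,
                      assays = defaultAssayTable("null"), seed = seed))
}

#' Generate a complete synthetic input bundle
#'
#' Produces, fully reproducibly from the profile seed: chromosome sizes,
#' non-overlapping TADs, per-assay peak tracks (peaks at anchor segments
#' with elevated presence probability and log-normal height), intra-TAD
#' truth interactions (anchors are exact segments), and a sparse intra-TAD
#' contact map with Poisson counts around a power-law distance decay,
#' multiplied by `loopBoost` at truth-loop bins.  When `dir` is given the
#' bundle is also written in the standard formats (chrom.sizes, tads.bed,
#' peaks_<assay>.narrowPeak, interactions.bedpe, contacts.tsv, anchors.bed);
#' identical profiles yield byte-identical files.
#'
#' @param profile a `SimProfile` from [simProfile] or [makeFixture].
#' @param dir optional output directory (created if needed).
#' @return invisible list with `chromSizes`, `tads`, `peaks` (GRanges, all
#'   assays), `interactions` ([PairedRegions-class]), `contacts`
#'   ([ContactMap-class]), `anchors` (GRanges of anchor segments), `profile`
#'   and, when written, `files`.
#' @export
simulateBundle <- function(profile, dir = NULL) {
  stopifnot(inherits(profile, "SimProfile"))
  set.seed(profile$seed)
  res <- profile$resolution

  # --- TADs ------------------------------------------------------------
  tadRows <- list()
  for (ch in names(profile$chromLengths)) {
    len <- profile$chromLengths[[ch]]
    pos <- profile$tadGap
    repeat {
      w <- round(runif(1, profile$tadLengthRange[1], profile$tadLengthRange[2]) /
                   res) * res
      if (pos + w > len - profile$tadGap) break
      tadRows[[length(tadRows) + 1L]] <- data.frame(chrom = ch, start = pos,
                                                    end = pos + w)
      pos <- pos + w + profile$tadGap
    }
  }
  tadDf <- do.call(rbind, tadRows)
  tads <- bedToGRanges(tadDf$chrom, tadDf$start, tadDf$end,
                       tad_id = sprintf("tad_%04d", seq_len(nrow(tadDf))))

  # --- loops and mediator-positive segments per TAD --------------------
  L <- profile$loopsPerTad
  f <- profile$positiveFraction
  nTarget <- ceiling((1 + sqrt(1 + 8 * L / f)) / 2)
  loopList <- list(); anchorSeg <- list(); bgSeg <- list(); tadBins <- list()
  for (k in seq_along(tads)) {
    ch <- as.character(seqnames(tads))[k]
    s0 <- start(tads)[k] - 1L; e0 <- end(tads)[k]
    firstBin <- ceiling((s0 - res / 2) / res)
    lastBin <- ceiling((e0 - res / 2) / res) - 1L
    bins <- max(firstBin, 0L):lastBin
    tadBins[[k]] <- data.frame(chrom = ch, bin = bins, stringsAsFactors = FALSE)
    n <- length(bins)
    if (choose(n, 2) < L || n < 2L * L)
      stopf("TAD %s has %d segments; cannot plant %d disjoint loops",
            tads$tad_id[k], n, L)
    if (nTarget > n)
      stopf(paste0("positiveFraction %.3g infeasible for TAD %s: needs %d ",
                   "retained segments but only %d exist (feasible fraction >= %.3g)"),
            f, tads$tad_id[k], nTarget, n, L / choose(n, 2))
    # candidate pairs within the loop span, picked greedily with
    # pairwise-disjoint anchors
    spanBins <- if (is.finite(profile$maxLoopSpan))
      max(1L, floor(profile$maxLoopSpan / res)) else n - 1L
    ci <- rep.int(seq_len(n - 1L), pmin(spanBins, (n - 1L):1L))
    cj <- unlist(lapply(seq_len(n - 1L), function(q)
      (q + 1L):min(n, q + spanBins)))
    ord <- sample.int(length(ci))
    used <- logical(n); i <- integer(L); j <- integer(L); got <- 0L
    for (p in ord) {
      if (used[ci[p]] || used[cj[p]]) next
      got <- got + 1L
      i[got] <- ci[p]; j[got] <- cj[p]
      used[c(ci[p], cj[p])] <- TRUE
      if (got == L) break
    }
    if (got < L)
      stopf("TAD %s: cannot place %d disjoint loops within maxLoopSpan %g",
            tads$tad_id[k], L, profile$maxLoopSpan)
    bi <- bins[i]; bj <- bins[j]
    loopList[[k]] <- data.frame(chrom = ch, bin_l = bi, bin_r = bj,
                                tad = tads$tad_id[k], stringsAsFactors = FALSE)
    anch <- sort(unique(c(bi, bj)))
    anchorSeg[[k]] <- data.frame(chrom = ch, bin = anch, stringsAsFactors = FALSE)
    nb <- max(0L, nTarget - length(anch))
    pool <- setdiff(bins, anch)
    bgSeg[[k]] <- data.frame(chrom = ch,
                             bin = if (nb > 0L) sort(sample(pool, min(nb, length(pool))))
                                   else integer(0),
                             stringsAsFactors = FALSE)
  }
  loops <- do.call(rbind, loopList)
  anchors <- do.call(rbind, anchorSeg)
  background <- do.call(rbind, bgSeg)
  anchorKey <- paste(anchors$chrom, anchors$bin)
  mediatorKey <- c(anchorKey, paste(background$chrom, background$bin))
  tadBinKey <- with(do.call(rbind, tadBins), paste(chrom, bin))

  # --- peaks per assay -------------------------------------------------
  segGrid <- do.call(rbind, lapply(names(profile$chromLengths), function(ch) {
    n <- as.integer(ceiling(profile$chromLengths[[ch]] / res))
    data.frame(chrom = ch, bin = 0:(n - 1L), stringsAsFactors = FALSE)
  }))
  segKey <- paste(segGrid$chrom, segGrid$bin)
  isAnchor <- segKey %in% anchorKey
  peakRows <- list()
  for (r in seq_len(nrow(profile$assays))) {
    a <- profile$assays[r, ]
    if (a$role == "mediator") {
      # in-TAD mediator peaks sit exactly on the anchor + derived background
      # segments (this is what pins the positive:negative ratio); outside
      # TADs the mediator appears at the background rate
      present <- segKey %in% mediatorKey
      present[isAnchor] <- runif(sum(isAnchor)) < a$anchorPresence
      outTad <- !(segKey %in% tadBinKey)
      present[outTad] <- runif(sum(outTad)) < a$backgroundPresence
    } else {
      p <- ifelse(isAnchor, a$anchorPresence, a$backgroundPresence)
      present <- runif(nrow(segGrid)) < p
    }
    idx <- which(present)
    if (!length(idx)) next
    w <- round(runif(length(idx), 150, 400))
    segStart <- segGrid$bin[idx] * res
    segLen <- pmin(segStart + res, profile$chromLengths[segGrid$chrom[idx]]) - segStart
    w <- pmin(w, segLen - 2)
    off <- floor(runif(length(idx)) * (segLen - w))
    meanlog <- ifelse(isAnchor[idx], a$anchorMeanlog, a$backgroundMeanlog)
    peakRows[[length(peakRows) + 1L]] <- data.frame(
      chrom = segGrid$chrom[idx], start = segStart + off, end = segStart + off + w,
      signal = round(rlnorm(length(idx), meanlog, a$sdlog), 3),
      summit = floor(w / 2) + round(runif(length(idx), -0.2, 0.2) * w),
      assay = a$assay, stringsAsFactors = FALSE)
  }
  peakDf <- do.call(rbind, peakRows)
  peakDf$summit <- pmax(0L, pmin(as.integer(peakDf$summit),
                                 peakDf$end - peakDf$start - 1L))
  peaks <- bedToGRanges(peakDf$chrom, peakDf$start, peakDf$end,
                        name = sprintf("peak_%05d", seq_len(nrow(peakDf))),
                        signal = peakDf$signal,
                        summitOffset = peakDf$summit, assay = peakDf$assay)
  peaks <- sort(peaks, ignore.strand = TRUE)

  # --- truth interactions ----------------------------------------------
  chromLen <- profile$chromLengths
  segEnd <- function(ch, bin) pmin((bin + 1) * res, chromLen[ch])
  interactions <- pairedRegions(loops$chrom,
                                loops$bin_l * res, segEnd(loops$chrom, loops$bin_l),
                                loops$bin_r * res, segEnd(loops$chrom, loops$bin_r),
                                score = 2 + rpois(nrow(loops), 3))

  # --- contacts (intra-TAD, contactResolution) -------------------------
  cres <- profile$contactResolution
  loopBinKey <- paste(loops$chrom,
                      (loops$bin_l * res + res %/% 2) %/% cres,
                      (loops$bin_r * res + res %/% 2) %/% cres)
  contactRows <- list()
  for (k in seq_along(tads)) {
    ch <- as.character(seqnames(tads))[k]
    s0 <- start(tads)[k] - 1L; e0 <- end(tads)[k]
    firstBin <- max(ceiling((s0 - cres / 2) / cres), 0)
    lastBin <- ceiling((e0 - cres / 2) / cres) - 1
    bins <- firstBin:lastBin
    n <- length(bins)
    if (n < 2L) next
    i <- rep.int(bins[seq_len(n - 1L)], (n - 1L):1L)
    j <- unlist(lapply(seq_len(n - 1L), function(q) bins[(q + 1L):n]))
    mu <- profile$countScale * (j - i)^(-profile$decayAlpha)
    boost <- paste(ch, i, j) %in% loopBinKey
    mu[boost] <- mu[boost] * profile$loopBoost
    cnt <- rpois(length(mu), mu)
    keep <- cnt > 0
    contactRows[[length(contactRows) + 1L]] <-
      data.frame(chrom = ch, bin_i = i[keep], bin_j = j[keep],
                 count = cnt[keep], stringsAsFactors = FALSE)
  }
  cdf <- do.call(rbind, contactRows)
  cdf <- cdf[order(cdf$chrom, cdf$bin_i, cdf$bin_j), ]
  rownames(cdf) <- NULL
  contacts <- new("ContactMap", contacts = cdf, resolution = cres)

  anchorGr <- bedToGRanges(anchors$chrom, anchors$bin * res,
                           segEnd(anchors$chrom, anchors$bin))
  out <- list(chromSizes = chromLen, tads = tads, peaks = peaks,
              interactions = interactions, contacts = contacts,
              anchors = anchorGr, profile = profile)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(chromsizes = file.path(dir, "chrom.sizes"),
               tads = file.path(dir, "tads.bed"),
               interactions = file.path(dir, "interactions.bedpe"),
               contacts = file.path(dir, "contacts.tsv"),
               anchors = file.path(dir, "anchors.bed"))
    writeChromSizes(chromLen, files["chromsizes"])
    writeTads(tads, files["tads"])
    writeBedpe(interactions, files["interactions"])
    writeContacts(contacts, files["contacts"])
    writeWithHeader(grangesToBed(anchorGr), files["anchors"], col.names = FALSE)
    for (a in unique(profile$assays$assay)) {
      p <- file.path(dir, paste0("peaks_", a, ".narrowPeak"))
      writeNarrowPeak(peaks[peaks$assay == a], p)
      files[paste0("peaks_", a)] <- p
    }
    out$files <- files
  }
  invisible(out)
}
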