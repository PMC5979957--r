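#' Tile the genome into fixed-resolution segments
#'
#' Segments tile each chromosome without gaps or overlaps; the last segment
#' of a chromosome may be shorter than the resolution.  The usual operating
#' points are 1 kb (physical interaction prediction) and 5 kb / 40 kb (Hi-C
#' heatmaps), but any positive resolution is accepted.
#'
#' @param chromSizes named vector of chromosome lengths (bp), as returned by
#'   [readChromSizes].
#' @param resolution segment width in bp (> 0).
#' @return GRanges of segments with an `index` metadata column (0-based bin
#'   index within the chromosome; `start = index * resolution`).
#' @examples
#' binGenome(c(chr1 = 10500), 1000)
#' @export
binGenome <- function(chromSizes, resolution) {
  if (length(resolution) != 1L || is.na(resolution) || resolution <= 0)
    stopf("resolution must be a single positive number")
  if (!length(chromSizes) || is.null(names(chromSizes)))
    stopf("chromSizes must be a named vector of chromosome lengths")
  resolution <- as.integer(resolution)
  sl <- stats::setNames(as.integer(chromSizes), names(chromSizes))
  gr <- tileGenome(sl, tilewidth = resolution, cut.last.tile.in.chrom = TRUE)
  gr$index <- as.integer((start(gr) - 1L) %/% resolution)
  gr
}

#' Assign ChIP-seq peaks to genome segments as a two-feature-per-assay table
#'
#' Every peak contributes to every segment it overlaps.  Per segment and
#' assay, the peak height is the maximum (mode `"max"`) or the sum (mode
#' `"sum"`) of the overlapping peaks' signals; the summit distance is the
#' bp distance between the segment centre and the summit of the peak selected
#' by maximum height (mode `"max"`; ties broken towards the closer summit) or
#' the minimum such distance over contributing peaks (mode `"sum"`).  The
#' summit position is `peak start + summit offset`, or the peak midpoint when
#' the offset is unknown (-1).  Summit distances are capped at the
#' resolution, which is also the no-peak sentinel, so absence of a peak is
#' monotonically the weakest signal (height 0, summit distance = resolution).
#'
#' Mode `"auto"` follows the resolution: maximum for resolutions up to 5 kb
#' (high-resolution physical interactions), sum above (low-resolution
#' heatmaps).
#'
#' @param segs segment GRanges from [binGenome].
#' @param peaks GRanges of peaks from [readNarrowPeak] (multiple assays may
#'   be concatenated with `c()`).
#' @param resolution segment resolution in bp.
#' @param mode aggregation mode: "auto", "max" or "sum".
#' @param assays optional character vector fixing the assay column order;
#'   defaults to the sorted unique assay labels found in `peaks`.
#' @return a [SegmentFeatureTable-class].
#' @export
assignPeaks <- function(segs, peaks, resolution,
                        mode = c("auto", "max", "sum"), assays = NULL) {
  if (!is.character(mode) || !all(mode %in% c("auto", "max", "sum")))
    stopf("unknown aggregation mode: %s", paste(setdiff(mode, c("auto", "max", "sum")), collapse = ", "))
  mode <- match.arg(mode)
  resolution <- as.integer(resolution)
  if (mode == "auto") mode <- if (resolution <= 5000L) "max" else "sum"
  assays <- assays %||% sort(unique(as.character(peaks$assay)))
  nseg <- length(segs)
  feat <- matrix(0, nrow = nseg, ncol = 2L * length(assays))
  colnames(feat) <- as.vector(rbind(paste0(assays, "_height"),
                                    paste0(assays, "_summitdist")))
  for (a in assays) feat[, paste0(a, "_summitdist")] <- resolution

  center0 <- segmentCenter0(segs)
  for (a in assays) {
    pk <- peaks[peaks$assay == a]
    if (!length(pk)) next
    hits <- findOverlaps(segs, pk, ignore.strand = TRUE)
    if (!length(hits)) next
    qi <- queryHits(hits); si <- subjectHits(hits)
    off <- pk$summitOffset[si]
    pstart0 <- start(pk)[si] - 1L
    pwidth <- width(pk)[si]
    summit0 <- ifelse(off >= 0L, pstart0 + off, pstart0 + pwidth %/% 2L)
    sdist <- pmin(abs(summit0 - center0[qi]), resolution)
    sig <- pk$signal[si]
    if (mode == "max") {
      # deterministic winner: highest signal, then closest summit
      o <- order(qi, -sig, sdist)
      first <- o[!duplicated(qi[o])]
      feat[qi[first], paste0(a, "_height")] <- sig[first]
      feat[qi[first], paste0(a, "_summitdist")] <- sdist[first]
    } else {
      s <- rowsum(sig, qi)
      rows <- as.integer(rownames(s))
      feat[rows, paste0(a, "_height")] <- as.vector(s)
      o <- order(qi, sdist)
      first <- o[!duplicated(qi[o])]
      feat[qi[first], paste0(a, "_summitdist")] <- sdist[first]
    }
  }
  new("SegmentFeatureTable", segments = segs, features = feat,
      assays = assays, resolution = resolution)
}
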