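#' Construct a PairedRegions object from coordinates
#'
#' Anchors are canonicalized so the left anchor starts first.  Coordinates
#' are 0-based half-open (as in BEDPE files).
#'
#' @param chrom chromosome per record (intra-chromosomal only).
#' @param leftStart,leftEnd,rightStart,rightEnd anchor coordinates.
#' @param score optional support score (default `NA`).
#' @return a [PairedRegions-class].
#' @export
pairedRegions <- function(chrom, leftStart, leftEnd, rightStart, rightEnd,
                          score = NA_real_) {
  n <- max(length(chrom), length(leftStart))
  chrom <- rep_len(chrom, n)
  score <- rep_len(as.numeric(score), n)
  swap <- rightStart < leftStart
  ls <- ifelse(swap, rightStart, leftStart); le <- ifelse(swap, rightEnd, leftEnd)
  rs <- ifelse(swap, leftStart, rightStart); re <- ifelse(swap, leftEnd, rightEnd)
  new("PairedRegions",
      left = bedToGRanges(chrom, ls, le),
      right = bedToGRanges(chrom, rs, re),
      score = score, dropped = 0L)
}

# tad_id per segment by centre-in-TAD membership (NA outside all TADs);
# centre membership avoids double assignment at TAD borders
tadMembership <- function(segs, tads) {
  centers <- GRanges(seqnames(segs), IRanges(segmentCenter0(segs) + 1L, width = 1L))
  hits <- findOverlaps(centers, tads, ignore.strand = TRUE)
  ids <- rep(NA_character_, length(segs))
  ids[queryHits(hits)] <- tads$tad_id[subjectHits(hits)]
  ids
}

#' Enumerate all intra-TAD pairs of retained segments
#'
#' A segment belongs to a TAD iff its centre lies inside the TAD interval;
#' segments outside every TAD are excluded.  Each TAD with `n` retained
#' segments contributes exactly `choose(n, 2)` pairs; there are no cross-TAD
#' pairs.  Output order is deterministic: by TAD, then left segment index,
#' then right segment index.
#'
#' @param sft a [SegmentFeatureTable-class].
#' @param keep logical vector (or integer indices) of retained segments,
#'   e.g. from [filterSegments].
#' @param tads TAD GRanges from [readTads] (non-overlapping per chromosome).
#' @return data.frame with one row per pair: `tad_id`, left/right segment
#'   coordinates (`*_chrom`, `*_start`, `*_end` in 0-based half-open
#'   convention), bin indices (`left_index`, `right_index`) and 0-based
#'   ranks among the TAD's retained segments (`left_order`, `right_order`).
#' @export
enumeratePairs <- function(sft, keep, tads) {
  segs <- segments(sft)
  if (is.logical(keep)) keep <- which(keep)
  segs <- segs[keep]
  ids <- tadMembership(segs, tads)
  inTad <- !is.na(ids)
  segs <- segs[inTad]; ids <- ids[inTad]
  empty <- data.frame(tad_id = character(),
                      left_chrom = character(), left_start = integer(),
                      left_end = integer(), left_index = integer(),
                      right_chrom = character(), right_start = integer(),
                      right_end = integer(), right_index = integer(),
                      left_order = integer(), right_order = integer(),
                      stringsAsFactors = FALSE)
  if (!length(segs)) return(empty)
  bed <- grangesToBed(segs)
  o <- order(match(ids, tads$tad_id), bed$start)
  bed <- bed[o, ]; ids <- ids[o]; idx <- segs$index[o]
  rank0 <- stats::ave(seq_along(ids), ids, FUN = seq_along) - 1L
  parts <- split(seq_along(ids), factor(ids, levels = unique(ids)))
  rows <- lapply(parts, function(p) {
    n <- length(p)
    if (n < 2L) return(NULL)
    i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
    j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
    cbind(left = p[i], right = p[j])
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(empty)
  data.frame(tad_id = ids[rows[, "left"]],
             left_chrom = bed$chrom[rows[, "left"]],
             left_start = bed$start[rows[, "left"]],
             left_end = bed$end[rows[, "left"]],
             left_index = idx[rows[, "left"]],
             right_chrom = bed$chrom[rows[, "right"]],
             right_start = bed$start[rows[, "right"]],
             right_end = bed$end[rows[, "right"]],
             right_index = idx[rows[, "right"]],
             left_order = rank0[rows[, "left"]],
             right_order = rank0[rows[, "right"]],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Featurize candidate pairs by min/max anchor encoding
#'
#' For every feature column `f` of the segment table (heights and summit
#' distances of all assays), the pair carries `max_f = max(f_left, f_right)`
#' and `min_f = min(f_left, f_right)` — an encoding invariant to anchor
#' order.  `genomic_distance` is the bp distance between the two segment
#' centres.
#'
#' @param pairs data.frame from [enumeratePairs].
#' @param sft the [SegmentFeatureTable-class] the segments came from.
#' @return the input data.frame extended with `max_*`/`min_*` feature
#'   columns and `genomic_distance`.
#' @export
featurizePairs <- function(pairs, sft) {
  if (!nrow(pairs)) {
    for (f in colnames(featureMatrix(sft)))
      pairs[[paste0("max_", f)]] <- pairs[[paste0("min_", f)]] <- numeric(0)
    pairs$genomic_distance <- numeric(0)
    return(pairs)
  }
  segs <- segments(sft)
  key <- paste(as.character(seqnames(segs)), segs$index)
  li <- match(paste(pairs$left_chrom, pairs$left_index), key)
  ri <- match(paste(pairs$right_chrom, pairs$right_index), key)
  if (anyNA(li) || anyNA(ri))
    stopf("pair references a segment missing from the feature table (e.g. %s index %s)",
          pairs$left_chrom[which(is.na(li))[1]] %||% pairs$right_chrom[which(is.na(ri))[1]],
          pairs$left_index[which(is.na(li))[1]] %||% pairs$right_index[which(is.na(ri))[1]])
  fm <- featureMatrix(sft)
  fl <- fm[li, , drop = FALSE]
  fr <- fm[ri, , drop = FALSE]
  mx <- pmax(fl, fr); mn <- pmin(fl, fr)
  colnames(mx) <- paste0("max_", colnames(fm))
  colnames(mn) <- paste0("min_", colnames(fm))
  centers <- segmentCenter0(segs)
  cbind(pairs, as.data.frame(mx), as.data.frame(mn),
        genomic_distance = abs(centers[ri] - centers[li]))
}

#' Enumerate and featurize intra-TAD candidate pairs
#'
#' Convenience wrapper: [enumeratePairs] then [featurizePairs].
#'
#' @inheritParams enumeratePairs
#' @return featurized pair data.frame.
#' @export
candidatePairs <- function(sft, keep, tads) {
  featurizePairs(enumeratePairs(sft, keep, tads), sft)
}

#' Label candidate pairs against experimental interactions
#'
#' A pair is positive iff some interaction on the same chromosome overlaps
#' the pair's left segment with its left anchor AND the pair's right segment
#' with its right anchor; otherwise negative.  Mode `"overlap"` requires at
#' least 1 bp of overlap on each side; `"strict"` requires the segment to
#' coincide exactly with the anchor interval.
#'
#' @param pairs featurized pair data.frame.
#' @param interactions a [PairedRegions-class].
#' @param mode "overlap" (default) or "strict".
#' @return the data.frame with a `label` column ("positive"/"negative").
#' @export
labelPairs <- function(pairs, interactions, mode = c("overlap", "strict")) {
  mode <- match.arg(mode)
  if (!nrow(pairs)) { pairs$label <- character(0); return(pairs) }
  segL <- bedToGRanges(pairs$left_chrom, pairs$left_start, pairs$left_end)
  segR <- bedToGRanges(pairs$right_chrom, pairs$right_start, pairs$right_end)
  type <- if (mode == "strict") "equal" else "any"
  hl <- findOverlaps(segL, leftAnchors(interactions), type = type,
                     ignore.strand = TRUE)
  hr <- findOverlaps(segR, rightAnchors(interactions), type = type,
                     ignore.strand = TRUE)
  keyL <- paste(queryHits(hl), subjectHits(hl))
  keyR <- paste(queryHits(hr), subjectHits(hr))
  pos <- unique(queryHits(hl)[keyL %in% keyR])
  pairs$label <- "negative"
  pairs$label[pos] <- "positive"
  pairs
}
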