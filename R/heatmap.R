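# bin -> stratum bookkeeping.  A bin belongs to a TAD iff its centre lies
# inside the TAD; a stratum is the set of bins of one TAD (or one whole
# chromosome), and its distance-d population size is n_bins - d.

binStratum <- function(chrom, bins, resolution, tads) {
  centers <- GRanges(chrom, IRanges(bins * resolution + resolution %/% 2L + 1L,
                                    width = 1L))
  hits <- findOverlaps(centers, tads, ignore.strand = TRUE)
  ids <- rep(NA_character_, length(bins))
  ids[queryHits(hits)] <- tads$tad_id[subjectHits(hits)]
  ids
}

tadBinRange <- function(tads, resolution) {
  # bins whose centre falls in [start, end): centre of bin b is b*res+res/2
  first <- ceiling(((start(tads) - 1L) - resolution / 2) / resolution)
  last <- ceiling((end(tads) - resolution / 2) / resolution) - 1L
  data.frame(tad_id = tads$tad_id, first = as.integer(pmax(first, 0L)),
             last = as.integer(last))
}

#' Distance-stratified percentile score for Hi-C contacts
#'
#' Hi-C contact counts fall off with genomic distance, so raw counts cannot
#' separate physical interactions from mere proximity.  The distance-based
#' score expresses each contact's strength relative to all bin pairs of the
#' same stratum (a TAD, or a whole chromosome) at the same bin distance: it
#' is the midrank percentile
#' `(#stronger + 0.5 * #equal-others) / N_d` over the `N_d` bin pairs of
#' that stratum-distance, where bin pairs with no recorded contact enter the
#' population as count 0.  Low scores mean stronger than the distance
#' expectation; the score is in `[0, 1]`, is invariant to rescaling all
#' counts in a stratum and is monotone decreasing in the count.
#'
#' With `stratum = "tad"`, contacts whose two bins do not lie in one common
#' TAD are dropped (with a message); training and prediction operate per TAD.
#'
#' @param cm a [ContactMap-class].
#' @param tads TAD GRanges (required for `stratum = "tad"`).
#' @param chromSizes named chromosome lengths (required for
#'   `stratum = "chromosome"`).
#' @param stratum "tad" (default) or "chromosome".
#' @return the ContactMap with `distance` and `dscore` columns added (and a
#'   `stratum` column naming the TAD).
#' @export
scoreContacts <- function(cm, tads = NULL, chromSizes = NULL,
                          stratum = c("tad", "chromosome")) {
  stratum <- match.arg(stratum)
  df <- contactTable(cm)
  res <- resolution(cm)
  if (!nrow(df)) {
    df$distance <- integer(); df$dscore <- numeric(); df$stratum <- character()
    return(new("ContactMap", contacts = df, resolution = res))
  }
  if (stratum == "tad") {
    if (is.null(tads)) stopf("stratum = 'tad' requires TAD coordinates")
    si <- binStratum(df$chrom, df$bin_i, res, tads)
    sj <- binStratum(df$chrom, df$bin_j, res, tads)
    ok <- !is.na(si) & !is.na(sj) & si == sj
    if (any(!ok))
      message(sum(!ok), " contact(s) outside a common TAD dropped")
    df <- df[ok, , drop = FALSE]
    df$stratum <- si[ok]
    rng <- tadBinRange(tads, res)
    nbins <- stats::setNames(rng$last - rng$first + 1L, rng$tad_id)
  } else {
    if (is.null(chromSizes)) stopf("stratum = 'chromosome' requires chromSizes")
    bad <- which(!(df$chrom %in% names(chromSizes)))
    if (length(bad)) stopf("contact on unknown chromosome %s", df$chrom[bad[1]])
    nbins <- stats::setNames(as.integer(ceiling(chromSizes / res)),
                             names(chromSizes))
    over <- df$bin_j >= nbins[df$chrom]
    if (any(over))
      stopf("bin index %d beyond chromosome %s", df$bin_j[which(over)[1]],
            df$chrom[which(over)[1]])
    df$stratum <- df$chrom
  }
  if (!nrow(df)) {
    df$distance <- integer(); df$dscore <- numeric()
    return(new("ContactMap", contacts = df[, c("chrom", "bin_i", "bin_j",
                                               "count", "distance", "dscore",
                                               "stratum")],
               resolution = res))
  }
  df$distance <- df$bin_j - df$bin_i
  df$dscore <- NA_real_
  grp <- paste(df$stratum, df$distance)
  for (g in unique(grp)) {
    rows <- which(grp == g)
    counts <- df$count[rows]
    n <- nbins[[df$stratum[rows[1]]]]
    Nd <- n - df$distance[rows[1]]
    if (length(rows) > Nd)
      stopf("stratum %s has %d recorded contacts at distance %d but only %d bin pairs",
            df$stratum[rows[1]], length(rows), df$distance[rows[1]], Nd)
    nzero <- Nd - length(rows)  # implicit count-0 bin pairs
    greater <- vapply(counts, function(c) sum(counts > c), numeric(1))
    equal <- vapply(counts, function(c) sum(counts == c) - 1, numeric(1)) +
      ifelse(counts == 0, nzero, 0)
    df$dscore[rows] <- (greater + 0.5 * equal) / Nd
  }
  rownames(df) <- NULL
  new("ContactMap", contacts = df, resolution = res)
}

#' Three-class labelling of scored contacts
#'
#' With threshold `theta`, a contact is an `interaction` when its
#' distance-based score is at most `theta`, a `non_interaction` when the
#' score is at least `1 - theta`, and `no_class` otherwise.  The default
#' `theta = 0.15` keeps high coverage of physical interactions while
#' excluding the ambiguous middle band from training; `theta = 0.5`
#' eliminates the no-class band entirely.
#'
#' @param cm a scored [ContactMap-class] from [scoreContacts].
#' @param theta threshold in (0, 0.5].
#' @return the ContactMap with a `state` column added.
#' @export
classifyContacts <- function(cm, theta = 0.15) {
  if (length(theta) != 1L || is.na(theta) || theta <= 0 || theta > 0.5)
    stopf("theta must lie in (0, 0.5]")
  df <- contactTable(cm)
  if (!"dscore" %in% names(df))
    stopf("contacts are not scored; run scoreContacts() first")
  df$state <- ifelse(df$dscore <= theta, "interaction",
                     ifelse(df$dscore >= 1 - theta, "non_interaction",
                            "no_class"))
  new("ContactMap", contacts = df, resolution = resolution(cm))
}

#' Convert classified contacts into labeled candidate pairs
#'
#' Bridges the heatmap route into the supervised-learning machinery:
#' `interaction` contacts become positive pairs, `non_interaction` contacts
#' negative pairs, `no_class` contacts are dropped (never trained on).
#' Diagonal contacts (`bin_i == bin_j`) are dropped too, since a candidate
#' pair needs a positive genomic distance.  Features are attached by
#' [featurizePairs]; segment orders are ranks among the TAD's segments.
#'
#' @param cm a classified [ContactMap-class] from [classifyContacts].
#' @param sft a [SegmentFeatureTable-class] at the same resolution.
#' @param tads TAD GRanges.
#' @return labeled, featurized pair data.frame.
#' @export
contactsToPairs <- function(cm, sft, tads) {
  if (resolution(cm) != resolution(sft))
    stopf("contact resolution (%d) differs from segment resolution (%d)",
          resolution(cm), resolution(sft))
  df <- contactTable(cm)
  if (!"state" %in% names(df))
    stopf("contacts are not classified; run classifyContacts() first")
  df <- df[df$state != "no_class" & df$bin_i < df$bin_j, , drop = FALSE]
  segs <- segments(sft)
  key <- paste(as.character(seqnames(segs)), segs$index)
  li <- match(paste(df$chrom, df$bin_i), key)
  ri <- match(paste(df$chrom, df$bin_j), key)
  if (anyNA(li) || anyNA(ri))
    stopf("contact bin beyond the binned genome (e.g. %s bin %d)",
          df$chrom[which(is.na(li) | is.na(ri))[1]],
          df$bin_j[which(is.na(li) | is.na(ri))[1]])
  ids <- tadMembership(segs, tads)
  # orders among all segments of the TAD (heatmaps apply no filtration)
  ord <- rep(NA_integer_, length(segs))
  inTad <- which(!is.na(ids))
  o <- inTad[order(ids[inTad], start(segs)[inTad])]
  ord[o] <- stats::ave(seq_along(o), ids[o], FUN = seq_along) - 1L
  bed <- grangesToBed(segs)
  pairs <- data.frame(tad_id = df$stratum %||% ids[li],
                      left_chrom = bed$chrom[li], left_start = bed$start[li],
                      left_end = bed$end[li], left_index = segs$index[li],
                      right_chrom = bed$chrom[ri], right_start = bed$start[ri],
                      right_end = bed$end[ri], right_index = segs$index[ri],
                      left_order = ord[li], right_order = ord[ri],
                      stringsAsFactors = FALSE, row.names = NULL)
  pairs <- featurizePairs(pairs, sft)
  pairs$label <- ifelse(df$state == "interaction", "positive", "negative")
  pairs
}

#' Write / read scored contacts as TSV
#'
#' Columns: chrom, bin_i, bin_j, count and, when present, distance, dscore,
#' state, stratum.  The resolution is stored in a `#` header line so
#' [readScoredContacts] can reconstruct the [ContactMap-class].
#'
#' @param cm a [ContactMap-class].
#' @param path file path.
#' @param header optional extra provenance comment.
#' @export
writeScoredContacts <- function(cm, path, header = NULL) {
  meta <- sprintf("resolution=%d", resolution(cm))
  writeWithHeader(contactTable(cm), path, header = c(header, meta))
}

#' @rdname writeScoredContacts
#' @export
readScoredContacts <- function(path) {
  checkFile(path)
  hdr <- grep("^#", readLines(path, n = 10L), value = TRUE)
  meta <- grep("resolution=", hdr, value = TRUE)
  if (!length(meta)) stopf("%s: missing resolution header", path)
  res <- as.integer(sub(".*resolution=(\\d+).*", "\\1", meta[1]))
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  new("ContactMap", contacts = df, resolution = res)
}
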