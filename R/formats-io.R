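#' Read ChIP-seq peaks from a narrowPeak or BED file
#'
#' Accepts ENCODE narrowPeak (BED6+4, 10 columns: the 7th is signalValue and
#' the 10th the summit offset from the peak start) or plain 6-column BED, in
#' which case the BED score column is used as the peak height and the summit
#' offset is recorded as unknown (-1).  Lines starting with `#` are skipped.
#'
#' @param path path to the peak file.
#' @param assay assay label attached to every record (e.g. "CTCF").
#' @return a [GenomicRanges::GRanges], sorted by (chrom, start), with metadata
#'   columns `name`, `signal` (non-negative peak height), `summitOffset`
#'   (0-based offset of the summit from the peak start, or -1 when unknown)
#'   and `assay`.
#' @export
readNarrowPeak <- function(path, assay) {
  checkFile(path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(name = character(), signal = numeric(),
                           summitOffset = integer(), assay = character())
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 6L | (nf > 6L & nf < 10L))
  if (length(bad))
    stopf("%s:%d: expected 6 (BED) or >=10 (narrowPeak) tab-separated columns, got %d",
          path, lineno[bad[1]], nf[bad[1]])
  get <- function(i) vapply(fields, `[`, character(1), i)
  chrom <- get(1)
  start0 <- suppressWarnings(as.integer(get(2)))
  end0 <- suppressWarnings(as.integer(get(3)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stopf("%s:%d: non-integer coordinates", path, lineno[bad[1]])
  bad <- which(start0 < 0L)
  if (length(bad))
    stopf("%s:%d: negative start coordinate", path, lineno[bad[1]])
  bad <- which(end0 <= start0)
  if (length(bad))
    stopf("%s:%d: end <= start", path, lineno[bad[1]])
  name <- get(4)
  narrow <- nf >= 10L
  signal <- ifelse(narrow,
                   suppressWarnings(as.numeric(vapply(fields, function(f)
                     if (length(f) >= 7L) f[7] else NA_character_, character(1)))),
                   suppressWarnings(as.numeric(get(5))))
  bad <- which(is.na(signal) | signal < 0)
  if (length(bad))
    stopf("%s:%d: peak height must be a non-negative number", path, lineno[bad[1]])
  summit <- ifelse(narrow,
                   suppressWarnings(as.integer(vapply(fields, function(f)
                     if (length(f) >= 10L) f[10] else "-1", character(1)))),
                   -1L)
  summit[is.na(summit)] <- -1L
  width <- end0 - start0
  bad <- which(summit != -1L & (summit < 0L | summit >= width))
  if (length(bad))
    stopf("%s:%d: summit offset outside [0, peak width)", path, lineno[bad[1]])
  gr <- bedToGRanges(chrom, start0, end0,
                     name = name, signal = signal,
                     summitOffset = as.integer(summit),
                     assay = rep(assay, length(chrom)))
  sort(gr, ignore.strand = TRUE)
}

#' Write peaks as narrowPeak
#'
#' @param peaks GRanges as returned by [readNarrowPeak].
#' @param path output path.
#' @param header optional provenance comment written as a `#` line.
#' @export
writeNarrowPeak <- function(peaks, path, header = NULL) {
  bed <- grangesToBed(peaks)
  df <- data.frame(bed,
                   name = peaks$name %||% paste0("peak_", seq_along(peaks)),
                   score = 0L, strand = ".",
                   signal = formatSignal(peaks$signal),
                   pValue = -1L, qValue = -1L,
                   summit = peaks$summitOffset,
                   stringsAsFactors = FALSE)
  writeWithHeader(df, path, header = header, col.names = FALSE)
}

#' Read anchor pairs from a BEDPE file
#'
#' Requires at least 6 tab-separated columns (chrom1 start1 end1 chrom2
#' start2 end2); an optional numeric 7th column is taken as the support
#' score (e.g. a PET count).  Anchors are reordered so the left anchor starts
#' first; inter-chromosomal records are dropped and counted (the pipeline
#' predicts intra-TAD pairs only).
#'
#' @param path path to the BEDPE file.
#' @return a [PairedRegions-class].
#' @export
readBedpe <- function(path) {
  checkFile(path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines))
    return(new("PairedRegions", left = GRanges(), right = GRanges(),
               score = numeric(), dropped = 0L))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 6L)
  if (length(bad))
    stopf("%s:%d: BEDPE needs >= 6 tab-separated columns, got %d",
          path, lineno[bad[1]], nf[bad[1]])
  get <- function(i) vapply(fields, `[`, character(1), i)
  c1 <- get(1); c2 <- get(4)
  s1 <- suppressWarnings(as.integer(get(2))); e1 <- suppressWarnings(as.integer(get(3)))
  s2 <- suppressWarnings(as.integer(get(5))); e2 <- suppressWarnings(as.integer(get(6)))
  bad <- which(is.na(s1) | is.na(e1) | is.na(s2) | is.na(e2))
  if (length(bad)) stopf("%s:%d: non-integer coordinates", path, lineno[bad[1]])
  bad <- which(s1 < 0L | s2 < 0L)
  if (length(bad)) stopf("%s:%d: negative coordinate", path, lineno[bad[1]])
  bad <- which(e1 <= s1 | e2 <= s2)
  if (length(bad)) stopf("%s:%d: anchor end <= start", path, lineno[bad[1]])
  score <- rep(NA_real_, length(lines))
  has7 <- nf >= 7L
  score[has7] <- suppressWarnings(as.numeric(vapply(fields[has7], `[`,
                                                   character(1), 7)))
  intra <- c1 == c2
  dropped <- sum(!intra)
  if (dropped)
    message(dropped, " inter-chromosomal record(s) dropped from ", path)
  c1 <- c1[intra]
  s1 <- s1[intra]; e1 <- e1[intra]; s2 <- s2[intra]; e2 <- e2[intra]
  score <- score[intra]
  swap <- s2 < s1
  ls <- ifelse(swap, s2, s1); le <- ifelse(swap, e2, e1)
  rs <- ifelse(swap, s1, s2); re <- ifelse(swap, e1, e2)
  new("PairedRegions",
      left = bedToGRanges(c1, ls, le),
      right = bedToGRanges(c1, rs, re),
      score = score, dropped = as.integer(dropped))
}

#' Write anchor pairs as BEDPE
#'
#' Writes the 6 coordinate columns plus a 7th numeric column: the record
#' score, or the supplied prediction probabilities.
#'
#' @param pairs a [PairedRegions-class].
#' @param path output path.
#' @param prob optional numeric vector of prediction probabilities written as
#'   the 7th column instead of the score.
#' @param header optional provenance comment.
#' @export
writeBedpe <- function(pairs, path, prob = NULL, header = NULL) {
  l <- grangesToBed(leftAnchors(pairs))
  r <- grangesToBed(rightAnchors(pairs))
  col7 <- prob %||% interactionScores(pairs)
  col7 <- ifelse(is.na(col7), ".", formatSignal(col7))
  df <- data.frame(l$chrom, l$start, l$end, r$chrom, r$start, r$end, col7,
                   stringsAsFactors = FALSE)
  writeWithHeader(df, path, header = header, col.names = FALSE)
}

#' Read a sparse Hi-C contact file
#'
#' Accepts 4 columns (chrom, bin_i, bin_j, count) or 3 columns (bin_i, bin_j,
#' count, all assigned to `chrom`).  Triples with `bin_i > bin_j` are
#' mirrored into the upper triangle; duplicates are summed.
#'
#' @param path path to the contact file.
#' @param resolution bin width in bp.
#' @param chrom chromosome assigned to 3-column input.
#' @return a [ContactMap-class].
#' @export
readContacts <- function(path, resolution, chrom = "chr1") {
  checkFile(path)
  if (resolution <= 0) stopf("resolution must be positive")
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines))
    return(new("ContactMap",
               contacts = data.frame(chrom = character(), bin_i = integer(),
                                     bin_j = integer(), count = numeric()),
               resolution = as.integer(resolution)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 3L & nf != 4L)
  if (length(bad))
    stopf("%s:%d: expected 3 or 4 tab-separated columns, got %d",
          path, lineno[bad[1]], nf[bad[1]])
  off <- as.integer(nf == 4L)
  ch <- ifelse(nf == 4L, vapply(fields, `[`, character(1), 1), chrom)
  gi <- suppressWarnings(as.integer(mapply(function(f, o) f[1 + o], fields, off)))
  gj <- suppressWarnings(as.integer(mapply(function(f, o) f[2 + o], fields, off)))
  ct <- suppressWarnings(as.numeric(mapply(function(f, o) f[3 + o], fields, off)))
  bad <- which(is.na(gi) | is.na(gj) | is.na(ct))
  if (length(bad)) stopf("%s:%d: malformed contact triple", path, lineno[bad[1]])
  bad <- which(ct < 0)
  if (length(bad)) stopf("%s:%d: negative contact count", path, lineno[bad[1]])
  bad <- which(gi < 0L | gj < 0L)
  if (length(bad)) stopf("%s:%d: negative bin index", path, lineno[bad[1]])
  bi <- pmin(gi, gj); bj <- pmax(gi, gj)
  df <- data.frame(chrom = ch, bin_i = bi, bin_j = bj, count = ct,
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(count ~ chrom + bin_i + bin_j, df, sum)
  agg <- agg[order(agg$chrom, agg$bin_i, agg$bin_j), c("chrom", "bin_i", "bin_j", "count")]
  rownames(agg) <- NULL
  new("ContactMap", contacts = agg, resolution = as.integer(resolution))
}

#' Write a contact map as sparse 4-column text
#' @param cm a [ContactMap-class].
#' @param path output path.
#' @param header optional provenance comment.
#' @export
writeContacts <- function(cm, path, header = NULL) {
  df <- contactTable(cm)[, c("chrom", "bin_i", "bin_j", "count")]
  df$count <- formatSignal(df$count)
  writeWithHeader(df, path, header = header, col.names = FALSE)
}

#' Read a two-column chrom.sizes file
#' @param path path to the file (chrom\\tlength).
#' @return named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  checkFile(path)
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "numeric"))
  df$length <- as.integer(df$length)
  if (any(df$length <= 0)) stopf("%s: non-positive chromosome length", path)
  if (anyDuplicated(df$chrom)) stopf("%s: duplicated chromosome name", path)
  stats::setNames(df$length, df$chrom)
}

#' Write chromosome sizes
#' @param chromSizes named integer vector.
#' @param path output path.
#' @export
writeChromSizes <- function(chromSizes, path) {
  writeWithHeader(data.frame(names(chromSizes),
                             sprintf("%d", as.integer(chromSizes))),
                  path, col.names = FALSE)
}

#' Read TAD (or CCD) coordinates from BED3/BED4
#'
#' TADs on one chromosome must be non-overlapping; an overlap is an error.
#'
#' @param path path to the BED file.
#' @return GRanges with a `tad_id` metadata column (column 4, or generated
#'   `tad_<n>` identifiers for BED3).
#' @export
readTads <- function(path) {
  checkFile(path)
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE, fill = TRUE)
  if (ncol(df) < 3L) stopf("%s: BED needs >= 3 columns", path)
  if (any(df[[2]] < 0)) stopf("%s: negative coordinate", path)
  if (any(df[[3]] <= df[[2]])) stopf("%s: TAD end <= start", path)
  ids <- if (ncol(df) >= 4L && !all(is.na(df[[4]]))) as.character(df[[4]])
         else sprintf("tad_%04d", seq_len(nrow(df)))
  gr <- bedToGRanges(df[[1]], df[[2]], df[[3]], tad_id = ids)
  gr <- sort(gr, ignore.strand = TRUE)
  hits <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE,
                       ignore.strand = TRUE)
  if (length(hits))
    stopf("%s: overlapping TADs on %s (e.g. %s and %s)", path,
          as.character(seqnames(gr))[queryHits(hits)[1]],
          gr$tad_id[queryHits(hits)[1]], gr$tad_id[subjectHits(hits)[1]])
  gr
}

#' Write TADs as BED4
#' @param tads GRanges with `tad_id`.
#' @param path output path.
#' @export
writeTads <- function(tads, path) {
  df <- data.frame(grangesToBed(tads), id = tads$tad_id)
  writeWithHeader(df, path, col.names = FALSE)
}

#' Write a segment feature table as TSV
#'
#' Columns: chrom, start, end, index, then `<assay>_height` /
#' `<assay>_summitdist` per assay.  Resolution and assay list are stored in a
#' `#` header so [readFeatureTable] can reconstruct the object.
#'
#' @param sft a [SegmentFeatureTable-class].
#' @param path output path.
#' @param header optional extra provenance comment.
#' @export
writeFeatureTable <- function(sft, path, header = NULL) {
  seg <- grangesToBed(segments(sft))
  df <- data.frame(seg, index = segments(sft)$index, featureMatrix(sft),
                   check.names = FALSE)
  meta <- sprintf("resolution=%d assays=%s", resolution(sft),
                  paste(assayNames(sft), collapse = ","))
  writeWithHeader(df, path, header = c(header, meta))
}

#' Read a segment feature table written by [writeFeatureTable]
#' @param path path to the TSV.
#' @return a [SegmentFeatureTable-class].
#' @export
readFeatureTable <- function(path) {
  checkFile(path)
  hdr <- grep("^#", readLines(path, n = 10L), value = TRUE)
  meta <- grep("resolution=", hdr, value = TRUE)
  if (!length(meta)) stopf("%s: missing resolution/assays header", path)
  res <- as.integer(sub(".*resolution=(\\d+).*", "\\1", meta[1]))
  assays <- strsplit(sub(".*assays=([^ ]+).*", "\\1", meta[1]), ",")[[1]]
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  gr <- bedToGRanges(df$chrom, df$start, df$end, index = df$index)
  feat <- as.matrix(df[, setdiff(names(df), c("chrom", "start", "end", "index")),
                       drop = FALSE])
  new("SegmentFeatureTable", segments = gr, features = feat,
      assays = assays, resolution = res)
}

#' Write / read a candidate-pair table as TSV
#'
#' Plain TSV persistence of the pair data.frame produced by
#' [candidatePairs]; column structure is preserved exactly.
#'
#' @param pairs pair data.frame.
#' @param path file path.
#' @param header optional provenance comment.
#' @export
writePairTable <- function(pairs, path, header = NULL) {
  writeWithHeader(pairs, path, header = header)
}

#' @rdname writePairTable
#' @export
readPairTable <- function(path) {
  checkFile(path)
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             check.names = FALSE, stringsAsFactors = FALSE)
}
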