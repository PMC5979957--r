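# Internal helpers.  Coordinate convention: files are BED 0-based half-open;
# GRanges are 1-based closed.  bedToGRanges/grangesToBed are the only two
# places that convert.

bedToGRanges <- function(chrom, start0, end0, ...) {
  GRanges(chrom, IRanges(start0 + 1L, end0), ...)
}

grangesToBed <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)),
             start = start(gr) - 1L, end = end(gr),
             stringsAsFactors = FALSE)
}

# segment centre: start + floor(width/2) in 0-based coordinates
segmentCenter0 <- function(gr) {
  (start(gr) - 1L) + (end(gr) - start(gr) + 1L) %/% 2L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

checkFile <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  invisible(path)
}

# Mann-Whitney rank AUROC: probability a random positive outranks a random
# negative (ties count 1/2).
aurocScore <- function(prob, positive) {
  positive <- as.logical(positive)
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(prob)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

# fixed decimal formatting for floats written to text formats (bit-exact
# round trips); integers written as-is
formatSignal <- function(x) {
  ifelse(x == round(x), sprintf("%d", as.integer(round(x))), sprintf("%.6g", x))
}

writeWithHeader <- function(df, path, header = NULL, col.names = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col.names)
  invisible(path)
}

provenanceHeader <- function(config = NULL) {
  h <- paste0("chromloops ", as.character(utils::packageVersion("chromloops")))
  if (!is.null(config)) {
    hash <- substr(digestConfig(config), 1, 12)
    h <- paste0(h, " config:", hash)
  }
  h
}

# config hash without external digest dependency: md5 of the deparsed config
digestConfig <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(config[order(names(config))]), collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
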