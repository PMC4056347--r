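# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a GRanges from 0-based half-open interval columns
#' @noRd
.as_granges0 <- function(df, chrom = "chrom", start = "start", end = "end") {
  GenomicRanges::GRanges(
    seqnames = df[[chrom]],
    ranges = IRanges::IRanges(start = df[[start]] + 1L, end = df[[end]])
  )
}

#' Point positions (1-based) as width-1 GRanges
#' @noRd
.as_granges_pos <- function(df, chrom = "chrom", pos = "pos") {
  GenomicRanges::GRanges(
    seqnames = df[[chrom]],
    ranges = IRanges::IRanges(start = df[[pos]], width = 1L)
  )
}

#' findOverlaps wrappers tolerant of disjoint seqlevels
#' @noRd
.fo_first <- function(query, subject) {
  suppressWarnings(GenomicRanges::findOverlaps(query, subject,
                                               select = "first"))
}

#' @noRd
.fo_all <- function(query, subject) {
  suppressWarnings(GenomicRanges::findOverlaps(query, subject))
}

#' Variant identity key (position + alleles)
#' @noRd
.variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Stable empty data.frame with given column names/types
#' @noRd
.empty_df <- function(proto) proto[0L, , drop = FALSE]

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}
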