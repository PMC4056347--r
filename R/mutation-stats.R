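#' Somatic mutation rate over the sufficiently covered CDS
#'
#' Mutations (SNVs and small indels) falling inside the coverage mask are
#' counted against the mask size: `rate = count / (mask megabases)`. The
#' mask should contain the coding intervals whose read depth reached the
#' study's floor (at least 5 reads).
#'
#' @param variants Variant `data.frame` with `chrom`, `pos`.
#' @param mask `data.frame(chrom, start, end)`, 0-based half-open,
#'   non-empty.
#' @return Mutations per Mb (single numeric), with attributes `n_mutations`
#'   and `mask_bases`.
#' @examples
#' m <- data.frame(chrom = "chr1", start = 0, end = 10e6)
#' v <- data.frame(chrom = "chr1", pos = seq(1, 1e6, length.out = 50))
#' mutation_rate(v, m)  # 5 per Mb
#' @export
mutation_rate <- function(variants, mask) {
  .assert(is.data.frame(mask) && nrow(mask) > 0,
          "coverage mask is empty: cannot compute a mutation rate")
  bases <- sum(mask$end - mask$start)
  .assert(bases > 0, "coverage mask has zero width")
  n <- if (nrow(variants)) {
    sum(!is.na(.fo_first(.as_granges_pos(variants), .as_granges0(mask))))
  } else 0L
  structure(n / (bases / 1e6), n_mutations = n, mask_bases = bases)
}

#' Six-class pyrimidine-collapsed substitution spectrum
#'
#' Each SNV is collapsed onto its pyrimidine-referenced substitution class
#' (purine-referenced changes are complemented, e.g. G>A is counted as C>T),
#' and class fractions are returned. Gastric and many other cancers are
#' dominated by the C>T class.
#'
#' @param snvs `data.frame` with single-base `ref` and `alt` columns.
#' @return Named numeric vector over `C>A, C>G, C>T, T>A, T>C, T>G` summing
#'   to 1, with attribute `n`; all zero (and attribute `empty = TRUE`) on
#'   empty input.
#' @export
mutation_spectrum <- function(snvs) {
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  keep <- nchar(snvs$ref) == 1 & nchar(snvs$alt) == 1 &
    snvs$ref != snvs$alt
  ref <- snvs$ref[keep]; alt <- snvs$alt[keep]
  if (!length(ref)) {
    out <- setNames(rep(0, 6), classes)
    attr(out, "n") <- 0L
    attr(out, "empty") <- TRUE
    return(out)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  purine <- ref %in% c("A", "G")
  ref[purine] <- comp[ref[purine]]
  alt[purine] <- comp[alt[purine]]
  cls <- paste0(ref, ">", alt)
  counts <- table(factor(cls, levels = classes))
  out <- as.numeric(counts) / sum(counts)
  names(out) <- classes
  attr(out, "n") <- length(cls)
  attr(out, "empty") <- FALSE
  out
}
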