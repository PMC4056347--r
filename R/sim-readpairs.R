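#' Simulate discordant read pairs around injected structural variants
#'
#' Each injected SV event emits `n_support` uniquely mapped discordant read
#' pairs whose ends scatter within `pair_scatter` bases of the two true
#' breakpoints, with the strand/span geometry of its type (deletions:
#' convergent pairs spanning the deleted interval; insertions: convergent
#' short-span pairs; inversions: same-strand pairs; translocations: long-span
#' or cross-chromosome pairs). Germline events appear in both tumor and
#' blood; tumor-only events only in tumor. Scattered noise pairs are added
#' uniformly at `noise_pair_rate` per Mb.
#'
#' @param config A [sim_config()].
#' @return A list with `tumor` and `blood` read-pair `data.frame`s
#'   (`chrom1, pos1, strand1, chrom2, pos2, strand2, uniquely_mapped`),
#'   mate order normalized, plus `truth` (the injected event table).
#' @export
simulate_read_pairs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 303L)
  ev <- config$sv_events

  emit_event <- function(e) {
    n <- e$n_support
    sc <- function(p) pmax(1L, pmin(config$chrom_length,
      as.integer(round(p + runif(n, -config$pair_scatter, config$pair_scatter)))))
    p1 <- sc(e$pos1); p2 <- sc(e$pos2)
    strands <- switch(e$type,
      deletion = ,
      insertion = ,
      intra_translocation = ,
      inter_translocation = cbind(rep("+", n), rep("-", n)),
      inversion = { s <- sample(c("+", "-"), 1); cbind(rep(s, n), rep(s, n)) })
    data.frame(chrom1 = e$chrom1, pos1 = p1, strand1 = strands[, 1],
               chrom2 = e$chrom2, pos2 = p2, strand2 = strands[, 2],
               uniquely_mapped = TRUE, stringsAsFactors = FALSE)
  }

  emit_noise <- function() {
    n <- rpois(1, config$noise_pair_rate * config$genome_length / 1e6)
    if (!n) return(NULL)
    data.frame(
      chrom1 = sample(config$chroms, n, replace = TRUE),
      pos1 = sample.int(config$chrom_length, n, replace = TRUE),
      strand1 = sample(c("+", "-"), n, replace = TRUE),
      chrom2 = sample(config$chroms, n, replace = TRUE),
      pos2 = sample.int(config$chrom_length, n, replace = TRUE),
      strand2 = sample(c("+", "-"), n, replace = TRUE),
      uniquely_mapped = TRUE, stringsAsFactors = FALSE)
  }

  build <- function(rows) {
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom1 = character(), pos1 = integer(), strand1 = character(),
                 chrom2 = character(), pos2 = integer(), strand2 = character(),
                 uniquely_mapped = logical())
    normalize_pair_order(df)
  }

  tumor_rows <- list(); blood_rows <- list()
  if (nrow(ev)) {
    for (k in seq_len(nrow(ev))) {
      e <- ev[k, ]
      tumor_rows[[length(tumor_rows) + 1]] <- emit_event(e)
      if (isTRUE(e$germline)) {
        blood_rows[[length(blood_rows) + 1]] <- emit_event(e)
      }
    }
  }
  tn <- emit_noise(); if (!is.null(tn)) tumor_rows[[length(tumor_rows) + 1]] <- tn
  bn <- emit_noise(); if (!is.null(bn)) blood_rows[[length(blood_rows) + 1]] <- bn

  list(tumor = build(tumor_rows), blood = build(blood_rows),
       truth = list(sv_events = ev))
}

#' Normalize read-pair mate order
#'
#' Ensures `chrom1 <= chrom2` and, on the same chromosome, `pos1 <= pos2`,
#' swapping mates (and their strands) where needed.
#'
#' @param pairs Read-pair `data.frame`.
#' @return The normalized `data.frame`.
#' @export
normalize_pair_order <- function(pairs) {
  if (!nrow(pairs)) return(pairs)
  swap <- pairs$chrom1 > pairs$chrom2 |
    (pairs$chrom1 == pairs$chrom2 & pairs$pos1 > pairs$pos2)
  if (any(swap)) {
    tmp <- pairs[swap, ]
    pairs$chrom1[swap] <- tmp$chrom2; pairs$pos1[swap] <- tmp$pos2
    pairs$strand1[swap] <- tmp$strand2
    pairs$chrom2[swap] <- tmp$chrom1; pairs$pos2[swap] <- tmp$pos1
    pairs$strand2[swap] <- tmp$strand1
  }
  rownames(pairs) <- NULL
  pairs
}
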