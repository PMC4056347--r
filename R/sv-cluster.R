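#' Classify read pairs by discordance signature
#'
#' Assigns each mate-order-normalized read pair an evidence class from its
#' chromosome, strand and span geometry relative to the concordant insert
#' distribution:
#'
#' * different chromosomes: `inter_translocation`;
#' * same chromosome, same-strand mates: `inversion`;
#' * convergent (`+`/`-`) mates with span above `max_span`:
#'   `intra_translocation`;
#' * convergent span above `median + k * MAD`: `deletion`;
#' * convergent span below `median - k * MAD`: `insertion`;
#' * anything else (concordant or divergent): `none`.
#'
#' @param pairs Read-pair `data.frame` (`chrom1, pos1, strand1, chrom2,
#'   pos2, strand2, uniquely_mapped`), mate order normalized.
#' @param library_stats List with `median`, `mad` of the concordant insert
#'   size and multiplier `k` (default 3).
#' @param max_span Convergent span above which the pair is called an
#'   intrachromosomal translocation rather than a deletion (default 1 Mb).
#' @return The input with an `sv_class` column.
#' @export
classify_pairs <- function(pairs,
                           library_stats = list(median = 500, mad = 50, k = 3),
                           max_span = 1e6) {
  if (nrow(pairs)) {
    bad <- pairs$chrom1 > pairs$chrom2 |
      (pairs$chrom1 == pairs$chrom2 & pairs$pos1 > pairs$pos2)
    if (any(bad)) {
      stop("read pairs are not mate-order normalized (row ", which(bad)[1],
           "); call normalize_pair_order() first", call. = FALSE)
    }
  }
  k <- library_stats$k %||% 3
  hi <- library_stats$median + k * library_stats$mad
  lo <- library_stats$median - k * library_stats$mad
  span <- pairs$pos2 - pairs$pos1
  cls <- rep("none", nrow(pairs))
  inter <- pairs$chrom1 != pairs$chrom2
  same_strand <- !inter & pairs$strand1 == pairs$strand2
  conv <- !inter & pairs$strand1 == "+" & pairs$strand2 == "-"
  cls[inter] <- "inter_translocation"
  cls[same_strand] <- "inversion"
  cls[conv & span > max_span] <- "intra_translocation"
  cls[conv & span > hi & span <= max_span] <- "deletion"
  cls[conv & span < lo] <- "insertion"
  pairs$sv_class <- cls
  pairs
}

#' Cluster discordant read pairs into structural-variation signals
#'
#' Single-linkage clustering of same-class, uniquely mapped discordant pairs
#' whose corresponding breakpoint ends are each within `join_dist` bases.
#' Clusters supported by at least `min_support` pairs (default 4, the strict
#' reading of "more than three") are emitted as SVSs with breakpoint
#' intervals spanning the supporting read ends. Output order is
#' deterministic and independent of input order.
#'
#' @param pairs Classified pairs (see [classify_pairs()]); rows with class
#'   `none` or `uniquely_mapped = FALSE` are ignored.
#' @param join_dist Per-end join distance in bases (default 400, the SVS
#'   equivalence radius).
#' @param min_support Minimum supporting pairs per SVS (default 4).
#' @return `data.frame(chrom1, bp1_start, bp1_end, chrom2, bp2_start,
#'   bp2_end, sv_type, n_support)`, 1-based inclusive breakpoint intervals.
#' @export
cluster_svs <- function(pairs, join_dist = 400, min_support = 4) {
  proto <- data.frame(chrom1 = character(), bp1_start = integer(),
                      bp1_end = integer(), chrom2 = character(),
                      bp2_start = integer(), bp2_end = integer(),
                      sv_type = character(), n_support = integer())
  use <- pairs$sv_class != "none" & as.logical(pairs$uniquely_mapped)
  p <- pairs[use, , drop = FALSE]
  if (!nrow(p)) return(proto)
  p <- p[order(p$sv_class, p$chrom1, p$chrom2, p$pos1, p$pos2), , drop = FALSE]
  groups <- split(seq_len(nrow(p)),
                  paste(p$sv_class, p$chrom1, p$chrom2, sep = "\r"))
  out <- list()
  for (g in groups) {
    sub <- p[g, , drop = FALSE]
    n <- nrow(sub)
    # neighbor edges: both ends within join_dist (pos1-sorted scan)
    edges <- NULL
    if (n > 1) {
      el <- list()
      for (i in seq_len(n - 1)) {
        j <- i + 1L
        while (j <= n && sub$pos1[j] - sub$pos1[i] <= join_dist) {
          if (abs(sub$pos2[j] - sub$pos2[i]) <= join_dist) {
            el[[length(el) + 1]] <- c(i, j)
          }
          j <- j + 1L
        }
      }
      if (length(el)) edges <- do.call(rbind, el)
    }
    gg <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (!is.null(edges)) gg <- igraph::add_edges(gg, t(edges))
    comp <- igraph::components(gg)$membership
    for (cid in unique(comp)) {
      idx <- which(comp == cid)
      if (length(idx) < min_support) next
      out[[length(out) + 1]] <- data.frame(
        chrom1 = sub$chrom1[1],
        bp1_start = min(sub$pos1[idx]), bp1_end = max(sub$pos1[idx]),
        chrom2 = sub$chrom2[1],
        bp2_start = min(sub$pos2[idx]), bp2_end = max(sub$pos2[idx]),
        sv_type = sub$sv_class[1], n_support = length(idx))
    }
  }
  if (!length(out)) return(proto)
  svs <- do.call(rbind, out)
  svs <- svs[order(svs$chrom1, svs$bp1_start, svs$chrom2, svs$bp2_start,
                   svs$sv_type), , drop = FALSE]
  rownames(svs) <- NULL
  svs
}

# Distance between two 1-based inclusive intervals (0 when overlapping).
.interval_dist <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s2 - e1, s1 - e2))
}

#' Somatic SVS set by germline subtraction
#'
#' A tumor SVS is removed when some blood SVS (of any type) has both
#' breakpoints within `equiv_dist` bases (inclusive) of the tumor SVS's
#' breakpoints on the same chromosome pair.
#'
#' @param tumor_svs,blood_svs SVS `data.frame`s from [cluster_svs()].
#' @param equiv_dist Breakpoint equivalence radius (default 400 bp).
#' @return The somatic subset of `tumor_svs`.
#' @export
somatic_svs <- function(tumor_svs, blood_svs, equiv_dist = 400) {
  if (!nrow(tumor_svs) || !nrow(blood_svs)) return(tumor_svs)
  drop <- vapply(seq_len(nrow(tumor_svs)), function(i) {
    t <- tumor_svs[i, ]
    cand <- blood_svs$chrom1 == t$chrom1 & blood_svs$chrom2 == t$chrom2
    if (!any(cand)) return(FALSE)
    b <- blood_svs[cand, , drop = FALSE]
    d1 <- .interval_dist(t$bp1_start, t$bp1_end, b$bp1_start, b$bp1_end)
    d2 <- .interval_dist(t$bp2_start, t$bp2_end, b$bp2_start, b$bp2_end)
    any(d1 <= equiv_dist & d2 <= equiv_dist)
  }, logical(1))
  out <- tumor_svs[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
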