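#' BIC-penalized segmentation of binned depth ratios
#'
#' A transparent approximation to likelihood-based copy-number segmenters:
#' per-bin log2 tumor:normal count ratios (library-size normalized, 0.5
#' pseudocount) are merged bottom-up, at each step joining the adjacent
#' segment pair whose merge least increases the within-segment sum of
#' squares, until the smallest increase - scaled by a robust noise variance
#' estimated from first differences - exceeds the per-breakpoint penalty
#' `lambda`. Deterministic; ties merge the leftmost pair. This matches the
#' (`lambda`, bin size) interface of BIC-seq-style tools but not their exact
#' segment boundaries.
#'
#' @param bins `data.frame(chrom, start, end, tumor_count, normal_count)`
#'   with uniform bin width (default convention 1000 bp).
#' @param lambda Per-breakpoint penalty (default 100).
#' @return `data.frame(chrom, start, end, n_bins, log2_ratio, state)` with
#'   `state` unset (`NA`); classify with [classify_segments()].
#' @export
segment_depth_bins <- function(bins, lambda = 100) {
  widths <- bins$end - bins$start
  .assert(length(unique(widths)) == 1,
          "bins must have uniform size (found widths %s)",
          paste(head(unique(widths)), collapse = ", "))
  t_tot <- sum(bins$tumor_count); n_tot <- sum(bins$normal_count)
  .assert(t_tot > 0 && n_tot > 0, "empty count track")
  x_all <- log2(((bins$tumor_count + 0.5) / t_tot) /
                ((bins$normal_count + 0.5) / n_tot))

  out <- list()
  for (ch in unique(bins$chrom)) {
    sel <- bins$chrom == ch
    x <- x_all[sel]
    st <- bins$start[sel]; en <- bins$end[sel]
    o <- order(st)
    x <- x[o]; st <- st[o]; en <- en[o]
    .assert(all(st[-1] == en[-length(en)]),
            "bins must be contiguous within chromosome %s", ch)
    segs <- .merge_segments(x, lambda)
    out[[ch]] <- data.frame(
      chrom = ch,
      start = st[segs$first], end = en[segs$last],
      n_bins = segs$last - segs$first + 1L,
      log2_ratio = segs$mean, state = NA_character_)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Bottom-up greedy merging of a 1-d signal. Returns first/last bin index and
# mean per segment.
.merge_segments <- function(x, lambda) {
  n <- length(x)
  if (n == 1) return(data.frame(first = 1L, last = 1L, mean = x))
  dif <- diff(x)
  sigma2 <- max((median(abs(dif)) / 0.6745)^2 / 2, 1e-12)

  s <- x; s2 <- x^2; cnt <- rep(1L, n)   # per-segment sufficient statistics
  first <- seq_len(n); last <- seq_len(n)
  alive <- rep(TRUE, n)
  sse <- function(sm, sq, k) sq - sm^2 / k
  # delta SSE of merging adjacent alive segments i (left) and j (right)
  delta <- function(i, j) {
    sse(s[i] + s[j], s2[i] + s2[j], cnt[i] + cnt[j]) -
      sse(s[i], s2[i], cnt[i]) - sse(s[j], s2[j], cnt[j])
  }
  nxt <- c(seq_len(n)[-1], NA)   # linked list over alive segments
  prv <- c(NA, seq_len(n - 1))
  dvec <- rep(Inf, n)            # dvec[i] = delta of merging i with nxt[i]
  for (i in seq_len(n - 1)) dvec[i] <- delta(i, i + 1L)

  while (TRUE) {
    i <- which.min(dvec)
    if (!is.finite(dvec[i]) || dvec[i] / sigma2 >= lambda) break
    j <- nxt[i]
    s[i] <- s[i] + s[j]; s2[i] <- s2[i] + s2[j]; cnt[i] <- cnt[i] + cnt[j]
    last[i] <- last[j]
    alive[j] <- FALSE
    nxt[i] <- nxt[j]
    if (!is.na(nxt[i])) prv[nxt[i]] <- i
    dvec[j] <- Inf
    dvec[i] <- if (is.na(nxt[i])) Inf else delta(i, nxt[i])
    if (!is.na(prv[i])) dvec[prv[i]] <- delta(prv[i], i)
  }
  idx <- which(alive)
  data.frame(first = first[idx], last = last[idx], mean = s[idx] / cnt[idx])
}

#' Classify copy-number states from log2 ratios
#'
#' Under the `wgs` convention a segment with log2 ratio strictly greater
#' than 0.2 is `duplicated` and strictly smaller than -0.2 `deleted`
#' (boundary values are neutral; the thresholds are strict). The `acgh`
#' convention uses +0.152173 / -0.135797 for `gain` / `loss`.
#'
#' @param log2_ratio Numeric vector of finite log2 ratios.
#' @param convention `"wgs"` (default) or `"acgh"`.
#' @return Character vector of states (`"duplicated"/"deleted"/"neutral"`
#'   or `"gain"/"loss"/"neutral"`).
#' @examples
#' classify_segment(c(0.25, 0.2, -0.25), "wgs")
#' classify_segment(c(0.16, -0.14), "acgh")
#' @export
classify_segment <- function(log2_ratio, convention = c("wgs", "acgh")) {
  convention <- match.arg(convention)
  .assert(all(is.finite(log2_ratio)), "log2 ratios must be finite")
  if (convention == "wgs") {
    ifelse(log2_ratio > 0.2, "duplicated",
           ifelse(log2_ratio < -0.2, "deleted", "neutral"))
  } else {
    ifelse(log2_ratio > 0.152173, "gain",
           ifelse(log2_ratio < -0.135797, "loss", "neutral"))
  }
}

#' Apply state classification to a segment table
#'
#' @param segments Output of [segment_depth_bins()].
#' @param convention Passed to [classify_segment()].
#' @return The segments with `state` filled in.
#' @export
classify_segments <- function(segments, convention = "wgs") {
  segments$state <- classify_segment(segments$log2_ratio, convention)
  segments
}

#' Per-gene copy-number status from classified segments
#'
#' A gene takes the state of the segment class covering the largest part of
#' its span, provided that class covers at least `min_overlap_fraction` of
#' it; ties and insufficient coverage give `neutral`.
#'
#' @param segments Classified segment `data.frame` (`state` set).
#' @param gm A [gene_models()] object.
#' @param min_overlap_fraction Minimum covered fraction (default 0.5).
#' @return `data.frame(gene_id, state)`.
#' @export
gene_copy_status <- function(segments, gm, min_overlap_fraction = 0.5) {
  genes <- .as_granges0(gm)
  segs <- .as_granges0(segments)
  hits <- .fo_all(genes, segs)
  ov <- GenomicRanges::pintersect(genes[S4Vectors::queryHits(hits)],
                                  segs[S4Vectors::subjectHits(hits)])
  ow <- GenomicRanges::width(ov)
  state <- rep("neutral", nrow(gm))
  for (i in unique(S4Vectors::queryHits(hits))) {
    rows <- S4Vectors::queryHits(hits) == i
    cover <- tapply(ow[rows], segments$state[S4Vectors::subjectHits(hits)[rows]],
                    sum)
    cover <- cover[order(-cover)]
    frac <- cover[1] / (gm$end[i] - gm$start[i])
    if (frac >= min_overlap_fraction &&
        (length(cover) == 1 || cover[1] > cover[2])) {
      state[i] <- names(cover)[1]
    }
  }
  data.frame(gene_id = gm$gene_id, state = state, row.names = NULL)
}
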