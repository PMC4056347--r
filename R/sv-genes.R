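# Gene-level interpretation of structural-variation signals: breakage,
# interchromosomal fusions and fusion-transcript structure.

# GRanges of the two breakpoint interval sets of an SVS table.
.bp_granges <- function(svs, side) {
  GenomicRanges::GRanges(
    svs[[paste0("chrom", side)]],
    IRanges::IRanges(svs[[paste0("bp", side, "_start")]],
                     svs[[paste0("bp", side, "_end")]]))
}

# Exon GRanges of the gene models, with gene row index in mcols.
.exon_granges <- function(gm) {
  GenomicRanges::GRanges(
    rep(gm$chrom, lengths(gm$exon_starts)),
    IRanges::IRanges(unlist(gm$exon_starts) + 1L, unlist(gm$exon_ends)),
    gene = rep(seq_len(nrow(gm)), lengths(gm$exon_starts)))
}

#' Genes impaired by SVS breakage
#'
#' A gene has a breakage event when an SVS breakpoint interval overlaps its
#' transcribed span. With `exon_filter = TRUE`, SVSs with neither breakpoint
#' overlapping any exon are excluded first (the stricter convention used for
#' cohort-level impaired-gene tallies); intronic breakpoints then still
#' break a gene only via the other, exonic end of the same SVS.
#'
#' @param svs Somatic SVS `data.frame` (see [cluster_svs()]).
#' @param gm A [gene_models()] object.
#' @param exon_filter Exclude fully intronic/intergenic SVSs first
#'   (default `FALSE`, so intronic breakpoints count as breakage).
#' @return Character vector of impaired gene ids (sorted, unique).
#' @export
gene_breakage <- function(svs, gm, exon_filter = FALSE) {
  if (!nrow(svs)) return(character())
  if (exon_filter) {
    ex <- .exon_granges(gm)
    hit1 <- !is.na(.fo_first(.bp_granges(svs, 1), ex))
    hit2 <- !is.na(.fo_first(.bp_granges(svs, 2), ex))
    svs <- svs[hit1 | hit2, , drop = FALSE]
    if (!nrow(svs)) return(character())
  }
  genes <- .as_granges0(gm)
  h1 <- .fo_all(.bp_granges(svs, 1), genes)
  h2 <- .fo_all(.bp_granges(svs, 2), genes)
  idx <- unique(c(S4Vectors::subjectHits(h1), S4Vectors::subjectHits(h2)))
  sort(gm$gene_id[idx])
}

#' Interchromosomal gene-fusion candidates
#'
#' A fusion candidate is an SVS whose two breakpoints fall within two
#' distinct genes, of interchromosomal-translocation type, supported by at
#' least `min_support` read pairs (default 11, the strict reading of
#' "above 10").
#'
#' @param svs Somatic SVS `data.frame`.
#' @param gm A [gene_models()] object.
#' @param min_support Minimum supporting read pairs (default 11).
#' @return `data.frame(gene5, gene3, chrom1, bp1, chrom2, bp2, sv_type,
#'   n_support)`; `gene5` is the partner at the first (lower-ordered)
#'   breakpoint.
#' @export
call_fusions <- function(svs, gm, min_support = 11) {
  proto <- data.frame(gene5 = character(), gene3 = character(),
                      chrom1 = character(), bp1 = integer(),
                      chrom2 = character(), bp2 = integer(),
                      sv_type = character(), n_support = integer())
  keep <- svs$sv_type == "inter_translocation" & svs$n_support >= min_support
  svs <- svs[keep, , drop = FALSE]
  if (!nrow(svs)) return(proto)
  genes <- .as_granges0(gm)
  g1 <- .fo_first(.bp_granges(svs, 1), genes)
  g2 <- .fo_first(.bp_granges(svs, 2), genes)
  ok <- !is.na(g1) & !is.na(g2) & g1 != g2
  if (!any(ok)) return(proto)
  svs <- svs[ok, , drop = FALSE]
  out <- data.frame(
    gene5 = gm$gene_id[g1[ok]], gene3 = gm$gene_id[g2[ok]],
    chrom1 = svs$chrom1,
    bp1 = as.integer(round((svs$bp1_start + svs$bp1_end) / 2)),
    chrom2 = svs$chrom2,
    bp2 = as.integer(round((svs$bp2_start + svs$bp2_end) / 2)),
    sv_type = svs$sv_type, n_support = svs$n_support)
  rownames(out) <- NULL
  out
}

# CDS length of gene row i transcribed before (strand-aware upstream of) a
# 1-based genomic position; positions inside an exon count the retained part.
.cds_len_upstream <- function(gm, i, pos) {
  es <- gm$exon_starts[[i]]; ee <- gm$exon_ends[[i]]
  p <- pos - 1L
  if (gm$strand[i] == "+") {
    sum(pmax(0L, pmin(ee, p) - es))
  } else {
    sum(pmax(0L, ee - pmax(es, p + 1L)))
  }
}

# Indices (transcription order) of exons fully retained upstream of pos.
.exons_upstream <- function(gm, i, pos) {
  es <- gm$exon_starts[[i]]; ee <- gm$exon_ends[[i]]
  p <- pos - 1L
  n <- length(es)
  if (gm$strand[i] == "+") which(ee <= p)
  else rev(n + 1L - which(es >= p + 1L))
}

#' Predict the structure and reading frame of a fusion transcript
#'
#' Joins the 5' partner's CDS upstream of its breakpoint to the 3' partner's
#' CDS downstream of its breakpoint. The fusion is called `in_frame` when
#' the total retained CDS length is a multiple of 3, `frameshift` otherwise
#' (a frameshifted 3' partner is expected to terminate prematurely). A
#' breakpoint upstream of the 5' partner's CDS start flags the candidate
#' non-coding.
#'
#' @param candidate One row of [call_fusions()] output (or a list with
#'   `gene5, gene3, bp1, bp2`).
#' @param gm A [gene_models()] object.
#' @return List with `gene5, gene3`, retained CDS lengths `len5, len3`,
#'   `fusion_exons` (retained exon indices per partner, transcription
#'   order), `predicted_frame` (`"in_frame"` or `"frameshift"`) and
#'   `noncoding` flag.
#' @export
predict_fusion_transcript <- function(candidate, gm) {
  i5 <- match(candidate$gene5, gm$gene_id)
  i3 <- match(candidate$gene3, gm$gene_id)
  .assert(!is.na(i5) && !is.na(i3), "fusion partner absent from gene models")
  len5 <- .cds_len_upstream(gm, i5, candidate$bp1)
  len3 <- cds_length(gm)[[candidate$gene3]] -
    .cds_len_upstream(gm, i3, candidate$bp2)
  noncoding <- len5 <= 0
  exons5 <- .exons_upstream(gm, i5, candidate$bp1)
  n3 <- length(gm$exon_starts[[i3]])
  exons3 <- setdiff(seq_len(n3), .exons_upstream(gm, i3, candidate$bp2))
  list(gene5 = candidate$gene5, gene3 = candidate$gene3,
       len5 = len5, len3 = len3,
       fusion_exons = list(gene5 = exons5, gene3 = exons3),
       predicted_frame = if ((len5 + len3) %% 3 == 0) "in_frame"
                         else "frameshift",
       noncoding = noncoding)
}

#' Per-sample and cohort structural-variant count summary
#'
#' Tabulates somatic SVSs per sample over the five evidence classes and
#' reports per-type cohort means; each sample's total is the sum of its
#' class counts by construction.
#'
#' @param svs_by_sample Named list of somatic SVS `data.frame`s, one per
#'   sample.
#' @param sample_types Named character vector of cohort labels (e.g.
#'   `"DGC"`/`"IGC"`) for the same samples.
#' @return List with `per_sample` (`data.frame` of class counts + total)
#'   and `cohort_means` (mean per class and total per label).
#' @export
summarize_sv_counts <- function(svs_by_sample, sample_types) {
  classes <- c("insertion", "deletion", "inversion",
               "intra_translocation", "inter_translocation")
  samples <- names(svs_by_sample)
  per <- do.call(rbind, lapply(samples, function(s) {
    sv <- svs_by_sample[[s]]
    counts <- vapply(classes, function(cl) sum(sv$sv_type == cl), integer(1))
    data.frame(sample = s, type = unname(sample_types[s]),
               t(counts), total = sum(counts))
  }))
  if (is.null(per)) {
    per <- data.frame(sample = character(), type = character(),
                      insertion = integer(), deletion = integer(),
                      inversion = integer(), intra_translocation = integer(),
                      inter_translocation = integer(), total = integer())
  }
  names(per)[3:7] <- classes
  stopifnot(all(per$total == rowSums(per[classes])))
  labs <- unique(per$type)
  means <- do.call(rbind, lapply(labs, function(lb) {
    sub <- per[per$type == lb, , drop = FALSE]
    data.frame(type = lb, t(colMeans(sub[c(classes, "total")])))
  }))
  if (is.null(means)) {
    means <- data.frame(type = character(),
                        matrix(numeric(), 0, 6,
                               dimnames = list(NULL, c(classes, "total"))))
  }
  names(means)[-1] <- c(classes, "total")
  list(per_sample = per, cohort_means = means)
}
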