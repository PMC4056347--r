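#' Gene models for the synthetic genome
#'
#' A `gene_models` object is a data.frame with one row per gene
#' (`gene_id, chrom, start, end, strand` plus list-columns `exon_starts`,
#' `exon_ends`; all intervals 0-based half-open, exons sorted by genomic
#' coordinate and tiling the gene span edges as BED12 requires) carrying the
#' coding-strand CDS sequence of each gene in `attr(x, "cds_seq")`. Every
#' exon is treated as coding, so the CDS is the exon concatenation read in
#' transcription order; UTRs are not modeled.
#'
#' @param genes The gene table as described above.
#' @param cds_seq Named character vector of CDS sequences (5'->3' on the
#'   coding strand), one per gene; each length must be the exon total and a
#'   multiple of 3.
#' @return A `gene_models` object.
#' @export
gene_models <- function(genes, cds_seq) {
  need <- c("gene_id", "chrom", "start", "end", "strand",
            "exon_starts", "exon_ends")
  .assert(all(need %in% names(genes)), "gene table missing columns: %s",
          paste(setdiff(need, names(genes)), collapse = ", "))
  .assert(!anyDuplicated(genes$gene_id), "duplicated gene_id")
  .assert(all(genes$gene_id %in% names(cds_seq)),
          "cds_seq missing for some genes")
  for (i in seq_len(nrow(genes))) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    .assert(length(es) == length(ee) && all(ee > es) && !is.unsorted(es),
            "malformed exons for gene %s", genes$gene_id[i])
    .assert(es[1] == genes$start[i] && ee[length(ee)] == genes$end[i],
            "exons must tile the gene span edges (gene %s)", genes$gene_id[i])
    len <- sum(ee - es)
    .assert(len %% 3 == 0, "CDS length of %s not a multiple of 3", genes$gene_id[i])
    .assert(nchar(cds_seq[[genes$gene_id[i]]]) == len,
            "cds_seq length mismatch for %s", genes$gene_id[i])
  }
  structure(genes, cds_seq = cds_seq,
            class = c("gene_models", class(genes)))
}

#' Simulate gene models with random CDS sequences
#'
#' Places non-overlapping multi-exon genes of random structure and strand
#' along the synthetic genome and draws a random CDS sequence for each.
#' The last exon is trimmed so every CDS length is a multiple of 3.
#'
#' @param config A [sim_config()].
#' @param n_genes Number of genes to place (fewer if the genome fills up).
#' @param exon_range Min/max exons per gene.
#' @param exon_len_range Min/max exon length (bases).
#' @param intron_len_range Min/max intron length (bases).
#' @param gap_range Min/max intergenic gap (bases).
#' @return A [gene_models()] object.
#' @examples
#' cfg <- sim_config(genome_length = 2e6, n_chromosomes = 1, seed = 3)
#' gm <- simulate_gene_models(cfg, n_genes = 20)
#' nrow(gm)
#' @export
simulate_gene_models <- function(config, n_genes = 200,
                                 exon_range = c(2L, 6L),
                                 exon_len_range = c(90L, 240L),
                                 intron_len_range = c(200L, 2000L),
                                 gap_range = c(2000L, 20000L)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)

  rows <- vector("list", n_genes)
  seqs <- character(n_genes)
  ids <- sprintf("gene%04d", seq_len(n_genes))
  placed <- 0L
  for (ci in seq_along(config$chroms)) {
    cursor <- sample(gap_range[1]:gap_range[2], 1)
    while (placed < n_genes) {
      n_ex <- sample(exon_range[1]:exon_range[2], 1)
      ex_len <- sample(exon_len_range[1]:exon_len_range[2], n_ex, replace = TRUE)
      rem <- sum(ex_len) %% 3
      if (rem) ex_len[n_ex] <- ex_len[n_ex] + (3L - rem)
      in_len <- if (n_ex > 1)
        sample(intron_len_range[1]:intron_len_range[2], n_ex - 1, replace = TRUE)
        else integer()
      span <- sum(ex_len) + sum(in_len)
      if (cursor + span >= config$chrom_length) break
      es <- cursor + c(0L, cumsum(ex_len[-n_ex] + in_len))
      ee <- es + ex_len
      placed <- placed + 1L
      rows[[placed]] <- data.frame(
        gene_id = ids[placed], chrom = config$chroms[ci],
        start = cursor, end = cursor + span,
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
      rows[[placed]]$exon_starts <- I(list(as.integer(es)))
      rows[[placed]]$exon_ends <- I(list(as.integer(ee)))
      seqs[placed] <- paste(sample(c("A", "C", "G", "T"), sum(ex_len),
                                   replace = TRUE), collapse = "")
      cursor <- cursor + span + sample(gap_range[1]:gap_range[2], 1)
    }
    if (placed >= n_genes) break
  }
  genes <- do.call(rbind, rows[seq_len(placed)])
  gene_models(genes, setNames(seqs[seq_len(placed)], genes$gene_id))
}

#' Per-gene CDS length
#' @param gm A [gene_models()] object.
#' @return Named integer vector of CDS lengths.
#' @export
cds_length <- function(gm) {
  setNames(vapply(seq_len(nrow(gm)),
                  function(i) sum(gm$exon_ends[[i]] - gm$exon_starts[[i]]),
                  integer(1)),
           gm$gene_id)
}

#' CDS intervals of all genes as a coverage-style mask
#'
#' @param gm A [gene_models()] object.
#' @return `data.frame(chrom, start, end)` of merged exon intervals
#'   (0-based half-open, non-overlapping, sorted).
#' @export
cds_mask <- function(gm) {
  ex <- data.frame(
    chrom = rep(gm$chrom, lengths(gm$exon_starts)),
    start = unlist(gm$exon_starts),
    end = unlist(gm$exon_ends))
  gr <- GenomicRanges::reduce(.as_granges0(ex))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

# ---- internal coordinate mapping -------------------------------------------

# 0-based CDS offset of a 1-based genomic position within gene row i, or NA
# if the position is intronic/outside. Transcription order respects strand.
.genomic_to_cds <- function(gm, i, pos) {
  es <- gm$exon_starts[[i]]; ee <- gm$exon_ends[[i]]
  p <- pos - 1L  # 0-based
  k <- which(p >= es & p < ee)
  if (!length(k)) return(NA_integer_)
  if (gm$strand[i] == "+") {
    sum(ee[seq_len(k - 1)] - es[seq_len(k - 1)]) + (p - es[k])
  } else {
    n <- length(es)
    after <- if (k < n) sum(ee[(k + 1):n] - es[(k + 1):n]) else 0L
    after + (ee[k] - 1L - p)
  }
}

# Inverse of .genomic_to_cds: 1-based genomic position of 0-based CDS offset.
.cds_to_genomic <- function(gm, i, cds_pos) {
  es <- gm$exon_starts[[i]]; ee <- gm$exon_ends[[i]]
  lens <- ee - es
  if (gm$strand[i] == "-") { es <- rev(es); ee <- rev(ee); lens <- rev(lens) }
  cum <- cumsum(lens)
  k <- which(cds_pos < cum)[1]
  off <- cds_pos - c(0L, cum)[k]
  if (gm$strand[i] == "+") es[k] + off + 1L else ee[k] - off
}

# Distance from an intronic/genic 1-based position to the nearest exon
# boundary measured into the intron (1 = first intronic base). Inf if exonic
# or the gene has a single exon.
.intron_flank_distance <- function(gm, i, pos) {
  es <- gm$exon_starts[[i]]; ee <- gm$exon_ends[[i]]
  p <- pos - 1L
  if (any(p >= es & p < ee)) return(Inf)
  n <- length(es)
  if (n < 2) return(Inf)
  d <- Inf
  for (k in seq_len(n - 1)) {
    if (p >= ee[k] && p < es[k + 1]) {
      d <- min(p - ee[k] + 1L, es[k + 1] - p)
    }
  }
  d
}
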