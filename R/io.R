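# File interfaces. Depth tracks travel as bedGraph, gene models as BED12
# (+ optional CDS FASTA), read pairs as BEDPE, variants as VCF 4.x with
# AD/DP genotype fields, reports as TSV/JSON. Intervals on disk follow each
# format's convention (BED family 0-based half-open, VCF 1-based).

#' Write / read a windowed depth track as bedGraph
#'
#' @param windows `data.frame(chrom, start, end, depth)`.
#' @param path File path.
#' @return `read_depth_bedgraph()` returns the windows `data.frame`.
#' @export
write_depth_bedgraph <- function(windows, path) {
  gr <- .as_granges0(windows)
  gr$score <- windows$depth
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_depth_bedgraph
#' @export
read_depth_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             depth = gr$score)
}

#' Write / read gene models as BED12 (+ CDS FASTA)
#'
#' The exon structure travels in the BED12 blocks; the coding-strand CDS
#' sequences, when supplied, travel in a sidecar FASTA named by gene id.
#' Without sequences the models support interval operations (breakage,
#' fusions, copy status) but not codon-level consequence annotation.
#'
#' @param gm A [gene_models()] object.
#' @param path BED12 path.
#' @param cds_fasta Optional FASTA path for the CDS sequences.
#' @return `read_gene_models_bed()` returns a `gene_models` object.
#' @export
write_gene_models_bed <- function(gm, path, cds_fasta = NULL) {
  blocks <- IRanges::IRangesList(lapply(seq_len(nrow(gm)), function(i) {
    IRanges::IRanges(start = gm$exon_starts[[i]] - gm$start[i] + 1L,
                     end = gm$exon_ends[[i]] - gm$start[i])
  }))
  gr <- GenomicRanges::GRanges(
    gm$chrom, IRanges::IRanges(gm$start + 1L, gm$end),
    strand = gm$strand, name = gm$gene_id, score = 0,
    thick = IRanges::IRanges(gm$start + 1L, gm$end), blocks = blocks)
  rtracklayer::export(gr, path, format = "bed")
  if (!is.null(cds_fasta)) {
    seqs <- Biostrings::DNAStringSet(attr(gm, "cds_seq"))
    Biostrings::writeXStringSet(seqs, cds_fasta)
  }
  invisible(path)
}

#' @rdname write_gene_models_bed
#' @export
read_gene_models_bed <- function(path, cds_fasta = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  genes <- data.frame(
    gene_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  blocks <- gr$blocks
  genes$exon_starts <- I(lapply(seq_along(gr), function(i)
    genes$start[i] + GenomicRanges::start(blocks[[i]]) - 1L))
  genes$exon_ends <- I(lapply(seq_along(gr), function(i)
    genes$start[i] + GenomicRanges::end(blocks[[i]])))
  if (!is.null(cds_fasta)) {
    seqs <- Biostrings::readDNAStringSet(cds_fasta)
    cds <- setNames(as.character(seqs), names(seqs))
  } else {
    lens <- vapply(seq_len(nrow(genes)), function(i)
      sum(genes$exon_ends[[i]] - genes$exon_starts[[i]]), integer(1))
    cds <- setNames(strrep("A", lens), genes$gene_id)
  }
  gene_models(genes, cds)
}

#' Write / read discordant read pairs as BEDPE
#'
#' Standard 10-column BEDPE (both ends 0-based half-open, width-1
#' intervals; the name column is a running id, score the mapping
#' uniqueness flag).
#'
#' @param pairs Read-pair `data.frame`.
#' @param path File path.
#' @return `read_pairs_bedpe()` returns the pairs `data.frame`.
#' @export
write_pairs_bedpe <- function(pairs, path) {
  df <- data.frame(chrom1 = pairs$chrom1, start1 = pairs$pos1 - 1L,
                   end1 = pairs$pos1,
                   chrom2 = pairs$chrom2, start2 = pairs$pos2 - 1L,
                   end2 = pairs$pos2,
                   name = sprintf("pair%06d", seq_len(nrow(pairs))),
                   score = as.integer(pairs$uniquely_mapped),
                   strand1 = pairs$strand1, strand2 = pairs$strand2)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs_bedpe
#' @export
read_pairs_bedpe <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("chrom1", "start1", "end1", "chrom2",
                                 "start2", "end2", "name", "score",
                                 "strand1", "strand2"))
  data.frame(chrom1 = df$chrom1, pos1 = df$end1, strand1 = df$strand1,
             chrom2 = df$chrom2, pos2 = df$end2, strand2 = df$strand2,
             uniquely_mapped = df$score > 0)
}

#' Write / read variant tables as VCF
#'
#' Serializes the pipeline's variant records through a `VRanges`, carrying
#' read depths in `DP`/`AD`, call quality in `CQ`, mapping uniqueness in
#' `UM` and the detection source in `SRC` genotype fields.
#'
#' @param variants Variant `data.frame` (see [simulate_variant_tables()]).
#' @param path VCF path.
#' @param sample_name Sample column name in the VCF.
#' @return `read_variants_vcf()` returns the variant `data.frame`.
#' @export
write_variants_vcf <- function(variants, path, sample_name = "SAMPLE") {
  vr <- VariantAnnotation::VRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(variants$pos, width = nchar(variants$ref)),
    ref = variants$ref, alt = variants$alt,
    totalDepth = as.integer(variants$depth),
    altDepth = as.integer(variants$alt_reads),
    refDepth = as.integer(variants$depth - variants$alt_reads),
    sampleNames = sample_name)
  S4Vectors::mcols(vr)$CQ <- variants$call_quality
  S4Vectors::mcols(vr)$UM <- as.integer(variants$uniquely_mapped)
  S4Vectors::mcols(vr)$SRC <- gsub(",", "_", variants$detected_by)
  VariantAnnotation::writeVcf(vr, path)
  invisible(path)
}

#' @rdname write_variants_vcf
#' @export
read_variants_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  vr <- methods::as(vcf, "VRanges")
  ref <- as.character(VariantAnnotation::ref(vr))
  alt <- as.character(VariantAnnotation::alt(vr))
  vtype <- ifelse(nchar(ref) == nchar(alt), "SNV",
                  ifelse(nchar(ref) > nchar(alt), "DEL", "INS"))
  geno <- VariantAnnotation::geno(vcf)
  pick <- function(field, default) {
    if (field %in% names(geno)) as.vector(geno[[field]]) else default
  }
  n <- length(vr)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(vr)),
    pos = GenomicRanges::start(vr), ref = ref, alt = alt, vtype = vtype,
    depth = as.integer(VariantAnnotation::totalDepth(vr)),
    alt_reads = as.integer(VariantAnnotation::altDepth(vr)),
    call_quality = as.numeric(pick("CQ", rep(NA_real_, n))),
    uniquely_mapped = as.logical(pick("UM", rep(1L, n)) > 0),
    detected_by = gsub("_", ",", as.character(pick("SRC", rep("WGS", n)))),
    stringsAsFactors = FALSE)
  df <- cbind(id = .variant_key(df), df)
  df$id <- as.character(df$id)
  rownames(df) <- NULL
  df
}

#' Write a purity report TSV
#'
#' @param estimates Named list of `purity_estimate` objects (names are
#'   sample ids).
#' @param path File path.
#' @export
write_purity_report <- function(estimates, path) {
  df <- do.call(rbind, lapply(names(estimates), function(s) {
    e <- estimates[[s]]
    data.frame(sample = s, P = e$P, method = e$method,
               R2n = e$diagnostics$R2n %||% NA_real_,
               R1n = e$diagnostics$R1n %||% NA_real_)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
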