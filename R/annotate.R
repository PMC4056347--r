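#' Annotate variants with gene and consequence
#'
#' Maps each variant onto the gene models and assigns a consequence by
#' translating the affected codon on the coding strand:
#' `synonymous`, `nonsynonymous`, `nonsense` (stop gain; counted within the
#' nonsynonymous class by the driver scorer), `splice_site` (within the 2
#' intronic bases flanking an exon boundary), `frameshift` (CDS indel of
#' length not divisible by 3), `inframe_indel`, or `noncoding` (outside any
#' gene, or intronic beyond the splice flank).
#'
#' @param variants `data.frame` with at least `chrom, pos, ref, alt, vtype`
#'   (`pos` 1-based; `vtype` one of `"SNV"`, `"INS"`, `"DEL"`).
#' @param gm A [gene_models()] object; exonic reference bases are taken from
#'   its CDS sequences.
#' @return The input with `gene_id` and `consequence` columns appended.
#' @examples
#' cfg <- sim_config(genome_length = 1e6, n_chromosomes = 1, seed = 5)
#' gm <- simulate_gene_models(cfg, n_genes = 5)
#' v <- data.frame(chrom = "chr1", pos = gm$start[1] + 1, ref = "A", alt = "G",
#'                 vtype = "SNV")
#' annotate_variants(v, gm)[, c("gene_id", "consequence")]
#' @export
annotate_variants <- function(variants, gm) {
  stopifnot(inherits(gm, "gene_models"))
  n <- nrow(variants)
  gene_id <- rep(NA_character_, n)
  consequence <- rep("noncoding", n)
  if (n) {
    vgr <- .as_granges_pos(variants)
    ggr <- .as_granges0(gm)
    hit <- .fo_first(vgr, ggr)
    for (v in which(!is.na(hit))) {
      i <- hit[v]
      gene_id[v] <- gm$gene_id[i]
      consequence[v] <- .consequence_one(variants[v, ], gm, i)
    }
  }
  variants$gene_id <- gene_id
  variants$consequence <- consequence
  variants
}

# Consequence of one variant known to lie within gene row i.
.consequence_one <- function(rec, gm, i) {
  cds_pos <- .genomic_to_cds(gm, i, rec$pos)
  if (rec$vtype %in% c("INS", "DEL")) {
    len <- abs(nchar(rec$ref) - nchar(rec$alt))
    if (!is.na(cds_pos)) {
      return(if (len %% 3 != 0) "frameshift" else "inframe_indel")
    }
    if (.intron_flank_distance(gm, i, rec$pos) <= 2) return("splice_site")
    return("noncoding")
  }
  # SNV
  if (is.na(cds_pos)) {
    if (.intron_flank_distance(gm, i, rec$pos) <= 2) return("splice_site")
    return("noncoding")
  }
  seq <- attr(gm, "cds_seq")[[gm$gene_id[i]]]
  codon_i <- cds_pos %/% 3
  within <- cds_pos %% 3
  codon <- substr(seq, codon_i * 3 + 1, codon_i * 3 + 3)
  alt_cs <- if (gm$strand[i] == "+") rec$alt else .revcomp1(rec$alt)
  alt_codon <- codon
  substr(alt_codon, within + 1, within + 1) <- alt_cs
  aa_ref <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[alt_codon]]
  if (identical(aa_ref, aa_alt)) return("synonymous")
  if (identical(aa_alt, "*")) return("nonsense")
  "nonsynonymous"
}

.revcomp1 <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

# Coding-strand reference base at CDS offset (0-based); on the genome's plus
# strand this is the complement for minus-strand genes.
.cds_ref_base <- function(gm, i, cds_pos, genomic = TRUE) {
  b <- substr(attr(gm, "cds_seq")[[gm$gene_id[i]]], cds_pos + 1, cds_pos + 1)
  if (genomic && gm$strand[i] == "-") .revcomp1(b) else b
}
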