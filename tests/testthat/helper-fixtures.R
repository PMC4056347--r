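# Shared fixtures: small hand-built gene models and a standard purity
# simulation configuration.

# A two-gene model on one chromosome: geneP on the plus strand with a known
# CDS, geneM on the minus strand. Exons tile the gene span edges.
make_toy_genes <- function() {
  # geneP: exons [1000,1012) + [1512,1524); CDS (plus) = seq as given
  # geneM: exons [5000,5012) + [5512,5524); CDS read off the minus strand
  cds_p <- "AAACCCGGGTTTATGTGGAAATAG"  # 8 codons: K P G F M W K *
  cds_m <- "ATGGCTGCTAAACCCGGGTTTTAA"
  genes <- data.frame(
    gene_id = c("geneP", "geneM"),
    chrom = "chr1",
    start = c(1000L, 5000L), end = c(1524L, 5524L),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  genes$exon_starts <- I(list(c(1000L, 1512L), c(5000L, 5512L)))
  genes$exon_ends <- I(list(c(1012L, 1524L), c(5012L, 5524L)))
  gene_models(genes, c(geneP = cds_p, geneM = cds_m))
}

# Purity-simulation config: 20% of a 100-Mb genome heterozygously deleted.
purity_cfg <- function(pi0, seed, genome = 100e6) {
  chrom_len <- genome / 2
  sim_config(
    genome_length = genome, n_chromosomes = 2, purity = pi0,
    cnv_events = data.frame(chrom = c("chr1", "chr2"),
                            start = c(0, 0),
                            end = c(0.25 * chrom_len, 0.15 * chrom_len),
                            tumor_cn = 1L),
    seed = seed)
}

# Minimal tumor-call record for cascade tests.
call_rec <- function(chrom = "chr1", pos, ref = "A", alt = "T",
                     vtype = "SNV", depth = 30, alt_reads = 10,
                     call_quality = 40, uniquely_mapped = TRUE,
                     detected_by = "WGS,WES") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, vtype = vtype,
             depth = depth, alt_reads = alt_reads,
             call_quality = call_quality, uniquely_mapped = uniquely_mapped,
             detected_by = detected_by, stringsAsFactors = FALSE)
}

empty_calls <- function() call_rec(pos = 1)[0, ]

# n coincident read pairs supporting one deletion-type event.
del_pairs <- function(n, pos1 = 10000, pos2 = 20000, chrom = "chr1",
                      jitter1 = rep(0, n), jitter2 = rep(0, n)) {
  data.frame(chrom1 = chrom, pos1 = pos1 + jitter1, strand1 = "+",
             chrom2 = chrom, pos2 = pos2 + jitter2, strand2 = "-",
             uniquely_mapped = TRUE, stringsAsFactors = FALSE)
}
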