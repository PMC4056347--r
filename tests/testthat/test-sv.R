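# Discordant-pair classification, SVS clustering, somatic subtraction,
# breakage, fusions and SV count summaries.

lib_stats <- list(median = 500, mad = 50, k = 3)

test_that("pair classification follows the insert-size geometry", {
  mk <- function(c1, p1, s1, c2, p2, s2) {
    data.frame(chrom1 = c1, pos1 = p1, strand1 = s1,
               chrom2 = c2, pos2 = p2, strand2 = s2,
               uniquely_mapped = TRUE)
  }
  cases <- rbind(
    mk("chr1", 100, "+", "chr2", 100, "-"),        # inter
    mk("chr1", 100, "+", "chr1", 600, "-"),        # span = median: none
    mk("chr1", 100, "+", "chr1", 100 + 500 + 10 * 50, "-"),  # deletion
    mk("chr1", 100, "+", "chr1", 250, "-"),        # short span: insertion
    mk("chr1", 100, "+", "chr1", 100 + 2e6, "-"),  # huge span: intra
    mk("chr1", 100, "+", "chr1", 700, "+"))        # same strand: inversion
  cls <- classify_pairs(cases, lib_stats)$sv_class
  expect_equal(cls, c("inter_translocation", "none", "deletion", "insertion",
                      "intra_translocation", "inversion"))
  # boundary: span exactly median + k * MAD is still concordant
  at <- classify_pairs(mk("chr1", 100, "+", "chr1", 100 + 650, "-"),
                       lib_stats)$sv_class
  expect_equal(at, "none")
  expect_error(classify_pairs(mk("chr1", 900, "+", "chr1", 100, "-")),
               "normalized")
})

test_that("SVS support threshold is strict at four pairs", {
  expect_equal(nrow(cluster_svs(classify_pairs(del_pairs(3)))), 0)
  svs <- cluster_svs(classify_pairs(del_pairs(4)))
  expect_equal(nrow(svs), 1)
  expect_equal(svs$n_support, 4)
  # non-unique pairs do not count
  p <- del_pairs(4); p$uniquely_mapped[4] <- FALSE
  expect_equal(nrow(cluster_svs(classify_pairs(p))), 0)
})

test_that("clustering is invariant under input permutation", {
  set.seed(33)
  pairs <- rbind(
    del_pairs(5, pos1 = 10000, pos2 = 20000,
              jitter1 = sample(-150:150, 5), jitter2 = sample(-150:150, 5)),
    del_pairs(6, pos1 = 50000, pos2 = 65000,
              jitter1 = sample(-150:150, 6), jitter2 = sample(-150:150, 6)),
    data.frame(chrom1 = "chr2", pos1 = 1000, strand1 = "+", chrom2 = "chr3",
               pos2 = 2000, strand2 = "-", uniquely_mapped = TRUE))
  ref <- cluster_svs(classify_pairs(pairs))
  for (k in 1:10) {
    perm <- pairs[sample.int(nrow(pairs)), ]
    expect_identical(cluster_svs(classify_pairs(perm)), ref)
  }
  expect_equal(nrow(ref), 2)  # the lone inter pair is below min support
})

test_that("germline subtraction uses the 400-bp equivalence radius inclusively", {
  tum <- cluster_svs(classify_pairs(del_pairs(4, pos1 = 10000, pos2 = 20000)))
  mk_blood <- function(shift) {
    cluster_svs(classify_pairs(del_pairs(4, pos1 = 10000 + shift,
                                         pos2 = 20000 + shift)))
  }
  expect_equal(nrow(somatic_svs(tum, mk_blood(400))), 0)   # removed at 400
  expect_equal(nrow(somatic_svs(tum, mk_blood(401))), 1)   # retained at 401
  expect_identical(somatic_svs(tum, tum[0, ]), tum)        # empty blood
  # one matching end is not enough
  blood_half <- cluster_svs(classify_pairs(del_pairs(4, pos1 = 10000,
                                                     pos2 = 30000)))
  expect_equal(nrow(somatic_svs(tum, blood_half)), 1)
})

test_that("simulated tumor-only SVs survive and germline SVs are subtracted", {
  ev <- data.frame(
    chrom1 = "chr1", pos1 = c(1e6, 3e6, 5e6),
    chrom2 = "chr1", pos2 = c(1e6, 3e6, 5e6) + 1e5,
    type = "deletion", n_support = 6L,
    germline = c(FALSE, FALSE, TRUE))
  recovered <- 0; leaked <- 0
  for (s in 1:10) {
    cfg <- sim_config(genome_length = 10e6, n_chromosomes = 1,
                      sv_events = ev, noise_pair_rate = 1, seed = 880 + s)
    rp <- simulate_read_pairs(cfg)
    som <- somatic_svs(cluster_svs(classify_pairs(rp$tumor)),
                       cluster_svs(classify_pairs(rp$blood)))
    near <- function(pos) any(som$sv_type == "deletion" &
                              abs((som$bp1_start + som$bp1_end) / 2 - pos) < 500)
    recovered <- recovered + near(1e6) + near(3e6)
    leaked <- leaked + near(5e6)
  }
  expect_gte(recovered / 20, 0.95)
  expect_equal(leaked, 0)
})

test_that("gene breakage honors the exon filter convention", {
  gm <- make_toy_genes()
  # breakpoint in geneP's intron (0-based 1012..1512)
  svs <- data.frame(chrom1 = "chr1", bp1_start = 1100L, bp1_end = 1100L,
                    chrom2 = "chr1", bp2_start = 900000L, bp2_end = 900000L,
                    sv_type = "deletion", n_support = 5L)
  expect_equal(gene_breakage(svs, gm, exon_filter = FALSE), "geneP")
  expect_equal(gene_breakage(svs, gm, exon_filter = TRUE), character())
  # exonic breakpoint passes the filter
  svs_ex <- svs; svs_ex$bp1_start <- svs_ex$bp1_end <- 1005L
  expect_equal(gene_breakage(svs_ex, gm, exon_filter = TRUE), "geneP")
  # both breakpoints intergenic: nothing impaired
  svs_ig <- svs; svs_ig$bp1_start <- svs_ig$bp1_end <- 800000L
  expect_equal(gene_breakage(svs_ig, gm), character())
})

test_that("fusion candidates need two genes, interchromosomal type, >10 pairs", {
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = c("chr1", "chr2"),
    start = c(1000L, 2000L), end = c(7000L, 8000L),
    strand = c("+", "+"), stringsAsFactors = FALSE)
  genes$exon_starts <- I(list(c(1000L, 4000L), c(2000L, 5000L)))
  genes$exon_ends <- I(list(c(2500L, 7000L), c(3500L, 8000L)))
  gm2 <- gene_models(genes, c(gA = strrep("A", 4500), gB = strrep("A", 4500)))
  mk_svs <- function(n, type = "inter_translocation", c2 = "chr2",
                     b2 = 6000L) {
    data.frame(chrom1 = "chr1", bp1_start = 3000L, bp1_end = 3000L,
               chrom2 = c2, bp2_start = b2, bp2_end = b2,
               sv_type = type, n_support = n)
  }
  expect_equal(nrow(call_fusions(mk_svs(10L), gm2)), 0)   # "above 10" fails
  f <- call_fusions(mk_svs(11L), gm2)
  expect_equal(nrow(f), 1)
  expect_equal(f$gene5, "gA"); expect_equal(f$gene3, "gB")
  expect_equal(nrow(call_fusions(mk_svs(20L, type = "intra_translocation"),
                                 gm2)), 0)
  # breakpoint outside any gene on one side
  expect_equal(nrow(call_fusions(mk_svs(15L, b2 = 100L), gm2)), 0)
})

test_that("fusion transcripts are framed by retained CDS length mod 3", {
  genes <- data.frame(
    gene_id = c("g5", "g3"), chrom = c("chr1", "chr2"),
    start = c(0L, 0L), end = c(1002L, 1200L),
    strand = c("+", "+"), stringsAsFactors = FALSE)
  genes$exon_starts <- I(list(c(0L, 600L), c(0L, 700L)))
  genes$exon_ends <- I(list(c(300L, 1002L), c(250L, 1200L)))
  gm3 <- gene_models(genes, c(g5 = strrep("A", 702), g3 = strrep("A", 750)))
  # breakpoint after g5 exon 1 (intron): retained len5 = 300
  # g3 breakpoint in its intron: retained len3 = 500 (second exon)
  cand <- list(gene5 = "g5", gene3 = "g3", bp1 = 400L, bp2 = 400L)
  fx <- predict_fusion_transcript(cand, gm3)
  expect_equal(fx$len5, 300)
  expect_equal(fx$len3, 500)
  expect_equal((fx$len5 + fx$len3) %% 3, 2)
  expect_equal(fx$predicted_frame, "frameshift")
  expect_equal(fx$fusion_exons$gene5, 1)
  expect_equal(fx$fusion_exons$gene3, 2)

  # trim one base into the first exon: 300|450-like in-frame arithmetic
  cand2 <- list(gene5 = "g5", gene3 = "g3", bp1 = 400L, bp2 = 952L)
  fx2 <- predict_fusion_transcript(cand2, gm3)
  expect_equal(fx2$len3, 249)
  expect_equal((300 + 249) %% 3, 0)
  expect_equal(fx2$predicted_frame, "in_frame")

  # breakpoint before the 5' partner's CDS start: non-coding
  cand3 <- list(gene5 = "g5", gene3 = "g3", bp1 = 0L, bp2 = 400L)
  expect_true(predict_fusion_transcript(cand3, gm3)$noncoding)
})

test_that("frameshifted fusions terminate prematurely on the built sequence", {
  # codon-walk oracle: join the retained CDS pieces and translate
  genes <- data.frame(
    gene_id = c("t5", "t3"), chrom = c("chr1", "chr2"),
    start = c(0L, 0L), end = c(300L, 303L),
    strand = c("+", "+"), stringsAsFactors = FALSE)
  genes$exon_starts <- I(list(0L, 0L))
  genes$exon_ends <- I(list(300L, 303L))
  seq5 <- paste(rep("ATGGCT", 50), collapse = "")         # no stops in frame
  seq3 <- paste0(strrep("C", 103), "TAA", strrep("C", 197))
  gm4 <- gene_models(genes, c(t5 = seq5, t3 = seq3))
  cand <- list(gene5 = "t5", gene3 = "t3", bp1 = 101L, bp2 = 102L)
  fx <- predict_fusion_transcript(cand, gm4)
  expect_equal(fx$len5, 100)
  expect_equal(fx$len3, 202)
  expect_equal(fx$predicted_frame, "frameshift")
  fused <- paste0(substr(seq5, 1, 100), substr(seq3, 102, 303))
  n_cod <- nchar(fused) %/% 3
  codons <- substring(fused, 3 * (seq_len(n_cod) - 1) + 1,
                      3 * seq_len(n_cod))
  aa <- vapply(codons, function(cd) Biostrings::GENETIC_CODE[[cd]], "")
  expect_true(any(aa == "*"))                 # premature stop downstream
  expect_lt(which(aa == "*")[1], n_cod)
})

test_that("SV count summaries add up per class and per cohort", {
  mk_svs <- function(counts) {
    types <- rep(c("insertion", "deletion", "inversion",
                   "intra_translocation", "inter_translocation"), counts)
    data.frame(chrom1 = "chr1", bp1_start = seq_along(types),
               bp1_end = seq_along(types), chrom2 = "chr1",
               bp2_start = 1L, bp2_end = 1L, sv_type = types,
               n_support = 4L)
  }
  svs <- list(D1 = mk_svs(c(2, 3, 1, 0, 1)), D2 = mk_svs(c(4, 1, 1, 2, 1)),
              I1 = mk_svs(c(1, 1, 0, 0, 0)))
  sm <- summarize_sv_counts(svs, c(D1 = "DGC", D2 = "DGC", I1 = "IGC"))
  expect_equal(sm$per_sample$total, c(7, 9, 2))
  dgc <- sm$cohort_means[sm$cohort_means$type == "DGC", ]
  expect_equal(dgc$total, 8)
  expect_equal(dgc$insertion, 3)
  expect_equal(sum(dgc[, c("insertion", "deletion", "inversion",
                           "intra_translocation", "inter_translocation")]),
               dgc$total)
})
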