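# The synthetic-data generators: mixture structure, determinism, ground
# truth bookkeeping.

test_that("tumor depth follows the purity-admixture mixture law", {
  # closed form: deletion-region ratio / diploid ratio = 1 - pi/2
  for (pi0 in c(1.0, 0.4)) {
    cfg <- sim_config(genome_length = 60e6, n_chromosomes = 1, purity = pi0,
                      cnv_events = data.frame(chrom = "chr1", start = 0,
                                              end = 30e6, tumor_cn = 1L),
                      seed = 99)
    prof <- simulate_genome_profile(cfg)
    in_del <- prof$tumor$start < 30e6   # 600 windows in, 600 out
    r <- prof$tumor$depth / prof$normal$depth
    expect_equal(mean(r[in_del]) / mean(r[!in_del]), 1 - pi0 / 2,
                 tolerance = 0.02)
  }
})

test_that("zero purity leaves all windows statistically indistinguishable", {
  cfg <- sim_config(genome_length = 50e6, n_chromosomes = 1, purity = 0,
                    cnv_events = data.frame(chrom = "chr1", start = 0,
                                            end = 25e6, tumor_cn = 1L),
                    seed = 13)
  prof <- simulate_genome_profile(cfg)
  pk <- find_ratio_peaks(compute_depth_ratios(prof$tumor, prof$normal))
  expect_true(is.na(pk$R1n))
  expect_equal(nrow(pk$peaks), 1)
})

test_that("overlapping CNV events are rejected at configuration time", {
  expect_error(
    sim_config(genome_length = 10e6, n_chromosomes = 1,
               cnv_events = data.frame(chrom = "chr1",
                                       start = c(0, 4e6),
                                       end = c(5e6, 8e6), tumor_cn = 1L),
               seed = 1),
    "must not overlap")
})

test_that("generators are byte-deterministic in the seed", {
  cfg <- sim_config(genome_length = 5e6, n_chromosomes = 1,
                    germline_rate = 50, somatic_rate = 20,
                    sv_events = data.frame(chrom1 = "chr1", pos1 = 1e6,
                                           chrom2 = "chr1", pos2 = 2e6,
                                           type = "deletion",
                                           n_support = 5L, germline = FALSE),
                    seed = 77)
  s1 <- simulate_sample(cfg, n_genes = 30)
  s2 <- simulate_sample(cfg, n_genes = 30)
  expect_identical(s1$tumor_windows, s2$tumor_windows)
  expect_identical(s1$tumor_calls, s2$tumor_calls)
  expect_identical(s1$tumor_pairs, s2$tumor_pairs)
  expect_identical(s1$truth$somatic_ids, s2$truth$somatic_ids)
})

test_that("germline variants are shared, somatic are tumor-only", {
  cfg <- sim_config(genome_length = 5e6, n_chromosomes = 1,
                    germline_rate = 60, somatic_rate = 30, seed = 5)
  gm <- simulate_gene_models(cfg, n_genes = 40)
  v <- simulate_variant_tables(cfg, gm)
  expect_setequal(v$blood$id, v$truth$germline_ids)
  expect_setequal(v$tumor$id, c(v$truth$germline_ids, v$truth$somatic_ids))
  # conservation: tumor-only + shared = tumor table
  shared <- intersect(v$tumor$id, v$blood$id)
  only <- setdiff(v$tumor$id, v$blood$id)
  expect_equal(length(shared) + length(only), nrow(v$tumor))
})

test_that("germline rate zero leaves the blood call set empty", {
  cfg <- sim_config(genome_length = 5e6, n_chromosomes = 1,
                    germline_rate = 0, somatic_rate = 10, seed = 8)
  gm <- simulate_gene_models(cfg, n_genes = 20)
  v <- simulate_variant_tables(cfg, gm)
  expect_equal(nrow(v$blood), 0)
  expect_true(all(v$blood_pileup$alt_ratio == 0))
})

test_that("coding somatic counts are Poisson in rate x CDS megabases", {
  cfg0 <- sim_config(genome_length = 4e6, n_chromosomes = 1,
                     germline_rate = 0, somatic_rate = 50,
                     indel_fraction = 0, seed = 1)
  gm <- simulate_gene_models(cfg0, n_genes = 150)
  lam <- 50 * sum(cds_mask(gm)$end - cds_mask(gm)$start) / 1e6
  counts <- vapply(1:40, function(s) {
    cfg <- sim_config(genome_length = 4e6, n_chromosomes = 1,
                      germline_rate = 0, somatic_rate = 50,
                      indel_fraction = 0, seed = 1000 + s)
    v <- simulate_variant_tables(cfg, gm)
    sum(v$truth$gene_truth$ns + v$truth$gene_truth$s)
  }, numeric(1))
  # mean within 4 standard errors of the Poisson oracle mean
  expect_lt(abs(mean(counts) - lam), 4 * sqrt(lam / length(counts)))
  expect_gt(var(counts), lam * 0.5)  # dispersion of the right order
})

test_that("injected driver genes exceed the coding background", {
  cfg <- sim_config(genome_length = 4e6, n_chromosomes = 1,
                    germline_rate = 0, somatic_rate = 5,
                    driver_genes = data.frame(gene_id = "gene0003",
                                              extra_nssnv = 5L),
                    seed = 21)
  gm <- simulate_gene_models(cfg, n_genes = 50)
  v <- simulate_variant_tables(cfg, gm)
  gt <- v$truth$gene_truth
  expect_gte(gt$ns[gt$gene_id == "gene0003"], 5)
  bg <- setNames(rep(0, nrow(gm)), gm$gene_id)
  bg[gt$gene_id] <- gt$ns
  expect_gt(bg[["gene0003"]], mean(bg[names(bg) != "gene0003"]))
})

test_that("simulated variants annotate back to their intended classes", {
  cfg <- sim_config(genome_length = 4e6, n_chromosomes = 1,
                    germline_rate = 0, somatic_rate = 60,
                    ns_s_ratio = 2.5, indel_fraction = 0, seed = 31)
  gm <- simulate_gene_models(cfg, n_genes = 120)
  v <- simulate_variant_tables(cfg, gm)
  ann <- annotate_variants(v$tumor, gm)
  gt <- v$truth$gene_truth
  expect_equal(sum(ann$consequence %in% c("nonsynonymous", "nonsense")),
               sum(gt$ns))
  expect_equal(sum(ann$consequence == "synonymous"), sum(gt$s))
})

test_that("read-pair events are recoverable and noise-free cases are empty", {
  cfg <- sim_config(genome_length = 10e6, n_chromosomes = 2,
                    sv_events = data.frame(chrom1 = "chr1", pos1 = 1e6,
                                           chrom2 = "chr1", pos2 = 1.2e6,
                                           type = "deletion",
                                           n_support = 4L, germline = FALSE),
                    noise_pair_rate = 0, pair_scatter = 0, seed = 3)
  rp <- simulate_read_pairs(cfg)
  expect_equal(nrow(rp$tumor), 4)
  expect_equal(nrow(rp$blood), 0)
  svs <- cluster_svs(classify_pairs(rp$tumor))
  expect_equal(nrow(svs), 1)
  expect_equal(svs$n_support, 4)
  expect_equal(svs$sv_type, "deletion")

  cfg0 <- sim_config(genome_length = 10e6, n_chromosomes = 2,
                     noise_pair_rate = 0, seed = 3)
  rp0 <- simulate_read_pairs(cfg0)
  expect_equal(nrow(rp0$tumor), 0)
})

test_that("downstream clustering recovers nearly all scattered SV events", {
  hits <- 0L; total <- 0L
  for (s in 1:10) {
    set.seed(s)
    n_ev <- 10
    pos1 <- sort(sample.int(20e6 - 2e6, n_ev)) + 0
    ev <- data.frame(chrom1 = "chr1", pos1 = pos1,
                     chrom2 = "chr1", pos2 = pos1 + 1e5,
                     type = "deletion",
                     n_support = 6L, germline = FALSE)
    cfg <- sim_config(genome_length = 20e6, n_chromosomes = 1,
                      sv_events = ev, noise_pair_rate = 1,
                      pair_scatter = 150, seed = 4000 + s)
    rp <- simulate_read_pairs(cfg)
    svs <- cluster_svs(classify_pairs(rp$tumor))
    for (k in seq_len(n_ev)) {
      total <- total + 1L
      ok <- any(svs$sv_type == "deletion" &
                abs((svs$bp1_start + svs$bp1_end) / 2 - ev$pos1[k]) < 500 &
                abs((svs$bp2_start + svs$bp2_end) / 2 - ev$pos2[k]) < 500 &
                svs$n_support >= 4)
      if (ok) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})
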