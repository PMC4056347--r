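# Consequence annotation, the somatic filter cascade, mutation rate and
# substitution spectrum.

test_that("codon-level consequences are assigned on both strands", {
  gm <- make_toy_genes()
  # geneP (+): codon AAA at cds 0..2 (genomic 1001..1003)
  cases <- rbind(
    call_rec(pos = 1003, ref = "A", alt = "G"),   # AAA->AAG, Lys->Lys
    call_rec(pos = 1001, ref = "A", alt = "C"),   # AAA->CAA, Lys->Gln
    call_rec(pos = 1517, ref = "G", alt = "A"),   # TGG->TAG stop
    call_rec(pos = 1013, ref = "A", alt = "T"),   # first intronic base
    call_rec(pos = 1014, ref = "A", alt = "T"),   # second intronic base
    call_rec(pos = 1015, ref = "A", alt = "T"),   # third: beyond the flank
    call_rec(pos = 1005, ref = "NNN", alt = "N", vtype = "DEL"),  # 2-bp del
    call_rec(pos = 1005, ref = "NNNN", alt = "N", vtype = "DEL"), # 3-bp del
    call_rec(pos = 100, ref = "A", alt = "T"))    # intergenic
  ann <- annotate_variants(cases, gm)
  expect_equal(ann$consequence,
               c("synonymous", "nonsynonymous", "nonsense", "splice_site",
                 "splice_site", "noncoding", "frameshift", "inframe_indel",
                 "noncoding"))
  expect_equal(ann$gene_id[1], "geneP")
  expect_true(is.na(ann$gene_id[9]))

  # geneM (-): cds 0 sits at genomic 5524; CDS starts ATG, so the plus-strand
  # ref there is the complement T. T>C means ATG->GTG (Met->Val).
  m <- annotate_variants(call_rec(pos = 5524, ref = "T", alt = "C"), gm)
  expect_equal(m$gene_id, "geneM")
  expect_equal(m$consequence, "nonsynonymous")
  # third base of the minus-strand codon GCT (cds 3..5; genomic 5519):
  # GCT->GCC is synonymous (Ala), plus-strand alt is the complement G.
  m2 <- annotate_variants(call_rec(pos = 5519, ref = "A", alt = "G"), gm)
  expect_equal(m2$consequence, "synonymous")
})

test_that("filter cascade applies every stage at its printed thresholds", {
  tumor <- rbind(
    call_rec(pos = 101, depth = 4),                      # stage 1: depth < 5
    call_rec(pos = 102, depth = 5),                      # boundary: kept
    call_rec(pos = 103, depth = 201),                    # stage 1: depth > 200
    call_rec(pos = 104, call_quality = 19.5),            # stage 1: quality
    call_rec(pos = 105),                                 # stage 2: in blood
    call_rec(pos = 106),                                 # stage 3: blood 10x/0.25
    call_rec(pos = 107),                                 # stage 3 boundary: kept? no
    call_rec(pos = 108),                                 # blood depth 2: kept
    call_rec(pos = 109),                                 # blood ratio 0.19: kept
    call_rec(pos = 110, uniquely_mapped = FALSE),        # stage 4
    call_rec(pos = 111, detected_by = "WGS"),            # stage 5: dup, WGS only
    call_rec(pos = 112, detected_by = "WGS,WES"),        # stage 5: dup, both
    call_rec(pos = 113),                                 # stage 6: known
    call_rec(pos = 114))                                 # survivor
  blood <- call_rec(pos = 105)
  pileup <- data.frame(chrom = "chr1", pos = c(106, 107, 108, 109),
                       depth = c(10, 3, 2, 30),
                       alt_ratio = c(0.25, 0.2, 0.9, 0.19))
  dup <- data.frame(chrom = "chr1", start = 110, end = 112)  # covers 111,112
  known <- data.frame(chrom = "chr1", pos = 113, ref = "A", alt = "T")

  res <- suppressWarnings(
    filter_somatic(tumor, blood, pileup, dup_regions = dup,
                   known_variants = known))
  expect_setequal(res$variants$pos, c(102, 108, 109, 112, 114))
  expect_equal(res$stages$removed[res$stages$stage > 0], c(3, 1, 2, 1, 1, 1))
  # monotone survivor counts and exact bookkeeping
  expect_true(all(diff(res$stages$remaining) <= 0))
  expect_equal(sum(res$stages$removed) + nrow(res$variants), nrow(tumor))
})

test_that("positions missing from the blood pileup pass stage 3 with a warning", {
  tumor <- call_rec(pos = 500)
  expect_warning(
    res <- filter_somatic(tumor, empty_calls(),
                          data.frame(chrom = "chr1", pos = 1,
                                     depth = 30, alt_ratio = 0.5)),
    "missing from blood pileup")
  expect_equal(nrow(res$variants), 1)
})

test_that("surviving set is invariant to the stage thresholds' bookkeeping order", {
  # the cascade is a conjunction of per-record predicates: filtering twice,
  # with the blood subtraction effectively applied before or after the dup
  # rule, keeps the same survivors
  cfg <- sim_config(genome_length = 5e6, n_chromosomes = 1,
                    germline_rate = 40, somatic_rate = 20, seed = 61)
  gm <- simulate_gene_models(cfg, n_genes = 40)
  v <- simulate_variant_tables(cfg, gm)
  dup <- data.frame(chrom = "chr1", start = 0, end = 2e6)
  a <- filter_somatic(v$tumor, v$blood, v$blood_pileup, dup_regions = dup)
  b1 <- filter_somatic(v$tumor, empty_calls(), v$blood_pileup,
                       dup_regions = dup)
  b <- filter_somatic(b1$variants, v$blood, v$blood_pileup)
  expect_setequal(a$variants$id, b$variants$id)
})

test_that("on clean synthetic tables the cascade is exact", {
  cfg <- sim_config(genome_length = 6e6, n_chromosomes = 2,
                    germline_rate = 80, somatic_rate = 30, seed = 71)
  gm <- simulate_gene_models(cfg, n_genes = 60)
  v <- simulate_variant_tables(cfg, gm)
  res <- filter_somatic(v$tumor, v$blood, v$blood_pileup)
  stage1_ok <- v$truth$somatic_ids[
    v$tumor$depth[match(v$truth$somatic_ids, v$tumor$id)] >= 5]
  expect_setequal(res$variants$id, stage1_ok)
  expect_length(intersect(res$variants$id, v$truth$germline_ids), 0)
})

test_that("mutation rate is count per masked megabase", {
  mask <- data.frame(chrom = "chr1", start = 0, end = 10e6)
  v <- data.frame(chrom = "chr1", pos = round(seq(1, 9e6, length.out = 50)))
  expect_equal(as.numeric(mutation_rate(v, mask)), 5.0)
  expect_equal(as.numeric(mutation_rate(v[0, ], mask)), 0.0)
  outside <- data.frame(chrom = "chr2", pos = 100)
  expect_equal(as.numeric(mutation_rate(outside, mask)), 0.0)
  expect_error(mutation_rate(v, mask[0, ]), "empty")
})

test_that("estimated rate sits in the Poisson band around the true rate", {
  # 2 mutations/Mb over ~ the simulated CDS; averaged over seeds the
  # estimate must match the generating rate
  cfg0 <- sim_config(genome_length = 5e6, n_chromosomes = 1,
                     germline_rate = 0, somatic_rate = 30, seed = 1)
  gm <- simulate_gene_models(cfg0, n_genes = 150)
  mask <- cds_mask(gm)
  mb <- sum(mask$end - mask$start) / 1e6
  rates <- vapply(1:30, function(s) {
    cfg <- sim_config(genome_length = 5e6, n_chromosomes = 1,
                      germline_rate = 0, somatic_rate = 30, seed = 7000 + s)
    v <- simulate_variant_tables(cfg, gm)
    res <- filter_somatic(v$tumor, v$blood, v$blood_pileup)
    as.numeric(mutation_rate(res$variants, mask))
  }, numeric(1))
  se <- sqrt(30 / (mb * 30))  # Poisson standard error of the mean rate
  expect_lt(abs(mean(rates) - 30), 4 * se)
})

test_that("substitution classes collapse onto the pyrimidine reference", {
  snv <- function(ref, alt) data.frame(ref = ref, alt = alt)
  sp <- mutation_spectrum(snv(c("C", "G"), c("T", "A")))
  expect_equal(unname(sp[["C>T"]]), 1.0)
  sp2 <- mutation_spectrum(snv("A", "C"))
  expect_equal(unname(sp2[["T>G"]]), 1.0)
  # uniform over all 12 raw substitutions -> 1/6 per collapsed class
  ref <- rep(c("A", "C", "G", "T"), each = 3)
  alt <- c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G")
  sp3 <- mutation_spectrum(snv(ref, alt))
  expect_equal(as.numeric(sp3), rep(1 / 6, 6))
  expect_equal(sum(sp3), 1, tolerance = 1e-12)
  sp0 <- mutation_spectrum(snv(character(), character()))
  expect_true(attr(sp0, "empty"))
  expect_equal(sum(sp0), 0)
})
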