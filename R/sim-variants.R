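#' Simulate paired tumor/blood variant tables with ground truth
#'
#' Draws germline variants (present in both tumor and blood with allele
#' fraction ~0.5) and somatic variants (tumor only, allele fraction diluted
#' by purity and, inside CNV events, adjusted for tumor copy number:
#' `AF = purity / (purity * c + (1 - purity) * 2)` for one mutated copy).
#' Somatic variants falling in coding sequence are emitted as nonsynonymous
#' versus synonymous substitutions at the configured ns/s ratio (a small
#' fraction as indels), and each driver gene receives its configured number
#' of extra nonsynonymous SNVs. Variant counts are Poisson in the configured
#' per-Mb rates; positions are uniform over the genome.
#'
#' @param config A [sim_config()].
#' @param gm A [gene_models()] object for the same genome.
#' @return A list with
#'   * `tumor`, `blood`: variant `data.frame`s
#'     (`id, chrom, pos, ref, alt, vtype, depth, alt_reads, call_quality,
#'     uniquely_mapped, detected_by`),
#'   * `blood_pileup`: `data.frame(chrom, pos, depth, alt_ratio)` covering
#'     every tumor variant position,
#'   * `truth`: `somatic_ids`, `germline_ids` and `gene_truth`
#'     (injected coding nonsynonymous/synonymous counts per gene).
#' @export
simulate_variant_tables <- function(config, gm) {
  stopifnot(inherits(config, "sim_config"), inherits(gm, "gene_models"))
  .assert(config$somatic_rate >= 0, "somatic_rate must be >= 0")
  set.seed(config$seed + 202L)

  genome_mb <- config$genome_length / 1e6
  mask <- cds_mask(gm)
  mask_gr <- .as_granges0(mask)

  rand_positions <- function(n) {
    chrom <- sample(config$chroms, n, replace = TRUE)
    pos <- sample.int(config$chrom_length, n, replace = TRUE)
    data.frame(chrom = chrom, pos = pos)
  }
  in_cds <- function(df) {
    if (!nrow(df)) return(logical(0))
    !is.na(.fo_first(.as_granges_pos(df), mask_gr))
  }

  # --- germline -------------------------------------------------------------
  n_g <- rpois(1, config$germline_rate * genome_mb)
  germ <- rand_positions(n_g)
  if (n_g) {
    germ$ref <- sample(c("A", "C", "G", "T"), n_g, replace = TRUE)
    cds_hit <- in_cds(germ)
    for (v in which(cds_hit)) {         # keep exonic ref consistent with CDS
      i <- .gene_at(gm, germ$chrom[v], germ$pos[v])
      cp <- .genomic_to_cds(gm, i, germ$pos[v])
      if (!is.na(cp)) germ$ref[v] <- .cds_ref_base(gm, i, cp)
    }
    germ$alt <- vapply(germ$ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
    germ$vtype <- "SNV"
    germ$af <- 0.5
    germ$origin <- "germline"
    germ$in_cds <- cds_hit
  }

  # --- somatic --------------------------------------------------------------
  n_s <- rpois(1, config$somatic_rate * genome_mb)
  som <- rand_positions(n_s)
  som_cds <- in_cds(som)
  coding <- sum(som_cds)
  noncod <- som[!som_cds, , drop = FALSE]
  if (nrow(noncod)) {
    noncod$ref <- sample(c("A", "C", "G", "T"), nrow(noncod), replace = TRUE)
    noncod$alt <- vapply(noncod$ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
    noncod$vtype <- "SNV"
  }
  cod <- .draw_coding_mutations(gm, coding, config$ns_s_ratio,
                                config$indel_fraction)
  drv <- .draw_driver_mutations(gm, config$driver_genes, config$ns_s_ratio)
  som_all <- rbind(
    if (nrow(noncod)) noncod[, c("chrom", "pos", "ref", "alt", "vtype")],
    cod[, c("chrom", "pos", "ref", "alt", "vtype")],
    drv[, c("chrom", "pos", "ref", "alt", "vtype")])
  if (is.null(som_all)) {
    som_all <- data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          vtype = character())
  }
  som_all$origin <- "somatic"
  som_all$in_cds <- in_cds(som_all)
  # purity-diluted AF, copy-number adjusted inside CNV events
  fac <- .tumor_copy_factor(som_all$chrom, som_all$pos - 1L, som_all$pos,
                            config$cnv_events, config$purity)
  som_all$af <- if (nrow(som_all)) config$purity / (2 * fac) else numeric(0)

  both <- rbind(if (n_g) germ[, c("chrom", "pos", "ref", "alt", "vtype",
                                  "af", "origin", "in_cds")],
                som_all[, c("chrom", "pos", "ref", "alt", "vtype",
                            "af", "origin", "in_cds")])
  if (is.null(both)) both <- som_all
  # drop position collisions (vanishingly rare, keeps keys unique)
  both <- both[!duplicated(paste(both$chrom, both$pos)), , drop = FALSE]
  both <- both[order(both$chrom, both$pos), , drop = FALSE]
  both$id <- .variant_key(both)

  emit <- function(df, af_col = df$af) {
    n <- nrow(df)
    depth <- pmax(1L, rpois(n, config$diploid_depth_mean))
    alt_reads <- pmin(depth, pmax(1L, rbinom(n, depth, af_col)))
    data.frame(id = df$id, chrom = df$chrom, pos = df$pos, ref = df$ref,
               alt = df$alt, vtype = df$vtype, depth = depth,
               alt_reads = alt_reads,
               call_quality = round(runif(n, 30, 60), 1),
               uniquely_mapped = rep(TRUE, n),
               detected_by = ifelse(df$in_cds, "WGS,WES", "WGS"),
               stringsAsFactors = FALSE)
  }
  tumor <- emit(both)
  is_g <- both$origin == "germline"
  blood <- emit(both[is_g, , drop = FALSE], af_col = rep(0.5, sum(is_g)))

  pile_depth <- pmax(1L, rpois(nrow(both), config$diploid_depth_mean))
  pile_alt <- ifelse(is_g, rbinom(nrow(both), pile_depth, 0.5) / pile_depth, 0)
  blood_pileup <- data.frame(chrom = both$chrom, pos = both$pos,
                             depth = pile_depth, alt_ratio = pile_alt)

  gene_truth <- .gene_truth_counts(rbind(cod, drv))
  list(tumor = tumor, blood = blood, blood_pileup = blood_pileup,
       truth = list(somatic_ids = both$id[!is_g],
                    germline_ids = both$id[is_g],
                    gene_truth = gene_truth))
}

# Gene row index containing a position (genes assumed non-overlapping).
.gene_at <- function(gm, chrom, pos) {
  .fo_first(GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L)),
            .as_granges0(gm))
}

# Draw n coding somatic mutations at the target ns/s ratio by rejection
# sampling of (gene ~ CDS length, CDS offset, alt base); a fraction become
# small frameshifting indels instead.
.draw_coding_mutations <- function(gm, n, ns_s_ratio, indel_fraction,
                                   genes = NULL) {
  proto <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), vtype = character(),
                      gene_id = character(), class = character())
  if (n == 0) return(proto)
  lens <- cds_length(gm)
  if (!is.null(genes)) lens <- lens[genes]
  idx_all <- match(names(lens), gm$gene_id)
  p_ns <- if (is.infinite(ns_s_ratio)) 1 else ns_s_ratio / (1 + ns_s_ratio)
  out <- vector("list", n)
  for (v in seq_len(n)) {
    if (is.null(genes) && runif(1) < indel_fraction) {
      gi <- idx_all[sample.int(length(lens), 1, prob = lens)]
      cp <- sample.int(lens[[gm$gene_id[gi]]], 1) - 1L
      pos <- .cds_to_genomic(gm, gi, cp)
      del_len <- sample(1:2, 1)
      ref <- paste(rep("N", del_len + 1), collapse = "")
      out[[v]] <- data.frame(chrom = gm$chrom[gi], pos = pos, ref = ref,
                             alt = "N", vtype = "DEL",
                             gene_id = gm$gene_id[gi], class = "frameshift")
      next
    }
    target <- if (runif(1) < p_ns) "ns" else "s"
    repeat {
      gi <- idx_all[sample.int(length(lens), 1, prob = lens)]
      cp <- sample.int(lens[[gm$gene_id[gi]]], 1) - 1L
      ref_cs <- .cds_ref_base(gm, gi, cp, genomic = FALSE)
      alt_cs <- sample(setdiff(c("A", "C", "G", "T"), ref_cs), 1)
      pos <- .cds_to_genomic(gm, gi, cp)
      if (gm$strand[gi] == "+") { ref <- ref_cs; alt <- alt_cs }
      else { ref <- .revcomp1(ref_cs); alt <- .revcomp1(alt_cs) }
      cls <- .consequence_one(
        data.frame(pos = pos, ref = ref, alt = alt, vtype = "SNV"), gm, gi)
      got <- if (cls %in% c("nonsynonymous", "nonsense")) "ns"
             else if (cls == "synonymous") "s" else NA
      if (identical(got, target)) {
        out[[v]] <- data.frame(chrom = gm$chrom[gi], pos = pos, ref = ref,
                               alt = alt, vtype = "SNV",
                               gene_id = gm$gene_id[gi], class = cls)
        break
      }
    }
  }
  do.call(rbind, out)
}

# Extra nonsynonymous SNVs for each configured driver gene.
.draw_driver_mutations <- function(gm, driver_genes, ns_s_ratio) {
  proto <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), vtype = character(),
                      gene_id = character(), class = character())
  if (!nrow(driver_genes)) return(proto)
  .assert(all(driver_genes$gene_id %in% gm$gene_id),
          "driver gene absent from gene models")
  out <- list()
  for (d in seq_len(nrow(driver_genes))) {
    gid <- driver_genes$gene_id[d]
    for (k in seq_len(driver_genes$extra_nssnv[d])) {
      m <- NULL
      repeat {
        m <- .draw_coding_mutations(gm, 1, ns_s_ratio = Inf,
                                    indel_fraction = 0, genes = gid)
        if (m$class %in% c("nonsynonymous", "nonsense")) break
      }
      out[[length(out) + 1]] <- m
    }
  }
  do.call(rbind, out)
}

.gene_truth_counts <- function(cod) {
  if (!nrow(cod)) {
    return(data.frame(gene_id = character(), ns = integer(), s = integer(),
                      indel = integer()))
  }
  genes <- sort(unique(cod$gene_id))
  data.frame(
    gene_id = genes,
    ns = vapply(genes, function(g) sum(cod$gene_id == g &
      cod$class %in% c("nonsynonymous", "nonsense")), integer(1)),
    s = vapply(genes, function(g) sum(cod$gene_id == g &
      cod$class == "synonymous"), integer(1)),
    indel = vapply(genes, function(g) sum(cod$gene_id == g &
      cod$class == "frameshift"), integer(1)),
    row.names = NULL)
}
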