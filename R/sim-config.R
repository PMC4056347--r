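#' Configuration for the synthetic tumor/normal sample generator
#'
#' Bundles every parameter of the synthetic-cohort generator together with its
#' ground truth knobs. Defaults describe a desk-scale version of a typical
#' low-purity gastric-cancer study: ~32x whole-genome depth, 50-kb depth
#' windows, a somatic rate of 2 mutations/Mb, a nonsynonymous:synonymous
#' ratio of 2.5 and moderate negative-binomial depth overdispersion.
#'
#' @param genome_length Total genome size in bases.
#' @param n_chromosomes Number of equally sized chromosomes (named
#'   `"chr1"..."chrN"`).
#' @param window_size Depth window size in bases (default 50 kb).
#' @param purity Tumor cell fraction in `[0, 1]`.
#' @param diploid_depth_mean Mean sequencing depth of diploid regions (reads).
#' @param depth_dispersion Negative-binomial dispersion of window read counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson noise.
#' @param cnv_events `data.frame(chrom, start, end, tumor_cn)` of copy-number
#'   events carried by the tumor cells (0-based half-open). Events must not
#'   overlap.
#' @param somatic_rate Somatic mutation rate, mutations per Mb.
#' @param germline_rate Germline variant rate, variants per Mb.
#' @param ns_s_ratio Target nonsynonymous:synonymous ratio among coding
#'   somatic SNVs (nonsense counted as nonsynonymous).
#' @param driver_genes `data.frame(gene_id, extra_nssnv)`: genes receiving
#'   that many nonsynonymous SNVs above background.
#' @param sv_events `data.frame(chrom1, pos1, chrom2, pos2, type, n_support,
#'   germline)` of structural variants to inject; `type` is one of
#'   `"insertion"`, `"deletion"`, `"inversion"`, `"intra_translocation"`,
#'   `"inter_translocation"`; germline events appear in both tumor and blood.
#' @param noise_pair_rate Scattered discordant noise read pairs per Mb.
#' @param pair_scatter Read-end scatter around true SV breakpoints (bases).
#' @param insert_median,insert_mad Concordant insert-size location/scale used
#'   both to emit and to classify read pairs.
#' @param indel_fraction Fraction of somatic coding mutations emitted as small
#'   indels rather than SNVs.
#' @param seed Mandatory RNG seed; identical configs give identical output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(genome_length = 2e6, n_chromosomes = 2, seed = 1)
#' cfg$purity
#' @export
sim_config <- function(genome_length = 100e6,
                       n_chromosomes = 4,
                       window_size = 50000,
                       purity = 0.6,
                       diploid_depth_mean = 32,
                       depth_dispersion = 0.0025,
                       cnv_events = NULL,
                       somatic_rate = 2,
                       germline_rate = 1000,
                       ns_s_ratio = 2.5,
                       driver_genes = NULL,
                       sv_events = NULL,
                       noise_pair_rate = 1,
                       pair_scatter = 150,
                       insert_median = 500,
                       insert_mad = 50,
                       indel_fraction = 0.05,
                       seed) {
  .assert(!missing(seed) && is.numeric(seed) && length(seed) == 1,
          "sim_config: a single integer 'seed' is mandatory")
  .assert(purity >= 0 && purity <= 1, "purity must be in [0, 1], got %s", purity)
  .assert(somatic_rate >= 0, "somatic_rate must be >= 0")
  .assert(germline_rate >= 0, "germline_rate must be >= 0")
  .assert(genome_length >= window_size, "genome_length smaller than one window")
  .assert(n_chromosomes >= 1, "need at least one chromosome")

  chrom_length <- floor(genome_length / n_chromosomes)
  chroms <- paste0("chr", seq_len(n_chromosomes))

  if (is.null(cnv_events)) {
    cnv_events <- data.frame(chrom = character(), start = integer(),
                             end = integer(), tumor_cn = integer())
  }
  if (nrow(cnv_events)) {
    .assert(all(c("chrom", "start", "end", "tumor_cn") %in% names(cnv_events)),
            "cnv_events needs columns chrom, start, end, tumor_cn")
    .assert(all(cnv_events$chrom %in% chroms), "cnv_events on unknown chromosome")
    .assert(all(cnv_events$start >= 0 & cnv_events$end <= chrom_length),
            "cnv_events outside the genome")
    gr <- .as_granges0(cnv_events)
    ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
    .assert(length(ov) == 0, "cnv_events must not overlap each other")
  }
  if (is.null(driver_genes)) {
    driver_genes <- data.frame(gene_id = character(), extra_nssnv = integer())
  }
  if (is.null(sv_events)) {
    sv_events <- data.frame(chrom1 = character(), pos1 = integer(),
                            chrom2 = character(), pos2 = integer(),
                            type = character(), n_support = integer(),
                            germline = logical())
  } else {
    if (is.null(sv_events$germline)) sv_events$germline <- FALSE
    ok_types <- c("insertion", "deletion", "inversion",
                  "intra_translocation", "inter_translocation")
    .assert(all(sv_events$type %in% ok_types),
            "sv_events$type must be one of: %s", paste(ok_types, collapse = ", "))
    .assert(all(sv_events$chrom1 %in% chroms) && all(sv_events$chrom2 %in% chroms),
            "sv_events on unknown chromosome")
    .assert(all(sv_events$pos1 >= 1 & sv_events$pos1 <= chrom_length) &&
            all(sv_events$pos2 >= 1 & sv_events$pos2 <= chrom_length),
            "sv_events breakpoints outside the genome")
  }

  structure(list(
    genome_length = genome_length, n_chromosomes = n_chromosomes,
    chrom_length = chrom_length, chroms = chroms,
    window_size = window_size, purity = purity,
    diploid_depth_mean = diploid_depth_mean,
    depth_dispersion = depth_dispersion,
    cnv_events = cnv_events, somatic_rate = somatic_rate,
    germline_rate = germline_rate, ns_s_ratio = ns_s_ratio,
    driver_genes = driver_genes, sv_events = sv_events,
    noise_pair_rate = noise_pair_rate, pair_scatter = pair_scatter,
    insert_median = insert_median, insert_mad = insert_mad,
    indel_fraction = indel_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic sample configuration\n")
  cat(sprintf("  genome: %s bp over %d chromosome(s), %d bp windows\n",
              format(x$genome_length, big.mark = ","), x$n_chromosomes,
              x$window_size))
  cat(sprintf("  purity: %.2f, diploid depth %.1fx (dispersion %.4g)\n",
              x$purity, x$diploid_depth_mean, x$depth_dispersion))
  cat(sprintf("  somatic %.3g/Mb, germline %.3g/Mb, ns/s %.2f\n",
              x$somatic_rate, x$germline_rate, x$ns_s_ratio))
  cat(sprintf("  %d CNV event(s), %d SV event(s), %d driver gene(s), seed %d\n",
              nrow(x$cnv_events), nrow(x$sv_events), nrow(x$driver_genes),
              x$seed))
  invisible(x)
}

# Draw negative-binomial counts; dispersion 0 degrades to Poisson.
.rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

# Tumor expected copy factor relative to diploid for a window set:
# (pi * c + (1 - pi) * 2) / 2 within CNV events, 1 elsewhere.
.tumor_copy_factor <- function(chrom, start, end, cnv_events, purity) {
  fac <- rep(1, length(chrom))
  if (!nrow(cnv_events)) return(fac)
  win <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  ev <- .as_granges0(cnv_events)
  hit <- .fo_first(win, ev)
  idx <- !is.na(hit)
  cn <- cnv_events$tumor_cn[hit[idx]]
  fac[idx] <- (purity * cn + (1 - purity) * 2) / 2
  fac
}
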