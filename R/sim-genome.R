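#' Simulate windowed tumor/normal depth tracks with known purity
#'
#' Generates a pair of windowed read-depth tracks for a tumor sample of known
#' cellularity and its matched normal. Window read depths are drawn from a
#' negative binomial around the diploid mean; inside each injected copy-number
#' event with tumor copy number `c`, the tumor mean is scaled by the admixture
#' factor `(purity * c + (1 - purity) * 2) / 2`, which is exactly the mixture
#' of diploid normal cells and aberrant tumor cells that makes heterozygous
#' deletions usable as 1N anchors for purity estimation.
#'
#' @param config A [sim_config()].
#' @return A list with `tumor` and `normal` window `data.frame`s
#'   (`chrom, start, end, depth`; 0-based half-open), and `truth`
#'   (`purity`, the `cnv_events` table, and `copy_factor` per window).
#' @examples
#' cfg <- sim_config(genome_length = 10e6, n_chromosomes = 1, purity = 1,
#'                   cnv_events = data.frame(chrom = "chr1", start = 0,
#'                                           end = 2e6, tumor_cn = 1),
#'                   seed = 7)
#' prof <- simulate_genome_profile(cfg)
#' head(prof$tumor)
#' @export
simulate_genome_profile <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  n_win_per_chrom <- config$chrom_length %/% config$window_size
  .assert(n_win_per_chrom >= 1, "chromosomes shorter than one window")
  chrom <- rep(config$chroms, each = n_win_per_chrom)
  start <- rep.int((seq_len(n_win_per_chrom) - 1L) * config$window_size,
                   config$n_chromosomes)
  end <- start + config$window_size

  # window mean depth modeled through a read count at 100-bp read granularity
  reads_per_win <- config$diploid_depth_mean * config$window_size / 100
  fac <- .tumor_copy_factor(chrom, start, end, config$cnv_events, config$purity)

  normal_counts <- .rnb(length(chrom), reads_per_win, config$depth_dispersion)
  tumor_counts <- .rnb(length(chrom), reads_per_win * fac, config$depth_dispersion)

  to_depth <- function(counts) counts * 100 / config$window_size
  list(
    tumor = data.frame(chrom = chrom, start = start, end = end,
                       depth = to_depth(tumor_counts)),
    normal = data.frame(chrom = chrom, start = start, end = end,
                        depth = to_depth(normal_counts)),
    truth = list(purity = config$purity, cnv_events = config$cnv_events,
                 copy_factor = fac)
  )
}
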