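#' Simulate cohort-level per-gene mutation counts
#'
#' Gene-level counterpart of the full variant simulator, for studying the
#' driver-score statistics at scale: per-gene cohort-wide nonsynonymous and
#' synonymous SNV counts are drawn as independent Poissons from a shared
#' per-base mutation rate and ns/s ratio over the supplied covered lengths,
#' and selected driver genes receive a fixed excess of nonsynonymous
#' counts.
#'
#' @param covered_bases Named integer vector: efficiently covered bases per
#'   gene.
#' @param s_rate Synonymous mutation rate per covered base (cohort-wide).
#' @param ns_s_ratio True nonsynonymous:synonymous rate ratio.
#' @param drivers Named integer vector of extra nonsynonymous counts for
#'   driver genes (default none).
#' @param seed RNG seed.
#' @return List with `gene_counts` (`data.frame(gene_id, n_samples, ns, s,
#'   splice, indel)` compatible with [driver_scan()]), `coverages`, and the
#'   true `exp_ns` per gene.
#' @export
simulate_mutation_counts <- function(covered_bases, s_rate, ns_s_ratio,
                                     drivers = integer(), seed) {
  set.seed(seed)
  genes <- names(covered_bases)
  .assert(!is.null(genes), "covered_bases must be named by gene")
  mu_s <- covered_bases * s_rate
  mu_ns <- mu_s * ns_s_ratio
  s <- rpois(length(genes), mu_s)
  ns <- rpois(length(genes), mu_ns)
  if (length(drivers)) {
    idx <- match(names(drivers), genes)
    .assert(!anyNA(idx), "driver gene absent from covered_bases")
    ns[idx] <- ns[idx] + drivers
  }
  gene_counts <- data.frame(gene_id = genes, n_samples = as.integer(ns > 0),
                            ns = ns, s = s,
                            splice = 0L, indel = 0L, row.names = NULL)
  list(gene_counts = gene_counts,
       coverages = data.frame(gene_id = genes,
                              covered_bases = as.integer(covered_bases)),
       exp_ns = mu_ns)
}
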