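#' Cohort background nonsynonymous mutation rate
#'
#' The synonymous mutations observed across the cohort anchor the neutral
#' background: `ns_s_ratio = total nsSNVs / total sSNVs`, and the expected
#' nonsynonymous rate per sufficiently covered base is
#' `ns_s_ratio * total sSNVs / total covered bases`. Nonsense mutations
#' count within the nonsynonymous class.
#'
#' @param gene_counts `data.frame(gene_id, ns, s)` of observed cohort-wide
#'   nonsynonymous and synonymous SNV counts per gene (see
#'   [count_gene_mutations()]).
#' @param coverages `data.frame(gene_id, covered_bases)` of efficiently
#'   covered bases per gene (normal depth >= 4 and tumor depth >= 3 in the
#'   study design).
#' @return List with `ns_s_ratio`, `ns_rate_per_base`, `total_ns`,
#'   `total_s`, `total_bases`.
#' @export
background_rates <- function(gene_counts, coverages) {
  total_ns <- sum(gene_counts$ns)
  total_s <- sum(gene_counts$s)
  if (total_s == 0) {
    stop("no synonymous SNVs in the cohort: the background rate is ",
         "undefined; supply pseudocounts or a larger cohort", call. = FALSE)
  }
  total_bases <- sum(coverages$covered_bases)
  .assert(total_bases > 0, "total covered bases must be positive")
  ns_s_ratio <- total_ns / total_s
  list(ns_s_ratio = ns_s_ratio,
       ns_rate_per_base = ns_s_ratio * total_s / total_bases,
       total_ns = total_ns, total_s = total_s, total_bases = total_bases)
}

#' Expected nonsynonymous count for one gene
#'
#' `exp_ns = background rate per base x covered bases`, optionally weighted
#' by the gene's nonsynonymous-site fraction relative to the cohort average
#' (identity weighting when site fractions are not supplied).
#'
#' @param covered_bases Efficiently covered bases of the gene.
#' @param background Output of [background_rates()].
#' @param ns_site_weight Optional relative nonsynonymous-opportunity weight
#'   (default 1).
#' @return Expected nonsynonymous count (numeric).
#' @export
expected_nssnv <- function(covered_bases, background, ns_site_weight = 1) {
  background$ns_rate_per_base * covered_bases * ns_site_weight
}

#' Poisson upper-tail probability of an observed mutation count
#'
#' `P = sum_{k >= obs} exp(-mu) mu^k / k!`; an observation of 0 has
#' probability 1 by convention.
#'
#' @param obs Observed count (>= 0).
#' @param exp_count Expected count (> 0).
#' @return Upper-tail probability in `(0, 1]`.
#' @examples
#' poisson_pvalue(1, 1)    # 1 - exp(-1)
#' poisson_pvalue(0, 0.5)  # 1
#' @export
poisson_pvalue <- function(obs, exp_count) {
  .assert(all(exp_count > 0), "expected count must be positive")
  .assert(all(obs >= 0), "observed count must be non-negative")
  ppois(obs - 1, exp_count, lower.tail = FALSE)
}

#' Rank genes by adjusted Poisson driver score
#'
#' Benjamini-Hochberg adjusts the raw Poisson p-values across the tested
#' family and defines `score = -log10(adjusted p)`. Genes are ranked by raw
#' p ascending, ties broken by observed count descending, then gene id.
#'
#' @param results `data.frame` with `gene_id`, `obs_ns`, `exp_ns`,
#'   `p_value` (one row per tested gene).
#' @param n_tested Size of the multiplicity family (default `nrow(results)`).
#' @return The input with `adj_p`, `score` columns, sorted, classed
#'   `driver_table`.
#' @export
score_and_rank <- function(results, n_tested = nrow(results)) {
  results$adj_p <- p.adjust(results$p_value, method = "BH", n = n_tested)
  results$score <- -log10(results$adj_p)
  o <- order(results$p_value, -results$obs_ns, results$gene_id)
  results <- results[o, , drop = FALSE]
  rownames(results) <- NULL
  class(results) <- c("driver_table", class(results))
  results
}

#' Per-gene cohort mutation counts from annotated somatic variants
#'
#' @param variants Annotated somatic variant `data.frame` (output of
#'   [annotate_variants()], possibly concatenated over samples with a
#'   `sample` column).
#' @return `data.frame(gene_id, n_samples, ns, s, splice, indel)`.
#' @export
count_gene_mutations <- function(variants) {
  v <- variants[!is.na(variants$gene_id), , drop = FALSE]
  genes <- sort(unique(v$gene_id))
  cnt <- function(g, cond) sum(v$gene_id == g & cond)
  ns_cls <- v$consequence %in% c("nonsynonymous", "nonsense")
  data.frame(
    gene_id = genes,
    n_samples = vapply(genes, function(g) {
      if (is.null(v$sample)) as.integer(any(v$gene_id == g))
      else length(unique(v$sample[v$gene_id == g]))
    }, integer(1)),
    ns = vapply(genes, function(g) cnt(g, ns_cls), integer(1)),
    s = vapply(genes, function(g) cnt(g, v$consequence == "synonymous"),
               integer(1)),
    splice = vapply(genes, function(g) cnt(g, v$consequence == "splice_site"),
                    integer(1)),
    indel = vapply(genes, function(g)
      cnt(g, v$consequence %in% c("frameshift", "inframe_indel")), integer(1)),
    row.names = NULL)
}

#' Scan a cohort for candidate driver genes
#'
#' Computes the synonymous-anchored background, the per-gene expected
#' nonsynonymous count, the Poisson upper-tail p-value and the
#' BH-adjusted driver score for every gene with positive coverage. Genes
#' with no observed nonsynonymous mutation are reported with `p = 1` rather
#' than dropped, keeping the multiplicity family well defined. By default
#' only nonsynonymous SNVs enter the observed count; set
#' `include_indels_splice = TRUE` to add indels and splice-site SNVs.
#'
#' @param gene_counts Output of [count_gene_mutations()] covering the cohort
#'   (genes absent from it count as unmutated).
#' @param coverages `data.frame(gene_id, covered_bases)`; genes with zero
#'   covered bases are excluded and reported in the `excluded` attribute.
#' @param include_indels_splice Count indels and splice-site SNVs in the
#'   observed statistic (default `FALSE`).
#' @return A `driver_table` (see [score_and_rank()]) with one row per
#'   covered gene.
#' @export
driver_scan <- function(gene_counts, coverages,
                        include_indels_splice = FALSE) {
  excluded <- coverages$gene_id[coverages$covered_bases <= 0]
  cov <- coverages[coverages$covered_bases > 0, , drop = FALSE]
  m <- match(cov$gene_id, gene_counts$gene_id)
  obs <- ifelse(is.na(m), 0L, gene_counts$ns[m])
  if (include_indels_splice) {
    obs <- obs + ifelse(is.na(m), 0L, gene_counts$splice[m] +
                          gene_counts$indel[m])
  }
  bg <- background_rates(gene_counts, cov)
  exp_ns <- expected_nssnv(cov$covered_bases, bg)
  res <- data.frame(
    gene_id = cov$gene_id,
    n_samples_mutated = ifelse(is.na(m), 0L, gene_counts$n_samples[m]),
    obs_ns = obs, exp_ns = exp_ns,
    p_value = poisson_pvalue(obs, exp_ns))
  out <- score_and_rank(res)
  attr(out, "background") <- bg
  attr(out, "excluded") <- excluded
  out
}

#' @export
print.driver_table <- function(x, n = 10, ...) {
  cat(sprintf("Driver gene table: %d genes tested\n", nrow(x)))
  bg <- attr(x, "background")
  if (!is.null(bg)) {
    cat(sprintf("  background ns/s = %.2f, ns rate = %.3g per covered base\n",
                bg$ns_s_ratio, bg$ns_rate_per_base))
  }
  print.data.frame(head(as.data.frame(x), n), digits = 4)
  invisible(x)
}
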