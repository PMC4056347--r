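#' Integrated per-gene alteration matrix
#'
#' Combines the three somatic call sets of a cohort - point mutations,
#' gene-level copy-number states and SVS gene breakages - into a long-format
#' alteration matrix: one row per (gene, sample, category), categories
#' `SNV`, `INDEL`, `CNV_loss`, `CNV_gain`, `SV_breakpoint`. Point SNVs are
#' counted when their consequence alters the product (nonsynonymous,
#' nonsense or splice-site); synonymous and noncoding calls are ignored.
#'
#' @param variants Annotated somatic variants over all samples
#'   (`sample, gene_id, vtype, consequence`), or `NULL`.
#' @param gene_cnv Per-sample gene copy status
#'   (`sample, gene_id, state` with states from [classify_segment()] or
#'   `"gain"/"loss"`), or `NULL`.
#' @param impaired_genes `data.frame(sample, gene_id)` of SVS breakage
#'   calls, or `NULL`.
#' @param samples `data.frame(sample, type)` declaring every cohort sample
#'   and its label (e.g. `"DGC"`/`"IGC"`); call sets mentioning unknown
#'   samples are an error.
#' @return Object of class `alteration_matrix`: long `data.frame(gene_id,
#'   sample, category)` with the sample table in `attr(x, "samples")`.
#' @export
build_alteration_matrix <- function(variants = NULL, gene_cnv = NULL,
                                    impaired_genes = NULL, samples) {
  .assert(is.data.frame(samples) && all(c("sample", "type") %in% names(samples)),
          "samples must be a data.frame(sample, type)")
  check_samples <- function(df, what) {
    if (!is.null(df) && nrow(df)) {
      unknown <- setdiff(unique(df$sample), samples$sample)
      .assert(length(unknown) == 0, "unknown sample id in %s: %s", what,
              paste(unknown, collapse = ", "))
    }
  }
  check_samples(variants, "variants")
  check_samples(gene_cnv, "gene_cnv")
  check_samples(impaired_genes, "impaired_genes")

  rows <- list()
  add <- function(df) if (!is.null(df) && nrow(df))
    rows[[length(rows) + 1]] <<- df
  if (!is.null(variants) && nrow(variants)) {
    v <- variants[!is.na(variants$gene_id), , drop = FALSE]
    snv <- v[v$vtype == "SNV" &
             v$consequence %in% c("nonsynonymous", "nonsense", "splice_site"), ]
    indel <- v[v$vtype %in% c("INS", "DEL"), ]
    add(data.frame(gene_id = snv$gene_id, sample = snv$sample,
                   category = rep("SNV", nrow(snv))))
    add(data.frame(gene_id = indel$gene_id, sample = indel$sample,
                   category = rep("INDEL", nrow(indel))))
  }
  if (!is.null(gene_cnv) && nrow(gene_cnv)) {
    loss <- gene_cnv$state %in% c("deleted", "loss")
    gain <- gene_cnv$state %in% c("duplicated", "gain")
    add(data.frame(gene_id = gene_cnv$gene_id[loss],
                   sample = gene_cnv$sample[loss],
                   category = rep("CNV_loss", sum(loss))))
    add(data.frame(gene_id = gene_cnv$gene_id[gain],
                   sample = gene_cnv$sample[gain],
                   category = rep("CNV_gain", sum(gain))))
  }
  if (!is.null(impaired_genes) && nrow(impaired_genes)) {
    add(data.frame(gene_id = impaired_genes$gene_id,
                   sample = impaired_genes$sample,
                   category = rep("SV_breakpoint", nrow(impaired_genes))))
  }
  m <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), sample = character(),
               category = character())
  m <- unique(m)
  m <- m[order(m$gene_id, m$sample, m$category), , drop = FALSE]
  rownames(m) <- NULL
  structure(m, samples = samples,
            class = c("alteration_matrix", class(m)))
}

#' Read a published-style alteration table
#'
#' Parses a TSV with columns `sample, type, alteration, region` (one row
#' per alteration of one gene across samples, as printed in integrated
#' alteration tables) into an [build_alteration_matrix()]-shaped object for
#' a single gene. Alteration values `SNV` (including `Splice site`), `INS`/
#' `DEL`, `Loss`, `Gain` and `Break point` map onto the matrix categories.
#'
#' @param path TSV file path.
#' @param gene_id Gene the table describes.
#' @param samples `data.frame(sample, type)` of the full cohort (samples
#'   with no alteration are legitimate empty rows).
#' @return An `alteration_matrix`.
#' @export
read_alteration_table <- function(path, gene_id, samples) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  .assert(all(c("sample", "alteration") %in% names(tab)),
          "alteration table needs 'sample' and 'alteration' columns")
  map <- c("SNV" = "SNV", "Splice site" = "SNV", "INS" = "INDEL",
           "DEL" = "INDEL", "Loss" = "CNV_loss", "Gain" = "CNV_gain",
           "Break point" = "SV_breakpoint")
  kind <- if ("kind" %in% names(tab)) tab$kind else tab$alteration
  category <- ifelse(kind %in% names(map), map[kind],
                     ifelse(tab$alteration %in% names(map),
                            map[tab$alteration], "SNV"))
  m <- unique(data.frame(gene_id = gene_id, sample = tab$sample,
                         category = category))
  m <- m[order(m$gene_id, m$sample, m$category), , drop = FALSE]
  rownames(m) <- NULL
  structure(m, samples = samples,
            class = c("alteration_matrix", class(m)))
}

#' Mutual exclusivity of two alteration classes in one gene
#'
#' Partitions the cohort by presence of class-A alterations (point
#' mutations by default) and class-B alterations (copy-number loss) of a
#' gene, reporting the co-occurrence fraction `both / n_samples`. In
#' CDH1-style tumor suppressors, point mutation and copy loss are expected
#' to be largely mutually exclusive.
#'
#' @param matrix An `alteration_matrix`.
#' @param gene_id Gene to analyze.
#' @param classA,classB Category sets (defaults `c("SNV","INDEL")` and
#'   `"CNV_loss"`).
#' @return List with `A_only, B_only, both, neither, n_samples,
#'   fraction_both`.
#' @export
mutual_exclusivity <- function(matrix, gene_id,
                               classA = c("SNV", "INDEL"),
                               classB = "CNV_loss") {
  samples <- attr(matrix, "samples")$sample
  sub <- matrix[matrix$gene_id == gene_id, , drop = FALSE]
  hasA <- samples %in% sub$sample[sub$category %in% classA]
  hasB <- samples %in% sub$sample[sub$category %in% classB]
  list(A_only = sum(hasA & !hasB), B_only = sum(!hasA & hasB),
       both = sum(hasA & hasB), neither = sum(!hasA & !hasB),
       n_samples = length(samples),
       fraction_both = sum(hasA & hasB) / length(samples))
}

#' Mutated-gene overlap between two cohort groups
#'
#' Counts genes with at least one qualifying alteration per group and their
#' overlap: `n_union = n_A + n_B - n_common` and
#' `pct_common = 100 * n_common / n_union`.
#'
#' @param genes_A,genes_B Character vectors of mutated genes per group, or
#'   an `alteration_matrix` plus `group_A`/`group_B` sample-type labels.
#' @param matrix Optional `alteration_matrix` used with `group_A`/`group_B`.
#' @param group_A,group_B Sample-type labels selecting the two groups from
#'   `matrix` (memberships must be disjoint).
#' @param categories Categories counted as "mutated" when extracting from a
#'   matrix (default `c("SNV", "INDEL")`).
#' @return List with `n_A, n_B, n_common, n_union, pct_common`.
#' @examples
#' cohort_compare(genes_A = paste0("g", 1:10), genes_B = paste0("g", 6:12))
#' @export
cohort_compare <- function(genes_A = NULL, genes_B = NULL, matrix = NULL,
                           group_A = NULL, group_B = NULL,
                           categories = c("SNV", "INDEL")) {
  if (!is.null(matrix)) {
    samples <- attr(matrix, "samples")
    sA <- samples$sample[samples$type == group_A]
    sB <- samples$sample[samples$type == group_B]
    .assert(length(intersect(sA, sB)) == 0,
            "group memberships overlap: %s", paste(intersect(sA, sB),
                                                   collapse = ", "))
    sel <- matrix$category %in% categories
    genes_A <- unique(matrix$gene_id[sel & matrix$sample %in% sA])
    genes_B <- unique(matrix$gene_id[sel & matrix$sample %in% sB])
  }
  genes_A <- unique(genes_A); genes_B <- unique(genes_B)
  n_common <- length(intersect(genes_A, genes_B))
  n_union <- length(union(genes_A, genes_B))
  stopifnot(n_union == length(genes_A) + length(genes_B) - n_common)
  list(n_A = length(genes_A), n_B = length(genes_B),
       n_common = n_common, n_union = n_union,
       pct_common = if (n_union) 100 * n_common / n_union else NA_real_)
}
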