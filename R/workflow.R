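#' Simulate the complete input bundle for one tumor/blood pair
#'
#' Convenience wrapper tying the generators together: depth windows, variant
#' tables with blood pileup, and discordant read pairs, all under one seed
#' with their ground truth.
#'
#' @param config A [sim_config()].
#' @param gm Optional [gene_models()]; simulated from the config when
#'   omitted.
#' @param n_genes Genes to simulate when `gm` is omitted.
#' @return A list with `gene_models`, `tumor_windows`, `normal_windows`,
#'   `tumor_calls`, `blood_calls`, `blood_pileup`, `tumor_pairs`,
#'   `blood_pairs` and `truth` (merged across generators).
#' @export
simulate_sample <- function(config, gm = NULL, n_genes = 200) {
  if (is.null(gm)) gm <- simulate_gene_models(config, n_genes = n_genes)
  prof <- simulate_genome_profile(config)
  vars <- simulate_variant_tables(config, gm)
  pairs <- simulate_read_pairs(config)
  list(gene_models = gm,
       tumor_windows = prof$tumor, normal_windows = prof$normal,
       tumor_calls = vars$tumor, blood_calls = vars$blood,
       blood_pileup = vars$blood_pileup,
       tumor_pairs = pairs$tumor, blood_pairs = pairs$blood,
       truth = c(prof$truth, vars$truth, pairs$truth))
}

.stage_check <- function(stage, inputs, fields) {
  for (f in fields) {
    if (is.null(inputs[[f]])) {
      stop(sprintf("stage %s: missing required input '%s'", stage, f),
           call. = FALSE)
    }
  }
}

#' Run the full per-sample analysis
#'
#' Executes the pipeline on one tumor/blood pair: read-pair classification
#' and SVS clustering with germline subtraction, purity estimation (somatic
#' deletion SVSs anchor the low-purity fallback), the somatic variant
#' filter cascade with annotation and mutation statistics, copy-number
#' segmentation with gene status, and gene breakage / fusion calling.
#' Deterministic given fixed inputs; a failing stage aborts with the stage
#' name.
#'
#' @param inputs Input bundle as produced by [simulate_sample()] (or
#'   assembled from files via the readers in this package); optional
#'   elements `dup_regions` and `known_variants` feed the filter cascade.
#' @param params Optional overrides: `min_normal_depth`, `prominence`,
#'   `lambda`, `join_dist`, `min_support`, `fusion_min_support`,
#'   `exon_filter`, `library_stats`, `cnv_convention`.
#' @return Object of class `sample_run`: list with `purity`, `somatic`
#'   (variants + stage log), `mutation_rate`, `spectrum`, `svs`,
#'   `impaired_genes`, `fusions`, `cnv_segments`, `gene_cnv`.
#' @export
run_sample <- function(inputs, params = list()) {
  p <- function(name, default) params[[name]] %||% default
  gm <- inputs$gene_models
  .stage_check("sv_fusion", inputs, c("tumor_pairs", "blood_pairs"))
  lib <- p("library_stats", list(median = 500, mad = 50, k = 3))
  t_cls <- classify_pairs(inputs$tumor_pairs, lib)
  b_cls <- classify_pairs(inputs$blood_pairs, lib)
  join <- p("join_dist", 400); msup <- p("min_support", 4)
  t_svs <- cluster_svs(t_cls, join_dist = join, min_support = msup)
  b_svs <- cluster_svs(b_cls, join_dist = join, min_support = msup)
  svs <- somatic_svs(t_svs, b_svs)

  .stage_check("purity", inputs, c("tumor_windows", "normal_windows"))
  del_regions <- function(sv) {
    d <- sv[sv$sv_type == "deletion", , drop = FALSE]
    data.frame(chrom = d$chrom1, start = d$bp1_start - 1L, end = d$bp2_end)
  }
  purity <- estimate_purity(
    inputs$tumor_windows, inputs$normal_windows,
    somatic_deletions = del_regions(t_svs),
    blood_deletions = del_regions(b_svs),
    min_normal_depth = p("min_normal_depth", 10),
    prominence = p("prominence", 0.1))

  .stage_check("somatic_variants", inputs,
               c("tumor_calls", "blood_calls", "blood_pileup"))
  somatic <- filter_somatic(inputs$tumor_calls, inputs$blood_calls,
                            inputs$blood_pileup,
                            dup_regions = inputs$dup_regions,
                            known_variants = inputs$known_variants)
  ann <- annotate_variants(somatic$variants, gm)
  rate <- mutation_rate(ann, cds_mask(gm))
  spectrum <- mutation_spectrum(ann[ann$vtype == "SNV", , drop = FALSE])

  bins <- data.frame(
    chrom = inputs$tumor_windows$chrom, start = inputs$tumor_windows$start,
    end = inputs$tumor_windows$end,
    tumor_count = inputs$tumor_windows$depth,
    normal_count = inputs$normal_windows$depth)
  segs <- classify_segments(
    segment_depth_bins(bins, lambda = p("lambda", 100)),
    convention = p("cnv_convention", "wgs"))
  gene_cnv <- gene_copy_status(segs, gm)

  impaired <- gene_breakage(svs, gm, exon_filter = p("exon_filter", FALSE))
  fusions <- call_fusions(svs, gm,
                          min_support = p("fusion_min_support", 11))

  structure(list(purity = purity, somatic = list(variants = ann,
                                                 stages = somatic$stages),
                 mutation_rate = as.numeric(rate),
                 rate_detail = attributes(rate),
                 spectrum = spectrum, svs = svs,
                 impaired_genes = impaired, fusions = fusions,
                 cnv_segments = segs, gene_cnv = gene_cnv),
            class = "sample_run")
}

#' @export
print.sample_run <- function(x, ...) {
  cat("Per-sample profiling run\n")
  print(x$purity)
  cat(sprintf("  somatic variants: %d (rate %.2f/Mb)\n",
              nrow(x$somatic$variants), x$mutation_rate))
  cat(sprintf("  somatic SVSs: %d; impaired genes: %d; fusions: %d\n",
              nrow(x$svs), length(x$impaired_genes), nrow(x$fusions)))
  cat(sprintf("  CNV segments: %d (%d non-neutral)\n", nrow(x$cnv_segments),
              sum(x$cnv_segments$state != "neutral")))
  invisible(x)
}

#' Run the cohort-level analysis
#'
#' Runs [run_sample()] for every tumor/blood pair, then aggregates: the
#' per-sample purity/mutation-rate/spectrum table, the cohort driver scan,
#' the structural-variant count summary, the integrated alteration matrix,
#' and the two-group mutated-gene comparison (skipped with a warning when
#' only one group label is present). Every aggregate is assembled directly
#' from the per-sample stage outputs.
#'
#' @param cohort Named list of per-sample input bundles (see
#'   [run_sample()]); all samples must share the gene models.
#' @param sample_types Named character vector of group labels
#'   (e.g. `"DGC"`/`"IGC"`) for the same sample names.
#' @param params Optional stage parameter overrides, passed through.
#' @return Object of class `cohort_report`.
#' @export
run_cohort <- function(cohort, sample_types, params = list()) {
  .assert(length(cohort) >= 1 && !is.null(names(cohort)),
          "cohort must be a named list of sample input bundles")
  .assert(all(names(cohort) %in% names(sample_types)),
          "every sample needs a type label")
  gm <- cohort[[1]]$gene_models
  runs <- lapply(names(cohort), function(s) run_sample(cohort[[s]], params))
  names(runs) <- names(cohort)

  per_sample <- do.call(rbind, lapply(names(runs), function(s) {
    r <- runs[[s]]
    data.frame(sample = s, type = unname(sample_types[s]),
               purity = r$purity$P, purity_method = r$purity$method,
               mutation_rate = r$mutation_rate,
               n_somatic = nrow(r$somatic$variants),
               n_svs = nrow(r$svs), n_fusions = nrow(r$fusions))
  }))

  all_variants <- do.call(rbind, lapply(names(runs), function(s)
    cbind(sample = s, runs[[s]]$somatic$variants)))
  gene_counts <- count_gene_mutations(all_variants)
  coverages <- data.frame(gene_id = gm$gene_id,
                          covered_bases = as.integer(cds_length(gm)))
  drivers <- driver_scan(gene_counts, coverages)

  sv_summary <- summarize_sv_counts(lapply(runs, `[[`, "svs"), sample_types)

  samples_df <- data.frame(sample = names(runs),
                           type = unname(sample_types[names(runs)]))
  matrix <- build_alteration_matrix(
    variants = all_variants,
    gene_cnv = do.call(rbind, lapply(names(runs), function(s)
      cbind(sample = s, runs[[s]]$gene_cnv))),
    impaired_genes = do.call(rbind, lapply(names(runs), function(s) {
      g <- runs[[s]]$impaired_genes
      if (length(g)) data.frame(sample = s, gene_id = g) else NULL
    })),
    samples = samples_df)

  labs <- unique(samples_df$type)
  comparison <- if (length(labs) >= 2) {
    cohort_compare(matrix = matrix, group_A = labs[1], group_B = labs[2])
  } else {
    warning("single-type cohort: group comparison skipped", call. = FALSE)
    NULL
  }

  structure(list(samples = runs, per_sample = per_sample,
                 drivers = drivers, sv_summary = sv_summary,
                 alteration_matrix = matrix, comparison = comparison,
                 comparison_groups = if (length(labs) >= 2) labs[1:2] else labs),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report: %d samples\n", nrow(x$per_sample)))
  print.data.frame(x$per_sample, digits = 3, row.names = FALSE)
  cat("\nTop driver candidates:\n")
  print.data.frame(head(as.data.frame(x$drivers), 5), digits = 3,
                   row.names = FALSE)
  if (!is.null(x$comparison)) {
    cat(sprintf("\nMutated genes: %d (%s) / %d (%s), %d common (%.1f%% of union)\n",
                x$comparison$n_A, x$comparison_groups[1],
                x$comparison$n_B, x$comparison_groups[2],
                x$comparison$n_common, x$comparison$pct_common))
  }
  invisible(x)
}
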