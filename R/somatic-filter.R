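#' Somatic SNV/indel filtering cascade against the matched blood sample
#'
#' Applies the paired tumor/blood somatic filter in six fixed stages, each
#' logged with removal counts:
#'
#' 1. keep tumor calls with depth in `[5, 200]` and call quality >= 20;
#' 2. drop calls present in the blood call set (position + alleles);
#' 3. drop calls where the blood pileup has depth >= 3 **and** alternate
#'    ratio >= 0.2 (residual germline evidence);
#' 4. keep only uniquely mapped calls;
#' 5. inside duplicated regions (>= 90%-identity segmental duplications,
#'    supplied as a mask) keep only calls detected by both WGS and WES;
#' 6. drop calls present in any known-variant set (dbSNP-style or
#'    panel-of-normals-style exclusion lists).
#'
#' The stage order only affects the per-stage bookkeeping; the surviving set
#' is order-independent.
#'
#' @param tumor_calls,blood_calls Variant `data.frame`s with columns
#'   `chrom, pos, ref, alt, vtype, depth, alt_reads, call_quality,
#'   uniquely_mapped, detected_by` (`detected_by` a comma-joined subset of
#'   `"WGS","WES"`).
#' @param blood_pileup `data.frame(chrom, pos, depth, alt_ratio)`; tumor
#'   positions missing from it are treated as blood depth 0 (stage 3 passes)
#'   and counted in a warning.
#' @param dup_regions Optional `data.frame(chrom, start, end)` duplication
#'   mask (0-based half-open).
#' @param known_variants Optional `data.frame(chrom, pos, ref, alt)` or list
#'   of such tables.
#' @param min_depth,max_depth,min_quality Stage-1 thresholds (5, 200, 20).
#' @param blood_min_depth,blood_min_ratio Stage-3 thresholds (3, 0.2).
#' @return List with `variants` (the surviving calls) and `stages`
#'   (`data.frame(stage, description, removed, remaining)`).
#' @export
filter_somatic <- function(tumor_calls, blood_calls,
                           blood_pileup = NULL, dup_regions = NULL,
                           known_variants = NULL,
                           min_depth = 5, max_depth = 200, min_quality = 20,
                           blood_min_depth = 3, blood_min_ratio = 0.2) {
  v <- tumor_calls
  log_rows <- list()
  note <- function(stage, desc, keep) {
    log_rows[[length(log_rows) + 1]] <<- data.frame(
      stage = stage, description = desc,
      removed = sum(!keep), remaining = sum(keep))
    v[keep, , drop = FALSE]
  }

  keep1 <- v$depth >= min_depth & v$depth <= max_depth &
    v$call_quality >= min_quality
  v <- note(1L, sprintf("depth in [%d, %d], quality >= %g",
                        min_depth, max_depth, min_quality), keep1)

  keep2 <- !(.variant_key(v) %in% .variant_key(blood_calls))
  v <- note(2L, "not called in blood", keep2)

  if (is.null(blood_pileup) || !nrow(blood_pileup)) {
    bp_depth <- rep(0, nrow(v)); bp_ratio <- rep(0, nrow(v))
    n_missing <- nrow(v)
  } else {
    key <- paste(v$chrom, v$pos)
    m <- match(key, paste(blood_pileup$chrom, blood_pileup$pos))
    n_missing <- sum(is.na(m))
    bp_depth <- ifelse(is.na(m), 0, blood_pileup$depth[m])
    bp_ratio <- ifelse(is.na(m), 0, blood_pileup$alt_ratio[m])
  }
  if (n_missing > 0) {
    warning(n_missing, " tumor position(s) missing from blood pileup; ",
            "treated as blood depth 0", call. = FALSE)
  }
  keep3 <- !(bp_depth >= blood_min_depth & bp_ratio >= blood_min_ratio)
  v <- note(3L, sprintf("blood pileup depth < %g or alt ratio < %g",
                        blood_min_depth, blood_min_ratio), keep3)

  v <- note(4L, "uniquely mapped", as.logical(v$uniquely_mapped))

  if (!is.null(dup_regions) && nrow(dup_regions) && nrow(v)) {
    in_dup <- !is.na(.fo_first(.as_granges_pos(v), .as_granges0(dup_regions)))
    both <- vapply(strsplit(v$detected_by, ","), function(s)
      all(c("WGS", "WES") %in% trimws(s)), logical(1))
    keep5 <- !in_dup | both
  } else {
    keep5 <- rep(TRUE, nrow(v))
  }
  v <- note(5L, "in duplicated region only if detected by WGS and WES", keep5)

  if (!is.null(known_variants)) {
    if (is.data.frame(known_variants)) known_variants <- list(known_variants)
    known_keys <- unlist(lapply(known_variants, .variant_key))
    keep6 <- !(.variant_key(v) %in% known_keys)
  } else {
    keep6 <- rep(TRUE, nrow(v))
  }
  v <- note(6L, "not in known-variant sets", keep6)

  stages <- do.call(rbind, log_rows)
  stages <- rbind(data.frame(stage = 0L, description = "input",
                             removed = 0L, remaining = nrow(tumor_calls)),
                  stages)
  list(variants = v, stages = stages)
}
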