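#' Per-window tumor:normal depth ratios
#'
#' Divides the tumor by the normal depth over identically partitioned
#' windows, dropping windows whose normal depth falls below a floor (ratio
#' blow-up protection). The purity formula downstream is invariant to any
#' global rescaling of either track, so ratios are normalized to median 1
#' purely for diagnostics.
#'
#' @param tumor_windows,normal_windows `data.frame(chrom, start, end, depth)`
#'   on identical coordinates (0-based half-open).
#' @param min_normal_depth Windows with normal depth below this are dropped
#'   (default 10).
#' @param normalize Normalize ratios to median 1 (default `TRUE`).
#' @return `data.frame(chrom, start, end, ratio)` with attribute
#'   `n_dropped`, the number of low-coverage windows excluded.
#' @export
compute_depth_ratios <- function(tumor_windows, normal_windows,
                                 min_normal_depth = 10, normalize = TRUE) {
  same <- nrow(tumor_windows) == nrow(normal_windows) &&
    all(tumor_windows$chrom == normal_windows$chrom) &&
    all(tumor_windows$start == normal_windows$start) &&
    all(tumor_windows$end == normal_windows$end)
  if (!same) {
    if (nrow(tumor_windows) != nrow(normal_windows)) {
      stop("window sets differ in length (", nrow(tumor_windows), " vs ",
           nrow(normal_windows), ")", call. = FALSE)
    }
    bad <- which(tumor_windows$chrom != normal_windows$chrom |
                 tumor_windows$start != normal_windows$start |
                 tumor_windows$end != normal_windows$end)[1]
    stop(sprintf("window sets misaligned; first mismatch at row %d (%s:%d vs %s:%d)",
                 bad, tumor_windows$chrom[bad], tumor_windows$start[bad],
                 normal_windows$chrom[bad], normal_windows$start[bad]),
         call. = FALSE)
  }
  keep <- normal_windows$depth >= min_normal_depth
  out <- data.frame(chrom = tumor_windows$chrom[keep],
                    start = tumor_windows$start[keep],
                    end = tumor_windows$end[keep],
                    ratio = tumor_windows$depth[keep] /
                      normal_windows$depth[keep])
  if (normalize && nrow(out)) out$ratio <- out$ratio / median(out$ratio)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Peaks of the depth-ratio histogram
#'
#' Smooths the ratio distribution with a Gaussian kernel (Silverman's default
#' bandwidth) and extracts local maxima above a relative prominence floor.
#' A sample without tumor cells shows a single peak; heterozygous deletions
#' in tumor cells add a lower (1N) peak. The global mode is assigned to the
#' diploid (2N) ratio `R2n`; the highest peak strictly below it is the
#' haploid (1N) ratio `R1n`, absent when the histogram is unimodal.
#'
#' @param ratios Numeric ratio vector, or the output of
#'   [compute_depth_ratios()]. At least 200 windows are required.
#' @param bandwidth Kernel bandwidth; default `"nrd0"` (Silverman).
#' @param prominence Relative density floor for a peak, as a fraction of the
#'   maximal density (default 0.1).
#' @return An object of class `ratio_peaks`: list with `peaks`
#'   (`data.frame(ratio, weight)`, descending ratio), `R2n`, `R1n` (`NA` if
#'   unimodal) and `n_windows`.
#' @export
find_ratio_peaks <- function(ratios, bandwidth = "nrd0", prominence = 0.1) {
  if (is.data.frame(ratios)) ratios <- ratios$ratio
  if (length(ratios) < 200) {
    stop("need at least 200 ratio windows to locate depth-ratio peaks, got ",
         length(ratios), call. = FALSE)
  }
  d <- density(ratios, bw = bandwidth)
  y <- d$y
  im <- which(diff(sign(diff(y))) == -2) + 1
  im <- im[y[im] >= prominence * max(y)]
  peaks <- data.frame(ratio = d$x[im], weight = y[im])
  peaks <- peaks[order(-peaks$ratio), , drop = FALSE]
  R2n <- peaks$ratio[which.max(peaks$weight)]
  lower <- peaks[peaks$ratio < R2n, , drop = FALSE]
  R1n <- if (nrow(lower)) {
    # largest lower peak; ties broken toward the lower ratio
    cand <- lower[lower$weight == max(lower$weight), , drop = FALSE]
    min(cand$ratio)
  } else NA_real_
  structure(list(peaks = peaks, R2n = R2n, R1n = R1n,
                 n_windows = length(ratios)),
            class = "ratio_peaks")
}

#' Purity from the 2N and 1N depth-ratio peaks
#'
#' `P = 2 (R2n - R1n) / R2n`, clamped to `[0, 1]`. A pure tumor has its
#' haploid peak at half the diploid ratio (`P = 1`); coincident peaks give
#' `P = 0`.
#'
#' @param R2n Diploid-region depth ratio (> 0).
#' @param R1n Haploid-region depth ratio (>= 0, must not exceed `R2n`).
#' @param diagnostics Optional list stored in the result.
#' @return An object of class `purity_estimate` with fields `P`, `method`
#'   (`"peak"`) and `diagnostics`.
#' @examples
#' purity_from_peaks(1.0, 0.5)$P   # pure tumor
#' purity_from_peaks(0.8, 0.64)$P  # 40% purity at arbitrary scale
#' @export
purity_from_peaks <- function(R2n, R1n, diagnostics = list()) {
  .assert(is.finite(R2n) && R2n > 0, "R2n must be positive")
  .assert(is.finite(R1n) && R1n >= 0, "R1n must be non-negative")
  if (R1n > R2n) {
    stop("R1n exceeds R2n: peak-to-ploidy assignment is inverted", call. = FALSE)
  }
  P <- 2 * (R2n - R1n) / R2n
  structure(list(P = min(1, max(0, P)), method = "peak",
                 diagnostics = c(diagnostics, list(R2n = R2n, R1n = R1n))),
            class = "purity_estimate")
}

#' Deletion-anchored purity for low-purity samples
#'
#' When the tumor fraction is low the 1N peak merges into the diploid peak
#' and peak-based estimation fails. Somatic deletion regions then serve as
#' the 1N anchor: candidate regions are somatic deletions not overlapping
#' any blood (germline) deletion; a candidate whose mean ratio exceeds the
#' diploid reference ratio is discarded as a false positive. `R1n` is the
#' mean ratio over windows in the surviving regions.
#'
#' @param ratios Output of [compute_depth_ratios()] (needs coordinates).
#' @param somatic_deletions,blood_deletions `data.frame(chrom, start, end)`
#'   deletion region tables (0-based half-open); `blood_deletions` may be
#'   `NULL`.
#' @param R2n Diploid reference ratio; by default the mean ratio over the
#'   windows outside every candidate deletion region (the 2N-region average,
#'   the same statistic used for the 1N side).
#' @return A `purity_estimate` with `method = "deletion_anchored"`, or
#'   `method = "undetermined"` (with `P = NA`) when no candidate region
#'   survives.
#' @export
purity_deletion_anchored <- function(ratios, somatic_deletions,
                                     blood_deletions = NULL, R2n = NULL) {
  stopifnot(is.data.frame(ratios), is.data.frame(somatic_deletions))
  und <- function(reason) structure(
    list(P = NA_real_, method = "undetermined",
         diagnostics = list(reason = reason)),
    class = "purity_estimate")
  if (!nrow(somatic_deletions)) return(und("no somatic deletion regions"))

  dels <- .as_granges0(somatic_deletions)
  if (!is.null(blood_deletions) && nrow(blood_deletions)) {
    hit <- .fo_first(dels, .as_granges0(blood_deletions))
    somatic_deletions <- somatic_deletions[is.na(hit), , drop = FALSE]
    if (!nrow(somatic_deletions)) return(und("all candidates germline"))
    dels <- .as_granges0(somatic_deletions)
  }

  win <- .as_granges0(ratios)
  if (is.null(R2n)) {
    outside <- is.na(.fo_first(win, dels))
    if (!any(outside)) return(und("no diploid reference windows"))
    R2n <- mean(ratios$ratio[outside])
  }
  # windows fully inside a region carry pure 1N signal; windows straddling a
  # boundary mix in diploid coverage and are used only when nothing better
  region_hits <- function(k) {
    hit <- !is.na(suppressWarnings(GenomicRanges::findOverlaps(
      win, dels[k], type = "within", select = "first")))
    if (!any(hit)) hit <- !is.na(.fo_first(win, dels[k]))
    hit
  }
  region_means <- vapply(seq_len(nrow(somatic_deletions)), function(k) {
    hit <- region_hits(k)
    if (!any(hit)) NA_real_ else mean(ratios$ratio[hit])
  }, numeric(1))
  keep <- !is.na(region_means) & region_means <= R2n
  n_fp <- sum(!is.na(region_means) & region_means > R2n)
  if (!any(keep)) return(und("no surviving deletion region"))

  hit_any <- Reduce(`|`, lapply(which(keep), region_hits))
  R1n <- mean(ratios$ratio[hit_any])
  est <- purity_from_peaks(R2n, min(R1n, R2n))
  est$method <- "deletion_anchored"
  est$diagnostics <- c(est$diagnostics,
                       list(n_regions = sum(keep), n_false_positive = n_fp,
                            n_windows_1n = sum(hit_any)))
  est
}

#' Estimate tumor purity from paired depth tracks
#'
#' End-to-end purity estimation: computes windowed depth ratios, locates the
#' 2N/1N peaks and applies `P = 2 (R2n - R1n) / R2n`. When the 1N peak is
#' not distinct (absent, below the prominence floor, or implying `P < 0.5`,
#' where peak separation becomes unreliable) and somatic deletion regions
#' are supplied, the deletion-anchored fallback is used instead.
#'
#' @inheritParams compute_depth_ratios
#' @inheritParams find_ratio_peaks
#' @param somatic_deletions,blood_deletions Optional deletion region tables
#'   for the fallback mode (see [purity_deletion_anchored()]).
#' @param fallback_below Peak-mode estimates below this trigger the fallback
#'   when deletions are available (default 0.5).
#' @return A `purity_estimate`.
#' @examples
#' cfg <- sim_config(genome_length = 50e6, n_chromosomes = 2, purity = 0.7,
#'                   cnv_events = data.frame(chrom = "chr1", start = 0,
#'                                           end = 10e6, tumor_cn = 1),
#'                   seed = 11)
#' prof <- simulate_genome_profile(cfg)
#' estimate_purity(prof$tumor, prof$normal)
#' @export
estimate_purity <- function(tumor_windows, normal_windows,
                            somatic_deletions = NULL, blood_deletions = NULL,
                            min_normal_depth = 10, bandwidth = "nrd0",
                            prominence = 0.1, fallback_below = 0.5) {
  ratios <- compute_depth_ratios(tumor_windows, normal_windows,
                                 min_normal_depth = min_normal_depth)
  pk <- find_ratio_peaks(ratios$ratio, bandwidth = bandwidth,
                         prominence = prominence)
  diag <- list(peaks = pk$peaks, n_windows = pk$n_windows,
               n_dropped = attr(ratios, "n_dropped"))
  peak_est <- if (!is.na(pk$R1n)) {
    purity_from_peaks(pk$R2n, pk$R1n, diagnostics = diag)
  } else NULL

  distinct <- !is.null(peak_est) && peak_est$P >= fallback_below
  if (distinct || is.null(somatic_deletions)) {
    if (!is.null(peak_est)) return(peak_est)
    return(structure(list(P = NA_real_, method = "undetermined",
                          diagnostics = c(diag, list(reason = "unimodal"))),
                     class = "purity_estimate"))
  }
  purity_deletion_anchored(ratios, somatic_deletions, blood_deletions)
}

#' @export
print.purity_estimate <- function(x, ...) {
  if (is.na(x$P)) {
    cat("Tumor purity: undetermined (", x$diagnostics$reason %||% "", ")\n",
        sep = "")
  } else {
    cat(sprintf("Tumor purity P = %.3f  [method: %s]\n", x$P, x$method))
  }
  invisible(x)
}
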