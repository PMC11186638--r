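#' Parameters for window-based eCLIP enrichment
#'
#' The published analysis scores 10 kb windows: the log2 ratio of eCLIP to
#' size-matched control read counts is z-scored across windows and the
#' one-sided upper-tail normal p-values are FDR-corrected (Benjamini-Hochberg).
#'
#' @param window_size window width in bp (default 10000).
#' @param step distance between window starts; default `window_size` (tiling).
#'   With `step < window_size` windows overlap and reads are counted per
#'   overlap (a read may contribute to several windows).
#' @param pseudocount added to numerator and denominator counts so empty
#'   windows get log2 ratio 0 (default 1).
#' @param depth_normalize scale control counts by total-depth ratio
#'   eclip_total/control_total before the ratio (default TRUE).
#' @param alpha FDR threshold for the `significant` flag (default 0.05).
#' @param tail `"upper"` (enrichment only, default) or `"two_sided"`.
#' @return an `enrichment_params` list.
#' @export
enrichment_params <- function(window_size = 10000L, step = window_size,
                              pseudocount = 1.0, depth_normalize = TRUE,
                              alpha = 0.05, tail = c("upper", "two_sided")) {
  tail <- match.arg(tail)
  if (step <= 0) stop("config error: step must be > 0", call. = FALSE)
  stopifnot(window_size >= 1, pseudocount > 0, alpha > 0, alpha < 1)
  structure(list(window_size = as.integer(window_size), step = as.integer(step),
                 pseudocount = pseudocount, depth_normalize = isTRUE(depth_normalize),
                 alpha = alpha, tail = tail),
            class = "enrichment_params")
}

#' Tile a region into analysis windows
#'
#' Window starts are `region.start, region.start + step, ...` for every start
#' strictly inside the region; the final window is truncated at the region end.
#' With `step <= window_size` every base of the region is covered.
#'
#' @param region a length-1 `GRanges`.
#' @param params an [enrichment_params()] object.
#' @return `GRanges` of windows, unstranded.
#' @export
tile_windows <- function(region, params = enrichment_params()) {
  stopifnot(length(region) == 1L)
  s0 <- interval_start0(region)
  e0 <- interval_end0(region)
  starts <- seq.int(s0, e0 - 1L, by = params$step)
  ends <- pmin(starts + params$window_size, e0)
  genomic_intervals(as.character(GenomicRanges::seqnames(region)), starts, ends, ".")
}

#' Count reads per window
#'
#' For tiling windows (`step >= window_size`) each read is assigned to at most
#' one window by its midpoint `floor((start + end) / 2)` (half-open), so the
#' grid partitions the reads; reads whose midpoint falls outside all windows
#' are ignored. For overlapping windows counting switches to interval overlap
#' and a read may be multi-counted.
#'
#' @param reads `GRanges` of reads.
#' @param windows `GRanges` from [tile_windows()].
#' @param params the [enrichment_params()] used to build the windows.
#' @return integer count vector, one entry per window.
#' @export
count_reads_per_window <- function(reads, windows, params = enrichment_params()) {
  if (length(windows) == 0L) return(integer(0))
  if (length(reads) == 0L) return(integer(length(windows)))
  if (params$step < params$window_size) {
    return(GenomicRanges::countOverlaps(windows, reads, minoverlap = 1L,
                                        ignore.strand = TRUE))
  }
  mid0 <- (interval_start0(reads) + interval_end0(reads)) %/% 2L
  pts <- genomic_intervals(as.character(GenomicRanges::seqnames(reads)),
                           mid0, mid0 + 1L, ".")
  GenomicRanges::countOverlaps(windows, pts, ignore.strand = TRUE)
}

#' Per-window log2 enrichment ratio
#'
#' `ratio_i = log2((n_eclip_i + pc) / (n_control_i * s + pc))` where `s` is the
#' library-depth ratio `eclip_total / control_total` when `depth_normalize`,
#' else 1.
#'
#' @param n_eclip,n_control equal-length count vectors.
#' @param totals length-2 numeric `(eclip_total, control_total)`; defaults to
#'   the sums of the supplied vectors.
#' @param params an [enrichment_params()] object.
#' @return numeric vector of log2 ratios.
#' @export
window_log2_enrichment <- function(n_eclip, n_control,
                                   totals = c(sum(n_eclip), sum(n_control)),
                                   params = enrichment_params()) {
  if (length(n_eclip) != length(n_control)) {
    stop("contract error: count vectors must have equal length", call. = FALSE)
  }
  s <- 1
  if (params$depth_normalize) {
    if (any(totals <= 0)) {
      stop("contract error: depth normalization needs positive totals", call. = FALSE)
    }
    s <- totals[1] / totals[2]
  }
  pc <- params$pseudocount
  log2((n_eclip + pc) / (n_control * s + pc))
}

#' z-scores, normal-tail p-values and BH q-values for log2 ratios
#'
#' z uses the population standard deviation (divisor n), matching the usual
#' definition of a sample z-score. p is the one-sided upper-tail normal
#' probability for `tail = "upper"` (enrichment over control), or
#' `2 * (1 - Phi(|z|))` two-sided. q is the Benjamini-Hochberg step-up over all
#' supplied windows jointly; `significant` means `q <= alpha`.
#'
#' @param log2_ratios numeric vector, length >= 2, non-constant.
#' @param params an [enrichment_params()] object.
#' @return data.frame with columns `log2_ratio`, `zscore`, `pvalue`, `qvalue`,
#'   `significant`.
#' @export
zscore_fdr <- function(log2_ratios, params = enrichment_params()) {
  x <- as.numeric(log2_ratios)
  if (length(x) < 2L) stop("contract error: need at least 2 windows", call. = FALSE)
  mu <- mean(x)
  sdp <- sqrt(mean((x - mu)^2))
  if (sdp == 0) {
    stop("degenerate-data error: zero variance across windows; z-scores undefined",
         call. = FALSE)
  }
  z <- (x - mu) / sdp
  p <- if (params$tail == "upper") stats::pnorm(z, lower.tail = FALSE)
       else 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  p <- pmin(p, 1)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(log2_ratio = x, zscore = z, pvalue = p, qvalue = q,
             significant = q <= params$alpha)
}

#' Full window-enrichment analysis for one RBP over one region
#'
#' Ties together [tile_windows()], [count_reads_per_window()],
#' [window_log2_enrichment()] and [zscore_fdr()]. The z-score/FDR family is all
#' windows of the supplied region for this RBP.
#'
#' @param eclip_reads,control_reads `GRanges` of eCLIP and size-matched control
#'   reads.
#' @param region length-1 `GRanges` to analyze.
#' @param params an [enrichment_params()] object.
#' @param rbp RBP label carried into the output.
#' @return data.frame with window coordinates (0-based half-open), counts and
#'   the statistics of [zscore_fdr()].
#' @export
eclip_window_enrichment <- function(eclip_reads, control_reads, region,
                                    params = enrichment_params(), rbp = "RBP") {
  win <- tile_windows(region, params)
  ne <- count_reads_per_window(eclip_reads, win, params)
  nc <- count_reads_per_window(control_reads, win, params)
  totals <- c(max(length(eclip_reads), 1L), max(length(control_reads), 1L))
  lr <- window_log2_enrichment(ne, nc, totals = totals, params = params)
  st <- zscore_fdr(lr, params)
  cbind(data.frame(
    chrom = as.character(GenomicRanges::seqnames(win)),
    start = interval_start0(win),
    end = interval_end0(win),
    rbp = rbp,
    n_eclip = ne,
    n_control = nc,
    stringsAsFactors = FALSE
  ), st)
}

#' Filter eCLIP peaks on significance and fold enrichment
#'
#' Keeps peaks with p <= `max_p` and fold enrichment >= `min_fold` (both
#' boundaries inclusive: only a p-value *greater than* 0.05 or a fold *less
#' than* two is removed). The p comparison is done in -log10 space with a 1e-9
#' tolerance to avoid floating-point representation artifacts at the boundary.
#'
#' @param peaks `GRanges` from [read_narrowpeak()] or [gen_peak_table()].
#' @param max_p maximum peak p-value kept (default 0.05).
#' @param min_fold minimum fold enrichment kept (default 2).
#' @return filtered `GRanges`, input order preserved.
#' @export
filter_peaks <- function(peaks, max_p = 0.05, min_fold = 2.0) {
  if (length(peaks) == 0L) return(peaks)
  mc <- S4Vectors::mcols(peaks)
  keep <- mc$neg_log10_p >= -log10(max_p) - 1e-9 & mc$fold_enrichment >= min_fold
  peaks[keep]
}

#' Count significant windows per RBP within a region
#'
#' @param results data.frame(s) from [eclip_window_enrichment()] (rows may mix
#'   RBPs evaluated on the same window grid).
#' @param region length-1 `GRanges`; only windows overlapping it are counted.
#' @return data.frame (`rbp`, `n_significant_windows`) sorted descending;
#'   zero rows when nothing is significant.
#' @export
summarize_rbp_windows <- function(results, region) {
  ov <- results$start < interval_end0(region) &
    results$end > interval_start0(region) &
    results$chrom == as.character(GenomicRanges::seqnames(region))
  sig <- results[results$significant & ov, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(data.frame(rbp = character(), n_significant_windows = integer()))
  }
  tab <- sort(table(sig$rbp), decreasing = TRUE)
  data.frame(rbp = names(tab), n_significant_windows = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Count peaks per RBP overlapping a region
#'
#' A peak counts iff it overlaps the region by >= 1 bp (half-open: a peak
#' ending exactly at the region start does not overlap).
#'
#' @param peaks `GRanges` of (typically filtered) peaks.
#' @param region length-1 `GRanges`.
#' @return list with `per_rbp` (data.frame rbp, n_peaks, sorted descending) and
#'   `total`.
#' @export
count_peaks_in_interval <- function(peaks, region) {
  if (length(peaks) == 0L) {
    return(list(per_rbp = data.frame(rbp = character(), n_peaks = integer()),
                total = 0L))
  }
  hit <- IRanges::overlapsAny(peaks, region, minoverlap = 1L,
                              ignore.strand = TRUE)
  sel <- peaks[hit]
  if (length(sel) == 0L) {
    return(list(per_rbp = data.frame(rbp = character(), n_peaks = integer()),
                total = 0L))
  }
  tab <- sort(table(S4Vectors::mcols(sel)$rbp), decreasing = TRUE)
  list(per_rbp = data.frame(rbp = names(tab), n_peaks = as.integer(tab),
                            row.names = NULL, stringsAsFactors = FALSE),
       total = length(sel))
}

#' Locate the densest RBP-peak cluster on a chromosome
#'
#' Clusters peaks with [merge_with_gap()] at `cluster_gap` and returns the
#' cluster containing the most peaks (ties broken leftmost), provided it holds
#' at least `min_peaks` peaks. The returned span is the union of member peaks.
#' This operationalizes the search for peak-dense subdomains such as the ~7 kb
#' RBP domain concentrating nearly all significant eCLIP peaks within a locus.
#'
#' @param peaks `GRanges`, all on one chromosome.
#' @param cluster_gap bp; peaks within this gap cluster together (default 1000).
#' @param min_peaks minimum cluster size reported (default 5).
#' @return list with `domain` (length-1 `GRanges`, or length-0 when no cluster
#'   qualifies) and `n_peaks`.
#' @export
find_peak_dense_domain <- function(peaks, cluster_gap = 1000L, min_peaks = 5L) {
  if (length(peaks) == 0L) {
    return(list(domain = GenomicRanges::GRanges(), n_peaks = 0L))
  }
  flat <- genomic_intervals(as.character(GenomicRanges::seqnames(peaks)),
                            interval_start0(peaks), interval_end0(peaks), ".")
  clusters <- merge_with_gap(flat, cluster_gap)
  counts <- lengths(S4Vectors::mcols(clusters)$revmap)
  best <- which(counts == max(counts))[1]  # reduce() output is sorted -> leftmost
  if (counts[best] < min_peaks) {
    return(list(domain = GenomicRanges::GRanges(), n_peaks = 0L))
  }
  dom <- clusters[best]
  S4Vectors::mcols(dom) <- NULL
  list(domain = dom, n_peaks = as.integer(counts[best]))
}
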