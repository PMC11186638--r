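#' Total fluorescent signal of one chromosome homolog
#'
#' The per-chromosome BrdU (or DAPI) incorporation is quantified as the average
#' pixel intensity multiplied by the area occupied by those pixels.
#'
#' @param area occupied area in pixels (>= 0).
#' @param mean_intensity average pixel intensity in arbitrary units (>= 0).
#' @return signal in AU * pixels.
#' @export
chrom_signal <- function(area, mean_intensity) {
  if (any(area < 0) || any(mean_intensity < 0)) {
    stop("validation error: area and mean_intensity must be >= 0", call. = FALSE)
  }
  area * mean_intensity
}

#' Per-cell homolog B/A signal ratios
#'
#' For every (cell_id, pair_id) the ratio of BrdU incorporation in homolog B
#' over homolog A is computed from [chrom_signal()]. The orientation is taken
#' from the explicit A/B labels in the table; the tool never auto-orients by
#' magnitude, which would bias ratios above 1. With `normalize_dapi`, each
#' homolog's BrdU signal is first divided by its DAPI signal (the ratio is
#' unchanged when the two DAPI signals are equal).
#'
#' Cells whose denominator (homolog A) signal is zero are excluded with a
#' warning rather than emitting NaN.
#'
#' @param table validated measurement data.frame, see [read_measurements()].
#' @param normalize_dapi divide BrdU by DAPI per homolog first (default FALSE).
#' @return data.frame with `cell_id`, `pair_id`, `group`, `ratio`.
#' @export
homolog_ratio <- function(table, normalize_dapi = FALSE) {
  table <- validate_measurements(table)
  if (normalize_dapi &&
      !all(c("dapi_area", "dapi_mean_intensity") %in% names(table))) {
    stop("validation error: DAPI normalization requires dapi_area and dapi_mean_intensity",
         call. = FALSE)
  }
  sig <- chrom_signal(table$brdu_area, table$brdu_mean_intensity)
  if (normalize_dapi) {
    dap <- chrom_signal(table$dapi_area, table$dapi_mean_intensity)
    if (any(dap == 0)) {
      stop("validation error: zero DAPI signal; cannot normalize", call. = FALSE)
    }
    sig <- sig / dap
  }
  a <- table$homolog == "A"
  key <- paste(table$cell_id, table$pair_id, sep = "\r")
  sigA <- sig[a][match(key[!a], key[a])]
  out <- data.frame(cell_id = table$cell_id[!a], pair_id = table$pair_id[!a],
                    group = table$group[!a], ratio = sig[!a] / sigA,
                    stringsAsFactors = FALSE)
  zero <- sigA == 0
  if (any(zero)) {
    warning(sprintf("excluding %d cell(s) with zero homolog-A signal: %s",
                    sum(zero), paste(out$cell_id[zero], collapse = ", ")))
    out <- out[!zero, , drop = FALSE]
  }
  out
}

#' Kruskal-Wallis rank test with tie correction
#'
#' Mid-ranks are assigned over the pooled sample;
#' `H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2`, divided by the tie
#' correction `1 - sum(t^3 - t)/(N^3 - N)`; the p-value is the upper tail of a
#' chi-square with k - 1 degrees of freedom. An exact permutation p-value is
#' available for small groups.
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 observations.
#' @param exact compute the p-value by complete-randomization Monte Carlo
#'   permutation instead of the chi-square approximation (intended for group
#'   sizes < 5; uses `n_perm` label permutations).
#' @param n_perm number of permutations when `exact = TRUE`.
#' @return list with `H` (tie-corrected), `df`, `pvalue`, `n`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))$H  # 3.857143
#' @export
kruskal_wallis <- function(groups, exact = FALSE, n_perm = 10000L) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("contract error: need >= 2 groups", call. = FALSE)
  }
  if (any(lengths(groups) < 2L)) {
    stop("contract error: every group needs >= 2 observations", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  if (length(unique(x)) == 1L) {
    stop("degenerate-data error: all observations identical; tie correction divides by zero",
         call. = FALSE)
  }
  H <- kw_statistic(x, g, N)
  k <- length(groups)
  df <- k - 1L
  if (exact) {
    obs <- H
    hits <- 0L
    for (i in seq_len(n_perm)) {
      hits <- hits + (kw_statistic(x, sample(g), N) >= obs - 1e-12)
    }
    pvalue <- (hits + 1) / (n_perm + 1)
  } else {
    pvalue <- stats::pchisq(H, df = df, lower.tail = FALSE)
  }
  list(H = H, df = df, pvalue = pvalue, n = N)
}

kw_statistic <- function(x, g, N) {
  r <- rank(x)  # mid-ranks for ties
  rbar <- tapply(r, g, mean)
  n_i <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(n_i * (rbar - (N + 1) / 2)^2)
  t <- table(x)
  corr <- 1 - sum(t^3 - t) / (N^3 - N)
  H / corr
}

#' Summarize replication-timing asynchrony per group
#'
#' Computes per-cell homolog ratios, per-group medians and boxplot quantiles
#' (5/25/50/75/95%), and tests each non-reference group against the reference
#' with a two-group [kruskal_wallis()] test. Groups with fewer than 2 valid
#' cells are skipped with a warning; the reference row reports no p-value.
#'
#' @param table measurement data.frame, see [read_measurements()].
#' @param reference_group group label of the control (e.g. "empty_vector").
#' @param normalize_dapi see [homolog_ratio()].
#' @param exact use the permutation p-value for groups with < 5 cells.
#' @return data.frame: `group`, `n_cells`, `median_ratio`, `q05`...`q95`,
#'   `H`, `df`, `p_vs_reference` (NA for the reference row).
#' @export
summarize_asynchrony <- function(table, reference_group,
                                 normalize_dapi = FALSE, exact = FALSE) {
  ratios <- homolog_ratio(table, normalize_dapi = normalize_dapi)
  if (!reference_group %in% ratios$group) {
    stop(sprintf("input error: reference group '%s' not present", reference_group),
         call. = FALSE)
  }
  by_group <- split(ratios$ratio, ratios$group)
  small <- names(by_group)[lengths(by_group) < 2L]
  if (length(small)) {
    warning(sprintf("skipping group(s) with < 2 valid cells: %s",
                    paste(small, collapse = ", ")))
    by_group <- by_group[lengths(by_group) >= 2L]
  }
  ref <- by_group[[reference_group]]
  labels <- c(reference_group, setdiff(names(by_group), reference_group))
  rows <- lapply(labels, function(gl) {
    v <- by_group[[gl]]
    qs <- stats::quantile(v, c(.05, .25, .5, .75, .95), names = FALSE, type = 7)
    if (gl == reference_group) {
      H <- NA_real_; df <- NA_integer_; p <- NA_real_
    } else {
      use_exact <- exact && min(length(v), length(ref)) < 5L
      kw <- kruskal_wallis(list(ref, v), exact = use_exact)
      H <- kw$H; df <- kw$df; p <- kw$pvalue
    }
    data.frame(group = gl, n_cells = length(v), median_ratio = qs[3],
               q05 = qs[1], q25 = qs[2], q50 = qs[3], q75 = qs[4], q95 = qs[5],
               H = H, df = df, p_vs_reference = p,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
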