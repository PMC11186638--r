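test_that("tile_windows covers regions and truncates the last window", {
  p <- enrichment_params()
  r <- genomic_intervals("chr6", 0, 30000)
  expect_length(tile_windows(r, p), 3)
  r2 <- genomic_intervals("chr6", 0, 25000)
  w2 <- tile_windows(r2, p)
  expect_length(w2, 3)
  expect_equal(interval_start0(w2[3]), 20000)
  expect_equal(interval_end0(w2[3]), 25000)
  # overlapping windows: starts enumerate every step inside the region
  w3 <- tile_windows(genomic_intervals("chr6", 0, 20000),
                     enrichment_params(window_size = 10000, step = 5000))
  expect_equal(interval_start0(w3), c(0, 5000, 10000, 15000))
  expect_error(enrichment_params(step = 0), "config error")
})

test_that("count_reads_per_window assigns by midpoint on tiling grids", {
  p <- enrichment_params()
  win <- tile_windows(genomic_intervals("chr6", 0, 20000), p)
  # midpoint of [9990, 10010) is 10000 -> second window
  r <- make_reads("chr6", 9990, 10010)
  expect_equal(count_reads_per_window(r, win, p), c(0L, 1L))
  expect_equal(count_reads_per_window(r[0], win, p), c(0L, 0L))
  many <- make_reads("chr6", seq(100, 5000, 49), seq(100, 5000, 49) + 50)
  expect_equal(count_reads_per_window(many, win, p),
               c(length(many), 0L))
  # overlapping grid -> overlap counting, reads may be multi-counted
  po <- enrichment_params(window_size = 10000, step = 5000)
  wo <- tile_windows(genomic_intervals("chr6", 0, 20000), po)
  expect_equal(count_reads_per_window(r, wo, po), c(1L, 1L, 1L, 0L))
})

test_that("window_log2_enrichment applies pseudocount and depth scaling", {
  p <- enrichment_params(depth_normalize = FALSE)
  expect_equal(window_log2_enrichment(7, 3, params = p), 1.0)
  expect_equal(window_log2_enrichment(0, 0, params = p), 0)
  expect_equal(window_log2_enrichment(3, 3, params = p), 0)
  # depth normalization: control twice as deep -> scaled to neutrality
  pn <- enrichment_params(depth_normalize = TRUE)
  expect_equal(
    window_log2_enrichment(c(10, 20), c(20, 40), totals = c(100, 200), params = pn),
    c(log2(11 / 11), log2(21 / 21)))
  expect_error(window_log2_enrichment(1:3, 1:2), "contract error")
})

test_that("zscore_fdr matches hand-computed z, p and the BH closed form", {
  p <- enrichment_params()
  st <- zscore_fdr(c(2, 4, 6), p)
  # population sd of (2,4,6) is sqrt(8/3)
  expect_equal(st$zscore, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(st$pvalue[3], 1 - pnorm(sqrt(3 / 2)), tolerance = 1e-12)
  expect_equal(round(st$pvalue[3], 4), 0.1103)

  # frozen BH example: sorted p (0.01, 0.02, 0.03, 0.04) -> q all 0.04
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  # location invariance (of the statistics; the ratios themselves shift)
  x <- rnorm(50)
  shifted <- zscore_fdr(x + 17.3, p)
  expect_equal(zscore_fdr(x, p)[c("zscore", "pvalue", "qvalue", "significant")],
               shifted[c("zscore", "pvalue", "qvalue", "significant")],
               tolerance = 1e-9)

  expect_error(zscore_fdr(rep(1, 10), p), "degenerate-data error")
  expect_error(zscore_fdr(3, p), "contract error")

  # two-sided option
  st2 <- zscore_fdr(c(2, 4, 6), enrichment_params(tail = "two_sided"))
  expect_equal(st2$pvalue[1], st2$pvalue[3])
  expect_equal(st2$pvalue[3], 2 * (1 - pnorm(sqrt(3 / 2))), tolerance = 1e-12)
})

test_that("z and q invariants hold on random vectors", {
  set.seed(99)
  p <- enrichment_params()
  for (rep in 1:20) {
    x <- rnorm(sample(10:500, 1), sd = runif(1, 0.1, 5))
    st <- zscore_fdr(x, p)
    expect_equal(mean(st$zscore), 0, tolerance = 1e-12)
    expect_equal(sqrt(mean(st$zscore^2)), 1, tolerance = 1e-12)
    expect_equal(st$qvalue, oracle_bh(st$pvalue), tolerance = 1e-12)
    expect_true(all(st$qvalue > 0 & st$qvalue <= 1))
    # q monotone non-decreasing in p-rank order
    expect_true(all(diff(st$qvalue[order(st$pvalue)]) >= -1e-15))
  }
})

test_that("filter_peaks keeps inclusive boundaries and re-satisfies its predicate", {
  mk <- function(p, fold) {
    gr <- genomic_intervals("chr6", seq(0, by = 1000, length.out = length(p)),
                            seq(0, by = 1000, length.out = length(p)) + 100)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      name = sprintf("RBP_X_%d", seq_along(p)), rbp = "RBP", cell_line = "X",
      score = 0L, fold_enrichment = fold, neg_log10_p = -log10(p),
      neg_log10_q = NA_real_, summit_offset = -1L)
    gr
  }
  peaks <- mk(p = c(0.05, 0.051, 0.01, 0.01), fold = c(2.0, 5, 1.99, 3))
  kept <- filter_peaks(peaks)
  # (p = 0.05, fold = 2.0) kept; (0.051, .) and (., 1.99) removed
  expect_equal(S4Vectors::mcols(kept)$name, c("RBP_X_1", "RBP_X_4"))
  mc <- S4Vectors::mcols(kept)
  expect_true(all(mc$neg_log10_p >= -log10(0.05) - 1e-9 &
                  mc$fold_enrichment >= 2))
  expect_length(filter_peaks(peaks[0]), 0)
})

test_that("summarize_rbp_windows and count_peaks_in_interval restrict to the region", {
  region <- genomic_intervals("chr6", 10000, 40000)
  res <- data.frame(
    chrom = "chr6",
    start = c(0, 10000, 20000, 30000, 40000, 10000, 20000),
    end = c(0, 10000, 20000, 30000, 40000, 10000, 20000) + 10000,
    rbp = c(rep("HNRNPU", 5), "SAFB", "SAFB"),
    significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  tab <- summarize_rbp_windows(res, region)
  expect_equal(tab$rbp, c("HNRNPU", "SAFB"))
  expect_equal(tab$n_significant_windows, c(3L, 1L))
  none <- res; none$significant <- FALSE
  expect_equal(nrow(summarize_rbp_windows(none, region)), 0)

  pk <- gen_peak_table(50, 50, seed = 2)$peaks
  # a peak ending exactly at region.start is not counted (half-open)
  e1 <- interval_end0(pk[1])
  reg <- genomic_intervals("chr6", e1, e1 + 10)
  expect_equal(count_peaks_in_interval(pk[1], reg)$total, 0L)
  all_reg <- genomic_intervals("chr6", 0, max(interval_end0(pk)))
  cnt <- count_peaks_in_interval(pk, all_reg)
  expect_equal(cnt$total, 50L)
  expect_equal(sum(cnt$per_rbp$n_peaks), 50L)
  expect_true(all(diff(cnt$per_rbp$n_peaks) <= 0))
  expect_equal(count_peaks_in_interval(pk[0], all_reg)$total, 0L)
})

test_that("find_peak_dense_domain recovers the densest cluster", {
  # 20 peaks inside a 7 kb stretch plus 5 scattered singletons
  cl_start <- seq(100000, by = 350, length.out = 20)
  lone <- c(5000, 20000, 40000, 60000, 80000)
  pk <- genomic_intervals("chr6", c(cl_start, lone), c(cl_start, lone) + 100)
  got <- find_peak_dense_domain(pk, cluster_gap = 1000, min_peaks = 5)
  expect_equal(got$n_peaks, 20L)
  expect_equal(interval_start0(got$domain), 100000)
  expect_equal(interval_end0(got$domain), cl_start[20] + 100)

  # all singletons far apart -> empty result, not an error
  none <- find_peak_dense_domain(genomic_intervals("chr6", lone, lone + 100),
                                 cluster_gap = 1000, min_peaks = 2)
  expect_length(none$domain, 0)
  expect_equal(none$n_peaks, 0L)

  # equal-count tie -> leftmost cluster
  two <- genomic_intervals("chr6", c(1000, 1100, 50000, 50100),
                           c(1000, 1100, 50000, 50100) + 50)
  tie <- find_peak_dense_domain(two, cluster_gap = 1000, min_peaks = 2)
  expect_equal(interval_start0(tie$domain), 1000)
})

test_that("eclip_window_enrichment flags a strongly bound window", {
  region <- genomic_intervals("chr6", 0, 500000)
  set.seed(4)
  bg_e <- sort(sample.int(499000, 2500))
  bg_c <- sort(sample.int(499000, 2500))
  # pile 400 extra eCLIP reads into window [200000, 210000)
  hot <- 200000 + sort(sample.int(9900, 400))
  eclip <- make_reads("chr6", c(bg_e, hot), c(bg_e, hot) + 100)
  ctrl <- make_reads("chr6", bg_c, bg_c + 100)
  res <- eclip_window_enrichment(eclip, ctrl, region, rbp = "HNRNPU")
  expect_equal(nrow(res), 50)
  hot_row <- which(res$start == 200000)
  expect_true(res$significant[hot_row])
  expect_equal(which.max(res$zscore), hot_row)
})
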