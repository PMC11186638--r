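test_that("filter_reads removes MAPQ <= 20 and duplicates, preserving order", {
  reads <- make_reads("chr6", c(0, 100, 200, 300), c(50, 150, 250, 350),
                      mapq = c(20L, 21L, 60L, 60L),
                      dup = c(FALSE, FALSE, TRUE, FALSE))
  kept <- filter_reads(reads)
  expect_equal(S4Vectors::mcols(kept)$name, c("r2", "r4"))
  # drop_duplicates = FALSE keeps the high-MAPQ duplicate
  kept2 <- filter_reads(reads, merge_params(drop_duplicates = FALSE))
  expect_equal(S4Vectors::mcols(kept2)$name, c("r2", "r3", "r4"))
})

test_that("mask_genic_reads honors overlap and strand mode", {
  reads <- make_reads("chr6", c(100, 100, 900, 2000), c(200, 200, 1100, 2100),
                      strand = c("+", "-", "+", "+"))
  genes <- genomic_intervals("chr6", c(50, 1000), c(500, 1500), c("+", "+"))
  # r1 inside gene same strand -> removed; r2 opposite strand -> kept;
  # r3 spans the gene edge by 100 bp -> removed; r4 outside -> kept
  kept <- mask_genic_reads(reads, genes, mode = "same_strand")
  expect_equal(S4Vectors::mcols(kept)$name, c("r2", "r4"))
  kept_any <- mask_genic_reads(reads, genes, mode = "any_strand")
  expect_equal(S4Vectors::mcols(kept_any)$name, "r4")
  expect_identical(mask_genic_reads(reads, GenomicRanges::GRanges()), reads)
})

test_that("merge_with_gap obeys the half-open gap boundary", {
  # gap = 900 <= 1000 -> one interval (frozen from the brute-force oracle)
  g1 <- merge_with_gap(genomic_intervals("chr6", c(100, 1100), c(200, 1200), "+"),
                       1000)
  expect_length(g1, 1)
  expect_equal(interval_start0(g1), 100)
  expect_equal(interval_end0(g1), 1200)
  # gap = 1001 > 1000 -> two intervals
  g2 <- merge_with_gap(genomic_intervals("chr6", c(100, 1201), c(200, 1300), "+"),
                       1000)
  expect_length(g2, 2)
  # single interval -> itself
  one <- genomic_intervals("chr6", 5, 10, "+")
  expect_equal(interval_end0(merge_with_gap(one, 1e6)), 10)
  # mixed chrom or strand -> contract violation
  expect_error(
    merge_with_gap(genomic_intervals(c("chr1", "chr2"), c(0, 0), c(10, 10), "+"), 5),
    "contract violation")
  expect_error(
    merge_with_gap(genomic_intervals("chr1", c(0, 0), c(10, 10), c("+", "-")), 5),
    "contract violation")
})

test_that("merge_with_gap is idempotent and monotone in max_gap", {
  set.seed(42)
  for (rep in 1:25) {
    iv <- random_intervals()
    gr <- genomic_intervals("chrX", iv$start, iv$end, "+")
    g <- sample.int(5000, 1)
    m1 <- merge_with_gap(gr, g)
    m1b <- merge_with_gap(m1, g)
    expect_equal(interval_start0(m1b), interval_start0(m1))
    expect_equal(interval_end0(m1b), interval_end0(m1))
    # coarsening: every g-contig lies inside exactly one (g + delta)-contig
    m2 <- merge_with_gap(gr, g + sample.int(5000, 1))
    ov <- GenomicRanges::countOverlaps(m1, m2, type = "within")
    expect_true(all(ov == 1))
  }
})

test_that("two-stage calling matches the brute-force fixpoint oracle", {
  set.seed(7)
  for (rep in 1:50) {
    iv <- random_intervals()
    reads <- make_reads("chr6", iv$start, iv$end)
    params <- merge_params(stage1_gap = sample.int(2000, 1),
                           stage2_gap = 2000 + sample.int(6000, 1),
                           min_length = sample(c(0, 5000, 20000), 1))
    got <- call_transcribed_loci(reads, params = params)
    exp <- oracle_two_stage(iv$start, iv$end, params$stage1_gap,
                            params$stage2_gap, params$min_length)
    expect_equal(interval_start0(got), exp$start)
    expect_equal(interval_end0(got), exp$end)
  }
})

test_that("call_transcribed_loci records provenance and enforces invariants", {
  # two stage-1 contigs [0,30000) and [35000,65000) bridged by a 5 kb gap
  reads <- make_reads("chr6", c(seq(0, 29900, 100), seq(35000, 64900, 100)),
                      c(seq(0, 29900, 100), seq(35000, 64900, 100)) + 100)
  loci <- call_transcribed_loci(reads)
  expect_length(loci, 1)
  mc <- S4Vectors::mcols(loci)
  expect_equal(mc$n_reads, length(reads))
  expect_equal(mc$n_stage1_contigs, 2L)
  expect_equal(mc$max_internal_gap, 5000L)
  expect_true(all(GenomicRanges::width(loci) >= 50000))

  # same reads duplicated on the minus strand -> independent identical loci
  minus <- reads
  GenomicRanges::strand(minus) <- "-"
  both <- call_transcribed_loci(c(reads, minus))
  expect_length(both, 2)
  expect_equal(unique(interval_start0(both)), interval_start0(loci))
  expect_setequal(interval_strand_chr(both), c("+", "-"))

  # double boundary from the contract: a 7001 bp gap prevents stage-2 merging
  # and leaves a 42,999 bp fragment below the cutoff
  r2 <- make_reads("chr6", c(seq(0, 29900, 100), seq(37001, 79900, 100)),
                   c(seq(0, 29900, 100), seq(37001, 79900, 100)) + 100)
  expect_length(call_transcribed_loci(r2), 0)
  # shrinking the gap to exactly 7000 merges everything into one 80 kb locus
  r3 <- make_reads("chr6", c(seq(0, 29900, 100), seq(37000, 79900, 100)),
                   c(seq(0, 29900, 100), seq(37000, 79900, 100)) + 100)
  l3 <- call_transcribed_loci(r3)
  expect_length(l3, 1)
  expect_equal(interval_end0(l3), 80000)
  expect_equal(S4Vectors::mcols(l3)$max_internal_gap, 7000L)

  expect_length(call_transcribed_loci(make_reads("chr6", 1, 2)[0]), 0)
})

test_that("planted loci are recovered through the full caller", {
  cfg <- tl_sim_config(chrom_length = 5e5,
                       planted_tls = list(c(50000, 110000, "+"),
                                          c(200000, 330000, "-")),
                       within_tl_gap_max = 900, background_rate = 0.05,
                       seed = 31)
  sim <- gen_read_set(cfg)
  loci <- call_transcribed_loci(sim$reads)
  expect_length(loci, 2)
  expect_equal(interval_start0(loci), interval_start0(sim$truth))
  expect_equal(interval_end0(loci), interval_end0(sim$truth))
  # a 45 kb planted locus is never reported
  sim45 <- gen_read_set(tl_sim_config(chrom_length = 2e5,
                                      planted_tls = list(c(0, 45000, "+")),
                                      background_rate = 0, seed = 8))
  expect_length(call_transcribed_loci(sim45$reads), 0)
})
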