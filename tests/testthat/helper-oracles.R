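# Independent oracles used by the property and acceptance tests. These stay
# deliberately naive (quadratic fixpoint loops, closed-form formulas) and
# share no code with the implementation paths they check.

# brute-force transitive-closure merge: repeatedly union any two intervals
# whose half-open gap max(start_b - end_a, start_a - end_b) is <= max_gap,
# until a fixpoint; returns a sorted data.frame(start, end) in 0-based
# half-open coordinates
oracle_merge <- function(starts, ends, max_gap) {
  iv <- cbind(starts, ends)
  repeat {
    n <- nrow(iv)
    merged <- FALSE
    for (i in seq_len(n - 1)) {
      if (merged) break
      for (j in (i + 1):n) {
        gap <- max(iv[j, 1] - iv[i, 2], iv[i, 1] - iv[j, 2])
        if (gap <= max_gap) {
          iv[i, ] <- c(min(iv[i, 1], iv[j, 1]), max(iv[i, 2], iv[j, 2]))
          iv <- iv[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  data.frame(start = iv[, 1], end = iv[, 2])
}

# two-stage oracle over an explicit read list (0-based half-open)
oracle_two_stage <- function(starts, ends, stage1_gap, stage2_gap, min_length) {
  c1 <- oracle_merge(starts, ends, stage1_gap)
  c2 <- oracle_merge(c1$start, c1$end, stage2_gap)
  c2[c2$end - c2$start >= min_length, , drop = FALSE]
}

# Benjamini-Hochberg step-up closed form: q_(i) = min_{j >= i} p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# random stranded interval sets for the merge-equivalence property
random_intervals <- function(n_max = 50, coord_max = 1e5) {
  n <- sample.int(n_max, 1)
  s <- sort(sample.int(coord_max, n))
  w <- sample.int(2000, n, replace = TRUE)
  list(start = s, end = s + w)
}

make_reads <- function(chrom, start, end, strand = "+", mapq = 60L, dup = FALSE) {
  gr <- genomic_intervals(chrom, start, end, strand)
  n <- length(gr)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = sprintf("r%d", seq_len(n)),
    mapq = as.integer(rep_len(mapq, n)),
    is_duplicate = rep_len(dup, n))
  gr
}

# minimal paired measurement table builder
make_measurements <- function(cell_ids, sigA, sigB, group = "g",
                              pair_id = "chr6", dapiA = 1000, dapiB = 1000) {
  n <- length(cell_ids)
  data.frame(
    cell_id = rep(cell_ids, each = 2),
    pair_id = pair_id,
    homolog = rep(c("A", "B"), n),
    brdu_area = rep(10, 2 * n),
    brdu_mean_intensity = as.vector(rbind(sigA / 10, sigB / 10)),
    dapi_area = rep(10, 2 * n),
    dapi_mean_intensity = as.vector(rbind(dapiA / 10, dapiB / 10)),
    group = group,
    stringsAsFactors = FALSE
  )
}
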