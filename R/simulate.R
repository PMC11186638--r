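#' Configuration for simulated stranded read sets with planted transcribed loci
#'
#' The generator emulates the read structure the locus caller assumes:
#' strand-specific contiguous expression inside planted loci (reads tiled so
#' consecutive starts are at most `read_length + within_tl_gap_max` apart, with
#' both locus boundaries anchored by a read), optional planted larger gaps
#' (emulating unmappable stretches such as full-length LINE elements), and
#' uniform Poisson background elsewhere.
#'
#' Background reads are only placed at least `flank_exclusion` bp away from any
#' planted locus; without that exclusion a stray background read within the
#' stage-2 merge distance of a locus end would fuse into the called locus and
#' make the planted boundaries unscorable (see the methods vignette).
#'
#' @param chrom_length chromosome length in bp.
#' @param planted_tls list of `c(start, end, strand)` triples (0-based
#'   half-open), non-overlapping per strand.
#' @param read_length read length in bp (default 100).
#' @param within_tl_gap_max largest gap between consecutive reads inside a
#'   locus (default 400; must stay below the stage-1 merge gap for the locus to
#'   be recoverable).
#' @param sub_gap_spec optional list of `c(position, gap_bp)` read-free gaps
#'   planted inside loci (stage-2 scale).
#' @param background_rate background reads per kb outside loci (default 0.05).
#' @param gene_mask `GRanges` of gene bodies excluded from background.
#' @param low_mapq_frac fraction of reads given MAPQ <= 20 (default 0).
#' @param dup_frac fraction of reads flagged duplicate (default 0).
#' @param flank_exclusion background-free margin around planted loci (default
#'   7500 bp, i.e. beyond the stage-2 merge reach).
#' @param chrom chromosome name (default "chr6").
#' @param seed integer seed; the generator is a pure function of the config.
#' @return a `tl_sim_config` list.
#' @export
tl_sim_config <- function(chrom_length, planted_tls = list(), read_length = 100L,
                          within_tl_gap_max = 400L, sub_gap_spec = list(),
                          background_rate = 0.05,
                          gene_mask = GenomicRanges::GRanges(),
                          low_mapq_frac = 0, dup_frac = 0,
                          flank_exclusion = 7500L, chrom = "chr6", seed = 1L) {
  stopifnot(chrom_length > 0, read_length > 0, within_tl_gap_max >= 0,
            background_rate >= 0, low_mapq_frac >= 0, low_mapq_frac <= 1,
            dup_frac >= 0, dup_frac <= 1)
  tls <- lapply(planted_tls, function(t) {
    list(start = as.numeric(t[1]), end = as.numeric(t[2]), strand = as.character(t[3]))
  })
  for (t in tls) {
    if (t$end > chrom_length) {
      stop("config error: planted TL exceeds chrom_length", call. = FALSE)
    }
    if (!t$strand %in% c("+", "-")) {
      stop("config error: planted TL strand must be '+' or '-'", call. = FALSE)
    }
  }
  for (s in c("+", "-")) {
    same <- Filter(function(t) t$strand == s, tls)
    if (length(same) > 1L) {
      o <- order(vapply(same, `[[`, 0, "start"))
      st <- vapply(same, `[[`, 0, "start")[o]
      en <- vapply(same, `[[`, 0, "end")[o]
      if (any(st[-1] < en[-length(en)])) {
        stop("config error: planted TLs overlap on one strand", call. = FALSE)
      }
    }
  }
  structure(list(chrom_length = as.numeric(chrom_length), planted_tls = tls,
                 read_length = as.integer(read_length),
                 within_tl_gap_max = as.integer(within_tl_gap_max),
                 sub_gap_spec = sub_gap_spec, background_rate = background_rate,
                 gene_mask = gene_mask, low_mapq_frac = low_mapq_frac,
                 dup_frac = dup_frac, flank_exclusion = as.numeric(flank_exclusion),
                 chrom = chrom, seed = as.integer(seed)),
            class = "tl_sim_config")
}

#' Generate a stranded read set with known transcribed loci
#'
#' @param cfg a [tl_sim_config()].
#' @return list with `reads` (`GRanges` with mcols `name`, `mapq`,
#'   `is_duplicate`) and `truth` (`GRanges` of planted loci).
#' @export
gen_read_set <- function(cfg) {
  stopifnot(inherits(cfg, "tl_sim_config"))
  with_seed(cfg$seed, {
    starts <- numeric(0); ends <- numeric(0); strands <- character(0)
    for (t in cfg$planted_tls) {
      segs <- split_by_subgaps(t$start, t$end, cfg$sub_gap_spec)
      for (sg in segs) {
        s <- tile_segment(sg[1], sg[2], cfg$read_length,
                          cfg$read_length + cfg$within_tl_gap_max)
        starts <- c(starts, s)
        ends <- c(ends, s + cfg$read_length)
        strands <- c(strands, rep(t$strand, length(s)))
      }
    }
    # background: uniform Poisson outside planted loci (padded) and gene mask
    if (cfg$background_rate > 0) {
      excl <- IRanges::IRanges()
      for (t in cfg$planted_tls) {
        excl <- c(excl, IRanges::IRanges(
          max(1, t$start + 1 - cfg$flank_exclusion), t$end + cfg$flank_exclusion))
      }
      if (length(cfg$gene_mask)) {
        excl <- c(excl, IRanges::ranges(cfg$gene_mask))
      }
      open <- IRanges::setdiff(IRanges::IRanges(1, cfg$chrom_length),
                               IRanges::reduce(excl))
      open <- open[IRanges::width(open) > cfg$read_length]
      if (length(open)) {
        w <- IRanges::width(open) - cfg$read_length
        n_bg <- stats::rpois(1, cfg$background_rate * sum(w) / 1000)
        if (n_bg > 0) {
          seg <- sample.int(length(open), n_bg, replace = TRUE, prob = w)
          off <- floor(stats::runif(n_bg) * w[seg])
          bs <- IRanges::start(open)[seg] - 1 + off
          starts <- c(starts, bs)
          ends <- c(ends, bs + cfg$read_length)
          strands <- c(strands, sample(c("+", "-"), n_bg, replace = TRUE))
        }
      }
    }
    n <- length(starts)
    mapq <- rep(60L, n)
    dup <- rep(FALSE, n)
    if (n > 0) {
      low <- stats::runif(n) < cfg$low_mapq_frac
      mapq[low] <- as.integer(floor(stats::runif(sum(low)) * 21))  # 0..20
      dup <- stats::runif(n) < cfg$dup_frac
    }
    reads <- if (n > 0) {
      o <- order(starts, ends)
      gr <- genomic_intervals(cfg$chrom, starts[o], ends[o], strands[o])
      S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        name = sprintf("sim_read_%06d", seq_len(n)),
        mapq = mapq[o], is_duplicate = dup[o])
      gr
    } else empty_reads()
    truth <- if (length(cfg$planted_tls)) {
      genomic_intervals(cfg$chrom,
                        vapply(cfg$planted_tls, `[[`, 0, "start"),
                        vapply(cfg$planted_tls, `[[`, 0, "end"),
                        vapply(cfg$planted_tls, `[[`, "", "strand"))
    } else GenomicRanges::GRanges()
    list(reads = reads, truth = truth)
  })
}

# deterministic tiling of [s, e) anchored at both ends: consecutive starts at
# most `spacing` apart and the last read ends exactly at e
tile_segment <- function(s, e, read_length, spacing) {
  if (e - s < read_length) return(numeric(0))
  st <- seq(s, e - read_length, by = spacing)
  if (st[length(st)] != e - read_length) st <- c(st, e - read_length)
  st
}

split_by_subgaps <- function(s, e, sub_gap_spec) {
  gaps <- Filter(function(g) g[1] >= s && g[1] + g[2] <= e, sub_gap_spec)
  if (!length(gaps)) return(list(c(s, e)))
  gaps <- gaps[order(vapply(gaps, `[`, 0, 1))]
  segs <- list()
  cur <- s
  for (g in gaps) {
    if (g[1] > cur) segs[[length(segs) + 1L]] <- c(cur, g[1])
    cur <- g[1] + g[2]
  }
  if (cur < e) segs[[length(segs) + 1L]] <- c(cur, e)
  segs
}

#' Configuration for paired eCLIP/control window counts
#'
#' @param n_windows number of windows.
#' @param base_rate expected control reads per window (Poisson lambda).
#' @param planted list of `c(window_index, fold)` enriched windows (fold > 1).
#' @param control_depth_factor control library depth multiplier (default 1).
#' @param seed integer seed.
#' @export
enrich_sim_config <- function(n_windows, base_rate = 20, planted = list(),
                              control_depth_factor = 1, seed = 1L) {
  stopifnot(n_windows >= 1, base_rate > 0, control_depth_factor > 0)
  for (p in planted) {
    if (p[1] < 1 || p[1] > n_windows) {
      stop("config error: planted window index out of range", call. = FALSE)
    }
    if (p[2] <= 1) stop("config error: planted fold must be > 1", call. = FALSE)
  }
  structure(list(n_windows = as.integer(n_windows), base_rate = base_rate,
                 planted = planted, control_depth_factor = control_depth_factor,
                 seed = as.integer(seed)),
            class = "enrich_sim_config")
}

#' Generate paired eCLIP/control counts with planted fold enrichment
#'
#' `control_i ~ Poisson(lambda * depth_factor)`;
#' `eclip_i ~ Poisson(lambda * fold_i)` with fold 1 except at planted windows.
#'
#' @param cfg an [enrich_sim_config()].
#' @return list with integer vectors `eclip`, `control` and logical `truth`.
#' @export
gen_paired_counts <- function(cfg) {
  stopifnot(inherits(cfg, "enrich_sim_config"))
  with_seed(cfg$seed, {
    fold <- rep(1, cfg$n_windows)
    truth <- logical(cfg$n_windows)
    for (p in cfg$planted) {
      fold[p[1]] <- p[2]
      truth[p[1]] <- TRUE
    }
    list(eclip = stats::rpois(cfg$n_windows, cfg$base_rate * fold),
         control = stats::rpois(cfg$n_windows,
                                cfg$base_rate * cfg$control_depth_factor),
         truth = truth)
  })
}

#' Generate a narrowPeak table with a known passing subset
#'
#' Exactly `n_pass` peaks satisfy the published filter (p <= 0.05 AND fold
#' enrichment >= 2); every other peak violates at least one criterion. Peak
#' order is shuffled so passing peaks are not positionally clustered.
#'
#' @param n total number of peaks.
#' @param n_pass number of peaks passing the filter, `0 <= n_pass <= n`.
#' @param seed integer seed.
#' @param rbps RBP labels sampled for peak names.
#' @param cell_line cell line token in peak names.
#' @param chrom chromosome.
#' @return list with `peaks` (`GRanges` as from [read_narrowpeak()]) and
#'   `truth` (logical pass flags, parallel to `peaks`).
#' @export
gen_peak_table <- function(n, n_pass, seed = 1L,
                           rbps = c("HNRNPU", "HNRNPA1", "HNRNPC", "HNRNPL",
                                    "HNRNPM", "HNRNPUL1", "KHSRP", "MATR3",
                                    "PTBP1", "SAFB"),
                           cell_line = "K562", chrom = "chr6") {
  stopifnot(n_pass >= 0, n_pass <= n)
  if (n == 0L) return(list(peaks = empty_peaks(), truth = logical(0)))
  with_seed(seed, {
    pass <- sample(rep(c(TRUE, FALSE), c(n_pass, n - n_pass)))
    width <- 150L + as.integer(floor(stats::runif(n) * 150))
    start <- cumsum(2000L + as.integer(floor(stats::runif(n) * 3000)))
    nlp <- numeric(n)
    fold <- numeric(n)
    # passing peaks: p in [1e-6, 0.05] and fold in [2, 8]
    nlp[pass] <- stats::runif(sum(pass), -log10(0.05), 6)
    fold[pass] <- stats::runif(sum(pass), 2, 8)
    # failing peaks violate p, fold, or both
    nf <- sum(!pass)
    mode <- sample.int(3, nf, replace = TRUE)
    bad_p <- stats::runif(nf, 0, -log10(0.07))        # p > 0.07
    good_p <- stats::runif(nf, -log10(0.05), 6)
    bad_f <- stats::runif(nf, 0.5, 1.9)
    good_f <- stats::runif(nf, 2, 8)
    nlp[!pass] <- ifelse(mode == 2, good_p, bad_p)
    fold[!pass] <- ifelse(mode == 1, good_f, bad_f)
    rbp <- sample(rbps, n, replace = TRUE)
    gr <- genomic_intervals(chrom, start, start + width, ".")
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      name = sprintf("%s_%s_peak%04d", rbp, cell_line, seq_len(n)),
      rbp = rbp, cell_line = cell_line,
      score = as.integer(pmin(1000, round(100 * fold))),
      fold_enrichment = fold, neg_log10_p = nlp,
      neg_log10_q = pmax(0, nlp - 0.3), summit_offset = width %/% 2L)
    list(peaks = gr, truth = pass)
  })
}

#' Configuration for simulated homolog measurement tables
#'
#' Emulates per-chromosome BrdU quantification in mitotic cells: homolog A
#' carries `base_signal` and homolog B carries `base_signal * mean_ratio`, each
#' perturbed by multiplicative log-normal noise with coefficient of variation
#' `noise_cv`. A `mean_ratio` of 1 is the synchronous case; delayed homologs in
#' asynchronous cells show ratios around 1.5.
#'
#' @param n_cells number of cells (>= 2).
#' @param mean_ratio expected B/A signal ratio (default 1).
#' @param noise_cv coefficient of variation of the log-normal noise
#'   (default 0.1).
#' @param base_signal homolog-A expected signal in AU*pixels (default 5e5).
#' @param group_label group name stamped on all rows.
#' @param pair_id chromosome pair label (default "chr6").
#' @param seed integer seed.
#' @export
homolog_sim_config <- function(n_cells, mean_ratio = 1.0, noise_cv = 0.1,
                               base_signal = 5e5, group_label = "group",
                               pair_id = "chr6", seed = 1L) {
  stopifnot(n_cells >= 2, mean_ratio > 0, noise_cv >= 0, base_signal > 0)
  structure(list(n_cells = as.integer(n_cells), mean_ratio = mean_ratio,
                 noise_cv = noise_cv, base_signal = base_signal,
                 group_label = group_label, pair_id = pair_id,
                 seed = as.integer(seed)),
            class = "homolog_sim_config")
}

#' Generate a homolog measurement table with a known mean ratio
#'
#' Signals are emitted as (area, mean_intensity) factor pairs whose product is
#' the simulated signal: the area is drawn log-normally around 1000 px and the
#' mean intensity is the signal divided by the area. DAPI columns are constant
#' and identical for the two homologs of a pair, so DAPI normalization is a
#' no-op on these tables.
#'
#' @param cfg a [homolog_sim_config()].
#' @return list with `table` (a measurement data.frame accepted by
#'   [read_measurements()]/[homolog_ratio()]), `truth_mean_ratio` (the planted
#'   ratio) and `ratios` (the realized per-cell ratios).
#' @export
gen_homolog_table <- function(cfg) {
  stopifnot(inherits(cfg, "homolog_sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_cells
    sdlog <- sqrt(log(1 + cfg$noise_cv^2))
    eps <- function(k) stats::rlnorm(k, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    sigA <- cfg$base_signal * eps(n)
    sigB <- cfg$base_signal * cfg$mean_ratio * eps(n)
    areaA <- stats::rlnorm(n, log(1000), 0.2)
    areaB <- stats::rlnorm(n, log(1000), 0.2)
    cell <- sprintf("%s_cell%03d", cfg$group_label, seq_len(n))
    tab <- data.frame(
      cell_id = rep(cell, each = 2),
      pair_id = cfg$pair_id,
      homolog = rep(c("A", "B"), n),
      brdu_area = as.vector(rbind(areaA, areaB)),
      brdu_mean_intensity = as.vector(rbind(sigA / areaA, sigB / areaB)),
      dapi_area = 1000,
      dapi_mean_intensity = 500,
      group = cfg$group_label,
      stringsAsFactors = FALSE
    )
    list(table = tab, truth_mean_ratio = cfg$mean_ratio, ratios = sigB / sigA)
  })
}

# run `code` under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
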