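#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML (or JSON) key-value config, fills defaults, normalizes bp units
#' (`"7kb"` / `"7 kb"` -> 7000; `"1.5mb"` -> 1500000) and rejects unknown keys
#' with a closest-match suggestion. Every parameter defaults to the published
#' value where one exists (stage gaps 1000 and 7000 bp, 50 kb length cutoff,
#' 10 kb windows, peak filter p <= 0.05 and fold >= 2).
#'
#' @param path config file, or `NULL`/empty file for all defaults.
#' @param overrides named list merged over the file contents (CLI flags).
#' @return normalized config list with class `run_config`.
#' @export
validate_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    seed = 1L, out_dir = "asartools_run",
    stages = c("tl", "eclip", "peaks", "homologs"),
    log_level = "info",
    # tl simulation + calling
    chrom = "chr6", chrom_length = 2e6,
    planted_tls = list(c(3e5, 3.9e5, "+"), c(8e5, 9.5e5, "-")),
    read_length = 100L, within_tl_gap_max = 400L, background_rate = 0.05,
    stage1_gap = 1000L, stage2_gap = 7000L, min_length = 50000L,
    min_mapq = 21L,
    # eclip windows
    n_windows = 5000L, base_rate = 20, planted_fold = 4,
    planted_frac = 0.02, window_size = 10000L, step = 10000L,
    pseudocount = 1.0, alpha = 0.05,
    # peak filter / dense domain
    n_peaks = 200L, n_pass = 60L, max_p = 0.05, min_fold = 2.0,
    cluster_gap = 1000L, min_peaks = 5L,
    # homolog asynchrony
    n_cells = 10L, mean_ratio = 1.5, noise_cv = 0.1, base_signal = 5e5,
    reference_group = "control", normalize_dapi = FALSE
  )
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop(sprintf("input error: no such config file: %s", path), call. = FALSE)
    }
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(user)) user <- list()
  }
  # plain key replacement, not modifyList(): values like planted_tls are
  # unnamed lists and must be replaced wholesale, never merged element-wise
  for (k in names(overrides)) user[[k]] <- overrides[[k]]
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    key <- unknown[1]
    d <- utils::adist(key, names(defaults))
    hint <- names(defaults)[which.min(d)]
    stop(sprintf("config error: unknown key '%s'%s", key,
                 if (min(d) <= 3) sprintf(" (did you mean '%s'?)", hint) else ""),
         call. = FALSE)
  }
  cfg <- defaults
  for (k in names(user)) cfg[[k]] <- user[[k]]
  bp_keys <- c("chrom_length", "read_length", "within_tl_gap_max", "stage1_gap",
               "stage2_gap", "min_length", "window_size", "step", "cluster_gap")
  for (k in bp_keys) cfg[[k]] <- parse_bp(cfg[[k]], k)
  for (k in c("seed", "n_windows", "n_peaks", "n_pass", "n_cells", "min_mapq",
              "min_peaks")) {
    v <- suppressWarnings(as.integer(cfg[[k]]))
    if (is.na(v)) stop(sprintf("config error: key '%s' must be an integer", k),
                       call. = FALSE)
    cfg[[k]] <- v
  }
  for (k in c("base_rate", "planted_fold", "planted_frac", "pseudocount",
              "alpha", "max_p", "min_fold", "mean_ratio", "noise_cv",
              "base_signal", "background_rate")) {
    v <- suppressWarnings(as.numeric(cfg[[k]]))
    if (is.na(v)) stop(sprintf("config error: key '%s' must be numeric", k),
                       call. = FALSE)
    cfg[[k]] <- v
  }
  if (cfg$stage2_gap < cfg$stage1_gap) {
    stop("config error: stage2_gap must be >= stage1_gap", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

# "7kb"/"7 kb"/"0.05 mb"/plain numbers -> bp
parse_bp <- function(x, key) {
  if (is.numeric(x)) return(as.numeric(x))
  s <- tolower(trimws(as.character(x)))
  m <- regmatches(s, regexec("^([0-9.]+)\\s*(bp|kb|mb)?$", s))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("config error: cannot parse '%s' for key '%s' as bp", x, key),
         call. = FALSE)
  }
  mult <- c(bp = 1, kb = 1e3, mb = 1e6)[[if (nzchar(m[3])) m[3] else "bp"]]
  as.numeric(m[2]) * mult
}

#' Run the simulate -> call -> score pipeline
#'
#' Executes the requested stages, each seeded from the global seed by a stable
#' per-stage offset (so adding a stage never perturbs another stage's
#' randomness), writes all outputs under `config$out_dir`, and records a
#' manifest (package version, config hash, seed, output checksums). Re-running
#' the same config yields byte-identical outputs; no timestamps are written.
#'
#' @param config a [validate_config()] result (or a path / NULL passed on to
#'   it).
#' @return the manifest, invisibly (data.frame of outputs and md5 checksums).
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outs <- character(0)
  emit <- function(p) outs[[length(outs) + 1L]] <<- p

  if ("tl" %in% cfg$stages) {
    sim <- gen_read_set(tl_sim_config(
      chrom_length = cfg$chrom_length, planted_tls = cfg$planted_tls,
      read_length = cfg$read_length, within_tl_gap_max = cfg$within_tl_gap_max,
      background_rate = cfg$background_rate, chrom = cfg$chrom,
      seed = stage_seed(cfg$seed, "tl")))
    rb <- file.path(cfg$out_dir, "reads.bed")
    write_bed(sim$reads, rb); emit(rb)
    tb <- file.path(cfg$out_dir, "truth_tls.bed")
    write_bed_plain(sim$truth, tb); emit(tb)
    loci <- call_transcribed_loci(sim$reads, params = merge_params(
      stage1_gap = cfg$stage1_gap, stage2_gap = cfg$stage2_gap,
      min_length = cfg$min_length, min_mapq = cfg$min_mapq))
    lb <- file.path(cfg$out_dir, "tls.bed")
    write_tl_bed(loci, lb, command = "asartools run [tl]", seed = cfg$seed)
    emit(lb); emit(paste0(lb, ".provenance.tsv"))
  }

  if ("eclip" %in% cfg$stages) {
    sseed <- stage_seed(cfg$seed, "eclip")
    n_pl <- max(1L, round(cfg$planted_frac * cfg$n_windows))
    idx <- with_seed(sseed, sample.int(cfg$n_windows, n_pl))
    counts <- gen_paired_counts(enrich_sim_config(
      n_windows = cfg$n_windows, base_rate = cfg$base_rate,
      planted = lapply(idx, function(i) c(i, cfg$planted_fold)),
      seed = sseed + 1L))
    lr <- window_log2_enrichment(counts$eclip, counts$control,
                                 params = enrichment_params(alpha = cfg$alpha))
    st <- zscore_fdr(lr, enrichment_params(alpha = cfg$alpha))
    tab <- cbind(data.frame(window = seq_len(cfg$n_windows),
                            n_eclip = counts$eclip, n_control = counts$control,
                            planted = counts$truth), st)
    wp <- file.path(cfg$out_dir, "windows.tsv")
    write_table_prov(tab, wp, command = "asartools run [eclip]", seed = cfg$seed)
    emit(wp)
  }

  if ("peaks" %in% cfg$stages) {
    pk <- gen_peak_table(cfg$n_peaks, cfg$n_pass,
                         seed = stage_seed(cfg$seed, "peaks"))
    pp <- file.path(cfg$out_dir, "peaks.narrowPeak")
    write_narrowpeak(pk$peaks, pp); emit(pp)
    kept <- filter_peaks(pk$peaks, max_p = cfg$max_p, min_fold = cfg$min_fold)
    kp <- file.path(cfg$out_dir, "peaks_kept.narrowPeak")
    write_narrowpeak(kept, kp); emit(kp)
    dom <- find_peak_dense_domain(kept, cluster_gap = cfg$cluster_gap,
                                  min_peaks = cfg$min_peaks)
    dd <- data.frame(
      chrom = if (length(dom$domain)) as.character(GenomicRanges::seqnames(dom$domain)) else character(),
      start = if (length(dom$domain)) interval_start0(dom$domain) else integer(),
      end = if (length(dom$domain)) interval_end0(dom$domain) else integer(),
      n_peaks = if (length(dom$domain)) dom$n_peaks else integer())
    dp <- file.path(cfg$out_dir, "rbp_domain.tsv")
    write_table_prov(dd, dp, command = "asartools run [peaks]", seed = cfg$seed)
    emit(dp)
  }

  if ("homologs" %in% cfg$stages) {
    hseed <- stage_seed(cfg$seed, "homologs")
    ref <- gen_homolog_table(homolog_sim_config(
      n_cells = cfg$n_cells, mean_ratio = 1.0, noise_cv = cfg$noise_cv,
      base_signal = cfg$base_signal, group_label = cfg$reference_group,
      seed = hseed))
    trt <- gen_homolog_table(homolog_sim_config(
      n_cells = cfg$n_cells, mean_ratio = cfg$mean_ratio,
      noise_cv = cfg$noise_cv, base_signal = cfg$base_signal,
      group_label = "asynchronous", seed = hseed + 1L))
    tab <- rbind(ref$table, trt$table)
    mp <- file.path(cfg$out_dir, "measurements.tsv")
    write_tsv_plain(tab, mp); emit(mp)
    summ <- summarize_asynchrony(tab, reference_group = cfg$reference_group,
                                 normalize_dapi = cfg$normalize_dapi)
    sp <- file.path(cfg$out_dir, "asynchrony.tsv")
    write_table_prov(summ, sp, command = "asartools run [homologs]",
                     seed = cfg$seed)
    emit(sp)
  }

  manifest <- data.frame(
    file = basename(outs),
    md5 = unname(tools::md5sum(outs)),
    stringsAsFactors = FALSE
  )
  mf <- file.path(cfg$out_dir, "manifest.tsv")
  con <- file(mf, "wt"); on.exit(close(con))
  writeLines(c(
    sprintf("# asartools_version: %s", as.character(utils::packageVersion("asartools"))),
    sprintf("# seed: %d", cfg$seed),
    sprintf("# config_hash: %s", config_hash(cfg)),
    sprintf("# stages: %s", paste(cfg$stages, collapse = ","))
  ), con)
  utils::write.table(manifest, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}

# plain BED6 for truth intervals (no read metadata)
write_bed_plain <- function(gr, path) {
  df <- data.frame(
    chrom = if (length(gr)) as.character(GenomicRanges::seqnames(gr)) else character(),
    start = if (length(gr)) interval_start0(gr) else integer(),
    end = if (length(gr)) interval_end0(gr) else integer(),
    name = if (length(gr)) sprintf("truth_%d", seq_along(gr)) else character(),
    score = if (length(gr)) rep(0L, length(gr)) else integer(),
    strand = if (length(gr)) interval_strand_chr(gr) else character())
  write_tsv_plain(df, path, col.names = FALSE)
}

# stable per-stage seed: global seed plus a deterministic string hash, kept
# inside 32-bit integer range
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)) * 131L)
  as.integer((as.numeric(seed) + h) %% .Machine$integer.max)
}

config_hash <- function(cfg) {
  flat <- cfg[order(names(cfg))]
  flat$out_dir <- NULL  # location must not change the hash
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(flat)), tmp)
  unname(tools::md5sum(tmp))
}
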