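#' Read aligned-read intervals from a BED6(+1) file
#'
#' Columns: chrom, start, end, name, score (interpreted as MAPQ), strand, and
#' an optional 7th column with the duplicate flag (0/1 or TRUE/FALSE; defaults
#' to FALSE when absent -- plain BED6 cannot carry it). Coordinates are kept
#' 0-based half-open.
#'
#' @param path path to a tab-separated BED file (no header; `#` lines ignored).
#' @return a `GRanges` with metadata columns `name`, `mapq` (integer) and
#'   `is_duplicate` (logical).
#' @export
read_bed <- function(path) {
  lines <- read_data_lines(path)
  if (length(lines$text) == 0L) {
    return(empty_reads())
  }
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    i <- which(nf < 6L)[1]
    stop(sprintf("parse error: %s line %d has %d fields, need >= 6",
                 path, lines$lineno[i], nf[i]), call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:7))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  mapq <- suppressWarnings(as.numeric(m[, 5]))
  if (anyNA(start) || anyNA(end) || anyNA(mapq)) {
    i <- which(is.na(start) | is.na(end) | is.na(mapq))[1]
    stop(sprintf("parse error: %s line %d has non-numeric start/end/score",
                 path, lines$lineno[i]), call. = FALSE)
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("validation error: %s line %d: empty or inverted interval (start=%s end=%s)",
                 path, lines$lineno[bad[1]], m[bad[1], 2], m[bad[1], 3]), call. = FALSE)
  }
  if (any(mapq < 0 | mapq > 255)) {
    i <- which(mapq < 0 | mapq > 255)[1]
    stop(sprintf("validation error: %s line %d: MAPQ %s outside [0, 255]",
                 path, lines$lineno[i], m[i, 5]), call. = FALSE)
  }
  dup <- rep(FALSE, length(fields))
  has7 <- nf >= 7L
  if (any(has7)) {
    raw <- m[, 7]
    dup[has7] <- raw[has7] %in% c("1", "TRUE", "True", "true")
  }
  gr <- genomic_intervals(m[, 1], start, end, m[, 6])
  S4Vectors::mcols(gr)$name <- m[, 4]
  S4Vectors::mcols(gr)$mapq <- as.integer(mapq)
  S4Vectors::mcols(gr)$is_duplicate <- dup
  gr
}

#' Write read intervals as BED6(+dup)
#'
#' Inverse of [read_bed()]. The duplicate column is emitted only when any read
#' is flagged, keeping plain inputs round-trip byte-stable.
#'
#' @param reads `GRanges` as returned by [read_bed()] or [gen_read_set()].
#' @param path output file.
#' @export
write_bed <- function(reads, path) {
  mc <- S4Vectors::mcols(reads)
  name <- if ("name" %in% names(mc)) mc$name else sprintf("r%d", seq_along(reads))
  mapq <- if ("mapq" %in% names(mc)) mc$mapq else 0L
  dup <- if ("is_duplicate" %in% names(mc)) mc$is_duplicate else rep(FALSE, length(reads))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(reads)),
    start = interval_start0(reads),
    end = interval_end0(reads),
    name = name,
    score = mapq,
    strand = interval_strand_chr(reads),
    stringsAsFactors = FALSE
  )
  if (any(dup)) df$dup <- as.integer(dup)
  write_tsv_plain(df, path, col.names = FALSE)
  invisible(path)
}

#' Read ENCODE narrowPeak (BED6+4) eCLIP peaks
#'
#' Maps column 7 (signalValue) to `fold_enrichment`, column 8 (pValue) to
#' `neg_log10_p`, column 9 (qValue) to `neg_log10_q` (`-1` means missing and
#' becomes `NA`), column 10 to `summit_offset`. The peak name is split on
#' `name_delim` and the first token taken as the RBP, the second (when present)
#' as the cell line.
#'
#' @param path narrowPeak file.
#' @param name_delim delimiter inside the peak name, default `"_"`.
#' @return `GRanges` with mcols `name`, `rbp`, `cell_line`, `score`,
#'   `fold_enrichment`, `neg_log10_p`, `neg_log10_q`, `summit_offset`.
#' @export
read_narrowpeak <- function(path, name_delim = "_") {
  lines <- read_data_lines(path)
  if (length(lines$text) == 0L) {
    return(empty_peaks())
  }
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 10L)) {
    i <- which(nf < 10L)[1]
    stop(sprintf("dialect error: %s line %d has %d columns; narrowPeak needs 10",
                 path, lines$lineno[i], nf[i]), call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:10))
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop(sprintf("parse error: %s line %d: non-numeric %s '%s'",
                   path, lines$lineno[i], what, m[i, col]), call. = FALSE)
    }
    v
  }
  fold <- num(7, "signalValue")
  p <- num(8, "pValue")
  q <- num(9, "qValue")
  summit <- num(10, "peak summit")
  if (any(!is.finite(fold)) || any(!is.finite(p))) {
    stop(sprintf("validation error: %s: signalValue/pValue must be finite", path),
         call. = FALSE)
  }
  toks <- strsplit(m[, 4], name_delim, fixed = TRUE)
  gr <- genomic_intervals(m[, 1], num(2, "start"), num(3, "end"), m[, 6])
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = m[, 4],
    rbp = vapply(toks, `[`, "", 1),
    cell_line = vapply(toks, function(t) if (length(t) >= 2) t[2] else NA_character_, ""),
    score = as.integer(num(5, "score")),
    fold_enrichment = fold,
    neg_log10_p = p,
    neg_log10_q = ifelse(q < 0, NA_real_, q),
    summit_offset = as.integer(summit)
  )
  gr
}

#' Write peaks in narrowPeak format
#' @param peaks `GRanges` as returned by [read_narrowpeak()] / [gen_peak_table()].
#' @param path output file.
#' @export
write_narrowpeak <- function(peaks, path) {
  mc <- S4Vectors::mcols(peaks)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = interval_start0(peaks),
    end = interval_end0(peaks),
    name = mc$name,
    score = mc$score,
    strand = interval_strand_chr(peaks),
    signalValue = format_num6(mc$fold_enrichment),
    pValue = format_num6(mc$neg_log10_p),
    qValue = ifelse(is.na(mc$neg_log10_q), "-1", format_num6(mc$neg_log10_q)),
    peak = mc$summit_offset,
    stringsAsFactors = FALSE
  )
  write_tsv_plain(df, path, col.names = FALSE)
  invisible(path)
}

#' Read gene intervals from a GTF (or BED) annotation
#'
#' Only `feature == "gene"` rows of a GTF are used. GTF coordinates are 1-based
#' inclusive and are converted to the internal 0-based half-open convention at
#' this boundary (delegated to [rtracklayer::import], which performs the same
#' conversion into `GRanges`).
#'
#' @param path annotation file; `.gtf`/`.gff` parsed as GTF, otherwise BED.
#' @return `GRanges` of gene bodies.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop(sprintf("input error: no such file: %s", path), call. = FALSE)
  if (grepl("\\.(gtf|gff3?)$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    S4Vectors::mcols(gr) <- NULL
    gr
  } else {
    b <- read_bed(path)
    S4Vectors::mcols(b) <- NULL
    b
  }
}

#' Read a homolog measurement table
#'
#' TSV with header columns `cell_id`, `pair_id`, `homolog` (A|B), `brdu_area`,
#' `brdu_mean_intensity`, optional `dapi_area`, `dapi_mean_intensity`, and
#' `group`. Every (cell_id, pair_id) must contribute exactly one A and one B
#' row; numeric fields must be >= 0.
#'
#' @param path TSV file (`#` comment lines ignored).
#' @return validated `data.frame`.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop(sprintf("input error: no such file: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  validate_measurements(df)
}

#' @rdname read_measurements
#' @param df a data.frame already in memory.
#' @export
validate_measurements <- function(df) {
  req <- c("cell_id", "pair_id", "homolog", "brdu_area", "brdu_mean_intensity", "group")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop(sprintf("validation error: missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (!all(df$homolog %in% c("A", "B"))) {
    bad <- unique(df$homolog[!df$homolog %in% c("A", "B")])
    stop(sprintf("validation error: homolog label(s) %s; must be 'A' or 'B'",
                 paste(shQuote(bad), collapse = ", ")), call. = FALSE)
  }
  numcols <- intersect(c("brdu_area", "brdu_mean_intensity", "dapi_area",
                         "dapi_mean_intensity"), names(df))
  for (cn in numcols) {
    v <- df[[cn]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0)) {
      stop(sprintf("validation error: column %s must be numeric and >= 0", cn),
           call. = FALSE)
    }
  }
  key <- interaction(df$cell_id, df$pair_id, drop = TRUE)
  tab <- table(key, factor(df$homolog, levels = c("A", "B")))
  unpaired <- rownames(tab)[tab[, "A"] != 1L | tab[, "B"] != 1L]
  if (length(unpaired)) {
    stop(sprintf("pairing error: cell/pair without exactly one A and one B row: %s",
                 paste(unpaired, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Write a result table as TSV with a provenance header
#'
#' Output tables carry `#`-prefixed comment lines recording the producing
#' command, seed and package version, sufficient to re-run the producing step.
#' No timestamps are written so identical runs are byte-identical.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param command character scalar describing the producing command.
#' @param seed integer seed used (or NA).
#' @export
write_table_prov <- function(df, path, command = "asartools", seed = NA) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# command: %s", command),
    sprintf("# seed: %s", ifelse(is.na(seed), "none", format(seed))),
    sprintf("# asartools_version: %s", as.character(utils::packageVersion("asartools")))
  ), con)
  utils::write.table(format_df6(df), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# -- internal helpers ---------------------------------------------------------

read_data_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("input error: no such file: %s", path), call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", raw) & nzchar(raw)
  list(text = raw[keep], lineno = which(keep))
}

empty_reads <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = character(), mapq = integer(), is_duplicate = logical())
  gr
}

empty_peaks <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = character(), rbp = character(), cell_line = character(),
    score = integer(), fold_enrichment = numeric(), neg_log10_p = numeric(),
    neg_log10_q = numeric(), summit_offset = integer())
  gr
}

# floats rendered at 6 significant digits so writer/reader round trips are
# byte-stable; integers untouched
format_num6 <- function(x) {
  out <- character(length(x))
  whole <- is.finite(x) & x == round(x)
  out[whole] <- format(x[whole], scientific = FALSE, trim = TRUE)
  out[!whole] <- formatC(x[!whole], digits = 6, format = "g")
  out
}

format_df6 <- function(df) {
  for (cn in names(df)) {
    if (is.double(df[[cn]])) df[[cn]] <- format_num6(df[[cn]])
  }
  df
}

write_tsv_plain <- function(df, path, col.names = TRUE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = col.names)
  invisible(path)
}
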