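#' Parameters for transcribed-locus calling
#'
#' Defaults are the published procedure: stranded reads separated by <= 1000 bp
#' are merged into contigs (stage 1), contigs are merged again allowing gaps of
#' up to 7 kb (stage 2, absorbing unmappable stretches such as full-length LINE
#' elements), and merged segments shorter than 50 kb are discarded. Reads with
#' MAPQ <= 20 or flagged as duplicates are removed first.
#'
#' @param stage1_gap bp; reads separated by at most this merge (default 1000).
#' @param stage2_gap bp; contigs separated by at most this merge (default 7000).
#' @param min_length bp; minimum locus length kept (default 50000, inclusive).
#' @param min_mapq minimum MAPQ kept (default 21, i.e. MAPQ <= 20 removed).
#' @param drop_duplicates drop reads flagged as duplicates (default TRUE).
#' @return a `merge_params` list.
#' @export
merge_params <- function(stage1_gap = 1000L, stage2_gap = 7000L,
                         min_length = 50000L, min_mapq = 21L,
                         drop_duplicates = TRUE) {
  stopifnot(stage1_gap >= 0, stage2_gap >= 0, min_length >= 0, min_mapq >= 0)
  if (stage1_gap > stage2_gap) {
    stop("config error: stage1_gap must be <= stage2_gap", call. = FALSE)
  }
  structure(list(stage1_gap = as.integer(stage1_gap),
                 stage2_gap = as.integer(stage2_gap),
                 min_length = as.integer(min_length),
                 min_mapq = as.integer(min_mapq),
                 drop_duplicates = isTRUE(drop_duplicates)),
            class = "merge_params")
}

#' Remove duplicate and low-quality reads
#'
#' Keeps reads with `mapq >= min_mapq` (so MAPQ 20 is removed and 21 kept at
#' the defaults) and, when `drop_duplicates`, drops flagged duplicates. Input
#' order is preserved.
#'
#' @param reads `GRanges` with mcols `mapq` and `is_duplicate`.
#' @param params a [merge_params()] object.
#' @return filtered `GRanges`.
#' @export
filter_reads <- function(reads, params = merge_params()) {
  mc <- S4Vectors::mcols(reads)
  keep <- mc$mapq >= params$min_mapq
  if (params$drop_duplicates) keep <- keep & !mc$is_duplicate
  reads[keep]
}

#' Remove reads overlapping annotated genes
#'
#' A read is removed if it overlaps any gene body by at least 1 bp under the
#' chosen strand mode. `same_strand` (default) removes only reads on the gene's
#' strand (unstranded genes match both); `any_strand` ignores strand. Reads
#' partially spanning a gene edge are removed, since partial genic overlap
#' would contaminate intergenic contigs.
#'
#' @param reads `GRanges` of reads.
#' @param genes `GRanges` of gene bodies (empty -> identity).
#' @param mode `"same_strand"` or `"any_strand"`.
#' @return filtered `GRanges`.
#' @export
mask_genic_reads <- function(reads, genes, mode = c("same_strand", "any_strand")) {
  mode <- match.arg(mode)
  if (length(genes) == 0L || length(reads) == 0L) return(reads)
  hits <- GenomicRanges::findOverlaps(reads, genes, minoverlap = 1L,
                                      ignore.strand = TRUE)
  if (mode == "same_strand") {
    rs <- as.character(GenomicRanges::strand(reads))[S4Vectors::queryHits(hits)]
    gs <- as.character(GenomicRanges::strand(genes))[S4Vectors::subjectHits(hits)]
    hits <- hits[gs == "*" | rs == "*" | rs == gs]
  }
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop)) reads[-drop] else reads
}

#' Merge intervals chained by gaps at most `max_gap`
#'
#' Two intervals end up in one output interval iff they are connected by a
#' chain of consecutive gaps `start(next) - end(prev) <= max_gap` (half-open
#' coordinates; abutting or overlapping intervals have gap <= 0 and always
#' merge). Output intervals are disjoint, sorted, and each spans the min start
#' to max end of its members.
#'
#' @param intervals `GRanges`, all on one chromosome and one strand.
#' @param max_gap maximum gap in bp that still merges (inclusive).
#' @return merged `GRanges` with an mcol `revmap` (member indices).
#' @export
merge_with_gap <- function(intervals, max_gap) {
  stopifnot(max_gap >= 0)
  if (length(intervals) == 0L) return(intervals)
  if (length(unique(as.character(GenomicRanges::seqnames(intervals)))) > 1L ||
      length(unique(as.character(GenomicRanges::strand(intervals)))) > 1L) {
    stop("contract violation: merge_with_gap requires a single chromosome and strand",
         call. = FALSE)
  }
  # GRanges gap between closed ranges equals the half-open gap start0(b)-end0(a);
  # reduce() keeps ranges apart when the gap is >= min.gapwidth, so merging
  # gaps <= max_gap needs min.gapwidth = max_gap + 1
  GenomicRanges::reduce(intervals, min.gapwidth = max_gap + 1L, with.revmap = TRUE)
}

#' Call transcribed loci (ASAR candidates) from stranded reads
#'
#' Pipeline: [filter_reads()] then [mask_genic_reads()], then independently per
#' (chromosome, strand): stage-1 [merge_with_gap()] of read intervals at
#' `stage1_gap`, stage-2 merge of the resulting contigs at `stage2_gap`, and
#' removal of merged segments shorter than `min_length`. Provenance (read
#' count, stage-1 contig count, largest internal gap bridged) is recorded per
#' locus.
#'
#' @param reads `GRanges` of reads with mcols `mapq`, `is_duplicate`.
#' @param genes `GRanges` of gene bodies for intergenic masking (may be empty).
#' @param params a [merge_params()] object.
#' @param mask_mode strand rule for masking, see [mask_genic_reads()].
#' @return `GRanges` of loci sorted by (chrom, start, strand), with mcols
#'   `name`, `n_reads`, `n_stage1_contigs`, `max_internal_gap`.
#' @examples
#' reads <- gen_read_set(tl_sim_config(
#'   chrom_length = 2e5, planted_tls = list(c(0, 6e4, "+")), seed = 1))$reads
#' call_transcribed_loci(reads, GenomicRanges::GRanges())
#' @export
call_transcribed_loci <- function(reads, genes = GenomicRanges::GRanges(),
                                  params = merge_params(),
                                  mask_mode = "same_strand") {
  reads <- filter_reads(reads, params)
  reads <- mask_genic_reads(reads, genes, mode = mask_mode)
  out <- list()
  if (length(reads)) {
    key <- paste(as.character(GenomicRanges::seqnames(reads)),
                 as.character(GenomicRanges::strand(reads)))
    for (grp in split(seq_along(reads), key)) {
      sub <- reads[grp]
      st <- as.character(GenomicRanges::strand(sub))[1]
      if (st == "*") next  # TLs are strand-specific by definition
      contigs <- merge_with_gap(sub, params$stage1_gap)
      n_reads_contig <- lengths(S4Vectors::mcols(contigs)$revmap)
      loci <- merge_with_gap(contigs, params$stage2_gap)
      rev2 <- S4Vectors::mcols(loci)$revmap
      mg <- vapply(rev2, function(idx) {
        if (length(idx) < 2L) return(0L)
        s0 <- interval_start0(contigs)[idx]
        e0 <- interval_end0(contigs)[idx]
        o <- order(s0)
        max(0L, as.integer(max(s0[o][-1] - e0[o][-length(o)])))
      }, integer(1))
      S4Vectors::mcols(loci) <- S4Vectors::DataFrame(
        n_reads = vapply(rev2, function(idx) sum(n_reads_contig[idx]), integer(1)),
        n_stage1_contigs = lengths(rev2),
        max_internal_gap = mg
      )
      out[[length(out) + 1L]] <- loci[interval_length(loci) >= params$min_length]
    }
  }
  loci <- if (length(out)) do.call(c, unname(out)) else GenomicRanges::GRanges(
    seqnames = character(), ranges = IRanges::IRanges(), strand = character(),
    n_reads = integer(), n_stage1_contigs = integer(), max_internal_gap = integer())
  loci <- GenomicRanges::sort(loci, ignore.strand = TRUE)
  if (length(loci)) {
    S4Vectors::mcols(loci)$name <- sprintf("TL_%03d", seq_along(loci))
    S4Vectors::mcols(loci) <- S4Vectors::mcols(loci)[
      , c("name", "n_reads", "n_stage1_contigs", "max_internal_gap")]
  } else {
    S4Vectors::mcols(loci)$name <- character(0)
  }
  loci
}

#' Write called loci as BED6 plus a provenance sidecar table
#' @param loci output of [call_transcribed_loci()].
#' @param path BED output path; sidecar written to `<path>.provenance.tsv`.
#' @param command,seed provenance fields, see [write_table_prov()].
#' @export
write_tl_bed <- function(loci, path, command = "call-tls", seed = NA) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(loci)),
    start = interval_start0(loci),
    end = interval_end0(loci),
    name = S4Vectors::mcols(loci)$name,
    score = S4Vectors::mcols(loci)$n_reads,
    strand = interval_strand_chr(loci),
    stringsAsFactors = FALSE
  )
  write_tsv_plain(df, path, col.names = FALSE)
  prov <- cbind(df[, c("chrom", "start", "end", "name", "strand")],
                as.data.frame(S4Vectors::mcols(loci)[
                  , c("n_reads", "n_stage1_contigs", "max_internal_gap")]))
  write_table_prov(prov, paste0(path, ".provenance.tsv"), command = command, seed = seed)
  invisible(path)
}
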