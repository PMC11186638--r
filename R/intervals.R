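#' Construct stranded genomic intervals (0-based half-open)
#'
#' All coordinates entering and leaving this package follow the BED convention:
#' 0-based starts, exclusive ends. Internally intervals are held as
#' [GenomicRanges::GRanges] (1-based closed); conversion happens exactly once,
#' here and in the accessors, so no off-by-one drift can accumulate.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start integer vector, 0-based inclusive starts.
#' @param end integer vector, exclusive ends; must satisfy `start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` (unstranded), recycled.
#' @return a `GRanges` with the same length as the inputs.
#' @examples
#' gi <- genomic_intervals("chr6", 100, 200, "+")
#' interval_start0(gi)  # 100
#' interval_end0(gi)    # 200
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  strand <- rep_len(as.character(strand), n)
  if (any(is.na(chrom) | !nzchar(chrom))) {
    stop("validation error: chrom must be non-empty", call. = FALSE)
  }
  if (any(is.na(start) | is.na(end))) {
    stop("validation error: start/end must be numeric", call. = FALSE)
  }
  bad <- which(!(start >= 0 & start < end))
  if (length(bad)) {
    stop(sprintf(
      "validation error: need 0 <= start < end; violated at entry %d (start=%s, end=%s)",
      bad[1], format(start[bad[1]]), format(end[bad[1]])
    ), call. = FALSE)
  }
  if (!all(strand %in% c("+", "-", ".", "*"))) {
    stop("validation error: strand must be one of '+', '-', '.'", call. = FALSE)
  }
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand
  )
}

#' @rdname genomic_intervals
#' @param gr a `GRanges`.
#' @export
interval_start0 <- function(gr) GenomicRanges::start(gr) - 1L

#' @rdname genomic_intervals
#' @export
interval_end0 <- function(gr) GenomicRanges::end(gr)

#' @rdname genomic_intervals
#' @export
interval_strand_chr <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  s[s == "*"] <- "."
  s
}

# interval length in bp under the half-open convention (== GRanges width here)
interval_length <- function(gr) GenomicRanges::width(gr)
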