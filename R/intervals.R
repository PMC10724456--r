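#' Construct a set of genomic intervals
#'
#' Intervals are the package's unit for transcribed regulatory elements (TREs),
#' enhancers, gene spans and SNP positions. Coordinates are 0-based half-open
#' (BED convention) everywhere inside the package; 1-based inputs (GTF, GWAS
#' catalog positions) are converted at the parser boundary.
#'
#' @param chrom character vector of chromosome names (compared by exact string
#'   match; no "chr" normalization is attempted).
#' @param start,end integer vectors; 0 <= start < end.
#' @param strand one of "+", "-", "*" per interval ("*" = unstranded).
#' @param id unique identifiers; when `NULL`, synthesized as
#'   `"chrom:start-end"`.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `strand`, `id`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*", id = NULL) {
  n <- max(length(chrom), length(start), length(end))
  start <- as.numeric(start)
  end <- as.numeric(end)
  strand <- rep_len(as.character(strand), n)
  if (length(chrom) == 1) chrom <- rep_len(chrom, n)
  if (length(start) != n || length(end) != n || length(chrom) != n)
    stop("chrom, start and end must have equal length")
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | start >= end)
  if (length(bad))
    stop(sprintf("invalid interval at position %d: start=%s end=%s (need 0 <= start < end)",
                 bad[1], format(start[bad[1]]), format(end[bad[1]])))
  if (!all(strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  if (is.null(id)) id <- interval_id(chrom, start, end)
  id <- as.character(id)
  if (anyDuplicated(id))
    stop("interval ids must be unique; duplicated: ",
         paste(unique(id[duplicated(id)])[seq_len(min(3, sum(duplicated(id))))], collapse = ", "))
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = strand, id = id, stringsAsFactors = FALSE)
}

interval_id <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             strand = character(), id = character(), stringsAsFactors = FALSE)
}

#' Convert intervals to a GRanges object
#'
#' Internal 0-based half-open coordinates become 1-based closed GRanges
#' coordinates (`start + 1`, `end`).
#' @param x interval data.frame from [genomic_intervals()].
#' @return a [GenomicRanges::GRanges] with the ids as names.
#' @export
as_granges <- function(x) {
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = ifelse(x$strand %in% c("+", "-"), x$strand, "*"))
  names(gr) <- x$id
  gr
}

granges_to_intervals <- function(gr, id = NULL) {
  start0 <- GenomicRanges::start(gr) - 1
  end0 <- GenomicRanges::end(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  if (is.null(id)) id <- interval_id(chrom, start0, end0)
  genomic_intervals(chrom, start0, end0,
                    strand = as.character(GenomicRanges::strand(gr)), id = id)
}

#' Merge interval collections into a non-overlapping sorted union
#'
#' Overlapping and bookended (gap 0) intervals are merged, mirroring the
#' default behaviour of `bedtools merge` on the pooled per-sample TRE calls.
#' Intervals separated by one or more intervening bases are kept apart.
#'
#' @param interval_sets a single interval data.frame or a list of them (one per
#'   sample).
#' @return interval data.frame sorted by (chrom, start), ids synthesized as
#'   `"chrom:start-end"`, unstranded.
#' @export
merge_intervals <- function(interval_sets) {
  if (is.data.frame(interval_sets)) interval_sets <- list(interval_sets)
  pooled <- do.call(rbind, lapply(interval_sets, function(x) {
    x[, c("chrom", "start", "end"), drop = FALSE]
  }))
  if (is.null(pooled) || nrow(pooled) == 0) return(empty_intervals())
  gr <- GenomicRanges::GRanges(pooled$chrom,
                               IRanges::IRanges(pooled$start + 1L, pooled$end))
  merged <- GenomicRanges::reduce(GenomicRanges::sort(gr, ignore.strand = TRUE),
                                  min.gapwidth = 1L)
  out <- granges_to_intervals(merged)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Pairwise gap between an interval and a set of reference intervals
#'
#' gap = 0 when the intervals share at least one base; otherwise the number of
#' bases strictly between the nearest edges. Used by the distal filter and the
#' nearest-gene assignment.
#' @keywords internal
interval_gap <- function(start1, end1, start2, end2) {
  pmax(pmax(start2 - end1, start1 - end2), 0)
}

#' Count overlaps between two region sets
#'
#' Summarizes how many intervals of `setA` share at least one base with any
#' interval of `setB` (the accounting used for ENCODE cCRE uniqueness).
#'
#' @param setA,setB interval data.frames.
#' @return list with `n_A`, `n_A_overlapping_B`, `n_A_unique`.
#' @export
region_overlap_summary <- function(setA, setB) {
  n_A <- nrow(setA)
  if (n_A == 0) return(list(n_A = 0L, n_A_overlapping_B = 0L, n_A_unique = 0L))
  if (nrow(setB) == 0)
    return(list(n_A = n_A, n_A_overlapping_B = 0L, n_A_unique = n_A))
  hits <- GenomicRanges::countOverlaps(as_granges(setA), as_granges(setB),
                                       ignore.strand = TRUE)
  n_over <- sum(hits > 0)
  list(n_A = n_A, n_A_overlapping_B = as.integer(n_over),
       n_A_unique = as.integer(n_A - n_over))
}
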