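#' Remove gene-proximal elements from a merged TRE set
#'
#' An element is retained iff its gap to every gene exceeds `min_gap_bp`
#' (strictly). The gap is 0 for any overlap and otherwise the number of bases
#' strictly between the nearest edges; by default the gene SPAN (5' and 3'
#' ends) defines the edges, with `mode = "tss"` measuring to the TSS alone.
#' Retention is strand-agnostic. Elements on chromosomes that carry no gene
#' are trivially distal and retained.
#'
#' @param enhancers interval data.frame.
#' @param genes gene annotation from [read_gene_annotation()].
#' @param min_gap_bp minimum gap in bp (default 5000; ">5 kb" is strict).
#' @param mode "span" (default) or "tss".
#' @return the retained subset of `enhancers`.
#' @export
filter_distal <- function(enhancers, genes, min_gap_bp = 5000,
                          mode = c("span", "tss")) {
  mode <- match.arg(mode)
  if (nrow(genes) == 0)
    stop("empty gene set: the distal filter would be vacuous")
  if (nrow(enhancers) == 0) return(enhancers)
  if (!any(unique(enhancers$chrom) %in% unique(genes$chrom)))
    warning("enhancers and genes share no chromosome names; ",
            "check naming dialects (e.g. 'chr1' vs '1')")
  if (mode == "span") {
    ggr <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(genes$start + 1L, genes$end))
  } else {
    ggr <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(genes$tss + 1L, genes$tss + 1L))
  }
  egr <- as_granges(enhancers)
  hit <- suppressWarnings(
    GenomicRanges::distanceToNearest(egr, ggr, ignore.strand = TRUE))
  dist <- rep(Inf, nrow(enhancers))
  dist[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  enhancers[dist > min_gap_bp, , drop = FALSE]
}

#' Reads Per Kilobase of feature per Million mapped reads
#'
#' RPKM(f, s) = counts(f, s) / ((length_f / 1e3) * (library_size_s / 1e6)).
#'
#' @param counts feature x sample count matrix.
#' @param lengths per-feature lengths in bp, named by feature id or in row
#'   order.
#' @param library_sizes per-sample total mapped reads, named by sample id or
#'   in column order.
#' @return matrix of the same shape, units "RPKM".
#' @export
compute_rpkm <- function(counts, lengths, library_sizes) {
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  if (!is.null(names(library_sizes))) library_sizes <- library_sizes[colnames(counts)]
  if (any(is.na(lengths)) || length(lengths) != nrow(counts))
    stop("lengths must cover every feature")
  if (any(is.na(library_sizes)) || length(library_sizes) != ncol(counts))
    stop("library_sizes must cover every sample")
  if (any(lengths <= 0)) stop("feature lengths must be positive")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  rpkm <- counts / (lengths / 1e3)
  rpkm <- sweep(rpkm, 2, library_sizes / 1e6, "/")
  attr(rpkm, "units") <- "RPKM"
  rpkm
}

#' Build the expressed enhancer universe
#'
#' Applies the expression filter to a merged, distal-filtered TRE set: an
#' enhancer is retained iff its RPKM is >= `rpkm_threshold` (inclusive) in at
#' least `min_samples` samples. Thresholds and input provenance are recorded
#' on the returned object.
#'
#' @param enhancers interval data.frame (merged, distal-filtered).
#' @param rpkm enhancer x sample RPKM matrix; rows must cover all enhancers.
#' @param rpkm_threshold inclusive expression cutoff (default 2).
#' @param min_samples minimum number of samples at or above the cutoff
#'   (default 1).
#' @param min_gap_bp recorded provenance of the upstream distal filter.
#' @return an object of class `enhancer_universe`: list with `enhancers`,
#'   `rpkm` (subset to retained enhancers) and `provenance`.
#' @export
build_universe <- function(enhancers, rpkm, rpkm_threshold = 2,
                           min_samples = 1, min_gap_bp = 5000) {
  if (rpkm_threshold <= 0) stop("rpkm_threshold must be strictly positive")
  if (min_samples < 1) stop("min_samples must be >= 1")
  missing_rows <- setdiff(enhancers$id, rownames(rpkm))
  if (length(missing_rows))
    stop("RPKM matrix lacks rows for enhancers: ",
         paste(utils::head(missing_rows, 3), collapse = ", "))
  rpkm <- rpkm[enhancers$id, , drop = FALSE]
  keep <- rowSums(rpkm >= rpkm_threshold) >= min_samples
  if (!any(keep)) warning("no enhancer passes the RPKM filter; empty universe")
  out <- list(
    enhancers = enhancers[keep, , drop = FALSE],
    rpkm = rpkm[keep, , drop = FALSE],
    provenance = list(rpkm_threshold = rpkm_threshold,
                      min_samples = min_samples,
                      min_gap_bp = min_gap_bp,
                      n_input_enhancers = nrow(enhancers),
                      n_samples = ncol(rpkm)))
  class(out) <- "enhancer_universe"
  out
}

#' @export
print.enhancer_universe <- function(x, ...) {
  cat("Expressed distal enhancer universe\n")
  cat(sprintf("  %d enhancers (from %d merged TREs) x %d samples\n",
              nrow(x$enhancers), x$provenance$n_input_enhancers,
              x$provenance$n_samples))
  cat(sprintf("  filters: RPKM >= %g in >= %d sample(s); > %d bp from genes\n",
              x$provenance$rpkm_threshold, x$provenance$min_samples,
              x$provenance$min_gap_bp))
  invisible(x)
}

#' Run the full universe construction from per-sample TRE calls
#'
#' merge -> distal filter -> RPKM -> expression filter, the construction of
#' the expressed distal TRE universe.
#'
#' @param tre_sets list of per-sample interval data.frames.
#' @param genes gene annotation.
#' @param counts counts over the merged TREs (rows may be a superset).
#' @param lengths,library_sizes see [compute_rpkm()]; when `lengths` is NULL
#'   the merged interval widths are used.
#' @param rpkm_threshold,min_samples,min_gap_bp filter settings.
#' @return `enhancer_universe`.
#' @export
enhancer_universe <- function(tre_sets, genes, counts, lengths = NULL,
                              library_sizes, rpkm_threshold = 2,
                              min_samples = 1, min_gap_bp = 5000) {
  merged <- merge_intervals(tre_sets)
  distal <- filter_distal(merged, genes, min_gap_bp = min_gap_bp)
  missing_rows <- setdiff(distal$id, rownames(counts))
  if (length(missing_rows))
    stop("count matrix lacks rows for merged TREs: ",
         paste(utils::head(missing_rows, 3), collapse = ", "))
  counts <- counts[distal$id, , drop = FALSE]
  if (is.null(lengths)) lengths <- stats::setNames(distal$end - distal$start, distal$id)
  rpkm <- compute_rpkm(counts, lengths, library_sizes)
  build_universe(distal, rpkm, rpkm_threshold = rpkm_threshold,
                 min_samples = min_samples, min_gap_bp = min_gap_bp)
}
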