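#' Assign SNPs to containing regions
#'
#' A SNP at 0-based position `pos` is contained in a region iff
#' `start <= pos < end`. Each SNP receives the id of its containing region or
#' NA.
#'
#' @param catalog SNP catalog (see [read_snp_catalog()]).
#' @param regions interval data.frame (must be non-overlapping for unique
#'   assignment; overlapping regions assign the first sorted hit).
#' @return data.frame: catalog columns plus `region_id`, `contained`.
#' @export
annotate_snps_in_regions <- function(catalog, regions) {
  out <- catalog
  out$region_id <- rep(NA_character_, nrow(catalog))
  out$contained <- rep(FALSE, nrow(catalog))
  if (nrow(catalog) == 0 || nrow(regions) == 0) return(out)
  sgr <- GenomicRanges::GRanges(catalog$chrom,
                                IRanges::IRanges(catalog$pos + 1L,
                                                 catalog$pos + 1L))
  rgr <- as_granges(regions)
  hits <- GenomicRanges::findOverlaps(sgr, rgr, ignore.strand = TRUE,
                                      select = "first")
  found <- !is.na(hits)
  out$region_id[found] <- regions$id[hits[found]]
  out$contained <- found
  out
}

#' SNP density in region sets versus the genome background
#'
#' Densities are SNPs per million base pairs. The genome-wide baseline is the
#' full catalog over the total genome size; each region set's enrichment
#' ratio is its density over that baseline.
#'
#' @param catalog SNP catalog.
#' @param region_sets a single interval data.frame or a named list of them;
#'   each set must be internally non-overlapping (merge first).
#' @param genome_size_bp total genome size in bp.
#' @return object of class `snp_density`: data.frame with one row per region
#'   set plus a `genome` baseline row; columns `region_set`, `n_snps`,
#'   `total_bp`, `density_per_mb`, `enrichment_ratio`.
#' @export
snp_density <- function(catalog, region_sets, genome_size_bp) {
  if (genome_size_bp <= 0) stop("genome_size_bp must be positive")
  if (is.data.frame(region_sets)) region_sets <- list(regions = region_sets)
  if (is.null(names(region_sets))) stop("region_sets must be named")
  baseline <- nrow(catalog) / (genome_size_bp / 1e6)
  rows <- lapply(names(region_sets), function(nm) {
    reg <- region_sets[[nm]]
    gr <- as_granges(reg)
    red <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
    if (sum(GenomicRanges::width(red)) != sum(reg$end - reg$start))
      stop("region set '", nm, "' contains overlapping intervals; merge first")
    ann <- annotate_snps_in_regions(catalog, reg)
    total_bp <- sum(reg$end - reg$start)
    dens <- if (total_bp > 0) sum(ann$contained) / (total_bp / 1e6) else 0
    data.frame(region_set = nm, n_snps = sum(ann$contained),
               total_bp = total_bp, density_per_mb = dens,
               enrichment_ratio = if (baseline > 0) dens / baseline else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(region_set = "genome", n_snps = nrow(catalog),
                               total_bp = genome_size_bp,
                               density_per_mb = baseline,
                               enrichment_ratio = 1,
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("snp_density", "data.frame")
  out
}
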