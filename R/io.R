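#' Read genomic intervals from a BED file
#'
#' Accepts BED3+ (tab-separated, >= 3 columns). Coordinates are taken verbatim
#' as 0-based half-open. Column 4, when present, supplies the interval id;
#' otherwise ids are synthesized as `"chrom:start-end"`. Column 6 supplies the
#' strand when present.
#'
#' @param path file path.
#' @return interval data.frame (see [genomic_intervals()]).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop(sprintf("%s line %d: BED requires >= 3 tab-separated columns",
                 path, which(nf < 3)[1]))
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad))
    stop(sprintf("%s line %d: non-integer coordinates", path, bad[1]))
  bad <- which(start < 0 | start >= end)
  if (length(bad))
    stop(sprintf("%s line %d: invalid interval (start=%d >= end=%d or negative)",
                 path, bad[1], as.integer(start[bad[1]]), as.integer(end[bad[1]])))
  id <- ifelse(nf >= 4, vapply(fields, function(f) if (length(f) >= 4) f[[4]] else "",
                               character(1)), NA_character_)
  id[is.na(id) | id == "" | id == "."] <-
    interval_id(chrom, start, end)[is.na(id) | id == "" | id == "."]
  strand <- vapply(fields, function(f) if (length(f) >= 6) f[[6]] else "*",
                   character(1))
  strand[!strand %in% c("+", "-")] <- "*"
  genomic_intervals(chrom, start, end, strand, id)
}

#' Write intervals as BED
#'
#' Emits BED6 with score 0; deterministic row order as given.
#' @param x interval data.frame.
#' @param path output file.
#' @export
write_bed <- function(x, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", x$chrom, as.integer(x$start),
                   as.integer(x$end), x$id,
                   ifelse(x$strand %in% c("+", "-"), x$strand, "."))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation (BED6 or minimal GTF)
#'
#' BED6 files (detected by extension `.bed` or forced via `format`) must carry
#' a strand for every record. Minimal GTF input uses fields 1 (chrom), 4/5
#' (1-based closed span, converted to 0-based half-open), 7 (strand) and the
#' `gene_id` attribute in field 9; the span of a gene is the union of its
#' feature lines.
#'
#' The transcription start site (TSS) is `start` for + genes and `end - 1` for
#' - genes.
#'
#' @param path file path.
#' @param format "auto", "bed" or "gtf".
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `tss`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff)$", path, ignore.case = TRUE)) "gtf" else "bed"
  }
  if (format == "bed") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) return(empty_genes())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 6))
      stop(sprintf("%s line %d: gene BED requires 6 columns (strand mandatory)",
                   path, which(lengths(fields) < 6)[1]))
    chrom <- vapply(fields, `[[`, character(1), 1)
    start <- as.numeric(vapply(fields, `[[`, character(1), 2))
    end <- as.numeric(vapply(fields, `[[`, character(1), 3))
    gene_id <- vapply(fields, `[[`, character(1), 4)
    strand <- vapply(fields, `[[`, character(1), 6)
    if (any(!strand %in% c("+", "-")))
      stop(sprintf("%s line %d: missing or invalid strand",
                   path, which(!strand %in% c("+", "-"))[1]))
    dup <- duplicated(gene_id)
    if (any(dup)) {
      # duplicates allowed only when coordinates agree exactly
      key <- paste(chrom, start, end, strand)
      first <- match(gene_id, gene_id)
      if (any(key[dup] != key[first[dup]]))
        stop("duplicate gene id with conflicting coordinates: ",
             gene_id[dup][key[dup] != key[first[dup]]][1])
      keep <- !dup
      chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
      gene_id <- gene_id[keep]; strand <- strand[keep]
    }
    return(make_genes(chrom, start, end, strand, gene_id))
  }
  # minimal GTF
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_genes())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 9))
    stop(sprintf("%s line %d: GTF requires 9 tab-separated fields",
                 path, which(lengths(fields) < 9)[1]))
  chrom <- vapply(fields, `[[`, character(1), 1)
  start1 <- as.numeric(vapply(fields, `[[`, character(1), 4))
  end1 <- as.numeric(vapply(fields, `[[`, character(1), 5))
  strand <- vapply(fields, `[[`, character(1), 7)
  attrs <- vapply(fields, `[[`, character(1), 9)
  if (any(!strand %in% c("+", "-")))
    stop(sprintf("%s line %d: missing or invalid strand",
                 path, which(!strand %in% c("+", "-"))[1]))
  m <- regmatches(attrs, regexpr('gene_id "[^"]+"', attrs))
  has <- grepl('gene_id "', attrs, fixed = TRUE)
  if (!all(has))
    stop(sprintf("%s line %d: no gene_id attribute", path, which(!has)[1]))
  gene_id <- sub('gene_id "([^"]+)"', "\\1", m)
  # union of feature lines per gene; GTF 1-based closed -> 0-based half-open
  start0 <- start1 - 1
  end0 <- end1
  agg_start <- tapply(start0, gene_id, min)
  agg_end <- tapply(end0, gene_id, max)
  gid <- names(agg_start)
  first <- match(gid, gene_id)
  chr <- chrom[first]
  str <- strand[first]
  consistent <- tapply(seq_along(gene_id), gene_id, function(i) {
    length(unique(chrom[i])) == 1 && length(unique(strand[i])) == 1
  })
  if (!all(consistent))
    stop("gene id on multiple chromosomes or strands: ",
         gid[!consistent][1])
  ord <- order(chr, as.numeric(agg_start), gid)
  make_genes(chr[ord], as.numeric(agg_start)[ord], as.numeric(agg_end)[ord],
             str[ord], gid[ord])
}

make_genes <- function(chrom, start, end, strand, gene_id) {
  iv <- genomic_intervals(chrom, start, end, strand, gene_id)
  tss <- ifelse(strand == "+", start, end - 1)
  data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
             strand = iv$strand, gene_id = iv$id, tss = tss,
             stringsAsFactors = FALSE)
}

empty_genes <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             strand = character(), gene_id = character(), tss = numeric(),
             stringsAsFactors = FALSE)
}

#' Read a signal matrix (features x samples TSV)
#'
#' Header row holds sample ids; first column holds feature ids. Entries must
#' be nonnegative numbers with no missing values.
#'
#' @param path file path.
#' @param units label attached to the matrix ("counts", "RPKM", "normalized").
#' @return numeric matrix with feature rownames and sample colnames, attribute
#'   `units`.
#' @export
read_matrix <- function(path, units = "counts") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop(path, ": matrix needs a feature id column and >= 1 sample")
  feat <- df[[1]]
  if (anyDuplicated(feat))
    stop(path, ": duplicated feature id: ", feat[duplicated(feat)][1])
  samp <- colnames(df)[-1]
  if (anyDuplicated(samp))
    stop(path, ": duplicated sample id: ", samp[duplicated(samp)][1])
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("%s: non-numeric or missing cell at feature '%s', sample '%s'",
                 path, feat[bad[1, 1]], samp[bad[1, 2]]))
  bad <- which(num < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("%s: negative value at feature '%s', sample '%s'",
                 path, feat[bad[1, 1]], samp[bad[1, 2]]))
  dimnames(num) <- list(feat, samp)
  attr(num, "units") <- units
  num
}

#' Write a signal matrix as TSV
#'
#' Values are rendered with 6 significant digits; output is byte-deterministic
#' for a given matrix.
#' @param m numeric matrix with dimnames.
#' @param path output file.
#' @param id_col header for the feature id column.
#' @export
write_matrix <- function(m, path, id_col = "feature_id") {
  header <- paste(c(id_col, colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

# fixed 6-significant-digit rendering; integers stay integral
fmt_num <- function(x) {
  out <- formatC(signif(x, 6), format = "g", digits = 6)
  trimws(out)
}

#' Read the sample sheet
#'
#' Required columns: `sample_id`, `gestational_age_weeks`, `trimester`, `sex`,
#' `assays` (comma-separated subset of rnaseq, proseq, k27ac, k4me1).
#' Trimester labels are validated against gestational age (I: <14 weeks,
#' II: 14-27, III: >= 28).
#'
#' @param path file path.
#' @return data.frame, one row per sample, in file order.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "gestational_age_weeks", "trimester", "sex", "assays")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop(path, ": sample sheet missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop(path, ": duplicated sample_id")
  age <- as.numeric(df$gestational_age_weeks)
  if (any(is.na(age) | age <= 0)) stop(path, ": gestational_age_weeks must be positive")
  expected <- trimester_of(age)
  if (any(df$trimester != expected))
    stop(path, ": trimester label inconsistent with gestational age for sample ",
         df$sample_id[df$trimester != expected][1])
  df$gestational_age_weeks <- age
  df
}

#' Trimester label from gestational age in weeks
#' @param age_weeks numeric vector of gestational ages.
#' @return character vector of "I", "II", "III".
#' @export
trimester_of <- function(age_weeks) {
  ifelse(age_weeks < 14, "I", ifelse(age_weeks < 28, "II", "III"))
}

#' Read a GWAS-catalog-style SNP table
#'
#' Expects columns `snp_id`, `chrom`, `pos_1based`, `trait`. Positions are
#' converted to the package's 0-based convention on load.
#' @param path file path.
#' @return data.frame with columns `snp_id`, `chrom`, `pos` (0-based), `trait`.
#' @export
read_snp_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("snp_id", "chrom", "pos_1based", "trait")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop(path, ": SNP catalog missing columns: ",
                         paste(miss, collapse = ", "))
  pos1 <- as.numeric(df$pos_1based)
  if (any(is.na(pos1) | pos1 < 1)) stop(path, ": pos_1based must be >= 1")
  if (anyDuplicated(df$snp_id)) stop(path, ": duplicated snp_id")
  data.frame(snp_id = as.character(df$snp_id), chrom = as.character(df$chrom),
             pos = pos1 - 1, trait = as.character(df$trait),
             stringsAsFactors = FALSE)
}

#' Write a result table as TSV with fixed numeric precision
#'
#' Numeric columns are rendered with 6 significant digits; row and column
#' order are preserved as given, making repeat runs byte-identical.
#' @param df data.frame.
#' @param path output file.
#' @export
write_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
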