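#' Assign each enhancer to its nearest gene
#'
#' The link target minimizes the gap between the enhancer interval and the
#' gene TSS (default) or the gene span edge (`mode = "span"`). Ties go to the
#' lexicographically smallest gene id; enhancers on chromosomes without genes
#' are left unlinked and flagged. Distances are signed: positive when the
#' linked point lies downstream (to the right) of the enhancer, negative when
#' upstream, 0 on overlap.
#'
#' @param enhancers interval data.frame.
#' @param genes gene annotation.
#' @param mode "tss" (default) or "span".
#' @return data.frame per enhancer: `enhancer_id`, `gene_id` (NA when
#'   unlinked), `distance` (signed bp), `linked`, `link_rule`.
#' @export
nearest_gene <- function(enhancers, genes, mode = c("tss", "span")) {
  mode <- match.arg(mode)
  if (nrow(genes) == 0) stop("gene set is empty")
  if (mode == "tss") {
    gstart <- genes$tss
    gend <- genes$tss + 1
  } else {
    gstart <- genes$start
    gend <- genes$end
  }
  out <- data.frame(enhancer_id = enhancers$id, gene_id = NA_character_,
                    distance = NA_real_, linked = FALSE,
                    link_rule = "nearest_gene", stringsAsFactors = FALSE,
                    row.names = NULL)
  for (i in seq_len(nrow(enhancers))) {
    on_chr <- which(genes$chrom == enhancers$chrom[i])
    if (length(on_chr) == 0) next
    gaps <- interval_gap(enhancers$start[i], enhancers$end[i],
                         gstart[on_chr], gend[on_chr])
    best <- on_chr[gaps == min(gaps)]
    j <- best[order(genes$gene_id[best])][1]
    gp <- min(gaps)
    sgn <- if (gp == 0) 0 else if (gstart[j] >= enhancers$end[i]) 1 else -1
    out$gene_id[i] <- genes$gene_id[j]
    out$distance[i] <- sgn * gp
    out$linked[i] <- TRUE
  }
  out
}

#' Enhancers-per-gene tally
#'
#' Counts linked enhancers per gene and rank-orders genes by descending
#' count (ties by gene id), the rank-order view of enhancer-dense loci.
#'
#' @param links output of [nearest_gene()].
#' @return data.frame `gene_id`, `n_enhancers`, `rank`.
#' @export
enhancers_per_gene <- function(links) {
  linked <- links[links$linked, , drop = FALSE]
  if (nrow(linked) == 0)
    return(data.frame(gene_id = character(), n_enhancers = integer(),
                      rank = integer(), stringsAsFactors = FALSE))
  tab <- table(linked$gene_id)
  df <- data.frame(gene_id = names(tab), n_enhancers = as.integer(tab),
                   stringsAsFactors = FALSE, row.names = NULL)
  df <- df[order(-df$n_enhancers, df$gene_id), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Hypergeometric gene-list overlap test
#'
#' Upper-tail probability of observing at least the realized overlap between
#' two lists drawn from a common finite universe: p = P(X >= k) with X ~
#' Hypergeometric(N = universe_size, K = |A|, n = |B|). Enrichment only.
#'
#' @param setA,setB character vectors (deduplicated internally).
#' @param universe_size size N of the universe both lists are drawn from.
#' @return list with `overlap`, `expected`, `p_value`, `n_A`, `n_B`,
#'   `universe_size`.
#' @export
hypergeometric_overlap <- function(setA, setB, universe_size) {
  setA <- unique(setA); setB <- unique(setB)
  if (length(setA) > universe_size || length(setB) > universe_size)
    stop("set larger than the universe")
  k <- length(intersect(setA, setB))
  nA <- length(setA); nB <- length(setB)
  if (k > 0 && k > min(nA, nB)) stop("impossible overlap")  # unreachable guard
  p <- stats::phyper(k - 1, nA, universe_size - nA, nB, lower.tail = FALSE)
  list(overlap = k, expected = nA * nB / universe_size, p_value = p,
       n_A = nA, n_B = nB, universe_size = universe_size)
}

#' Enhancer-gene expression correlation
#'
#' Pearson correlation across shared samples between each enhancer's
#' transcription (RPKM) and its paired gene's expression, with a two-sided
#' p-value from the t transform. Constant vectors give an undefined r and are
#' flagged.
#'
#' @param enhancer_rpkm enhancer x sample matrix.
#' @param gene_expr gene x sample matrix.
#' @param pairs data.frame with columns `enhancer_id`, `gene_id` (e.g. the
#'   linked pairs from [nearest_gene()]).
#' @return data.frame per pair: `enhancer_id`, `gene_id`, `pearson_r`,
#'   `p_value`, `n_samples`, `defined`.
#' @export
enhancer_gene_correlation <- function(enhancer_rpkm, gene_expr, pairs) {
  shared <- intersect(colnames(enhancer_rpkm), colnames(gene_expr))
  if (length(shared) < 3) stop("need >= 3 shared samples")
  miss_e <- setdiff(pairs$enhancer_id, rownames(enhancer_rpkm))
  if (length(miss_e)) stop("enhancers absent from RPKM matrix: ", miss_e[1])
  miss_g <- setdiff(pairs$gene_id, rownames(gene_expr))
  if (length(miss_g)) stop("genes absent from expression matrix: ", miss_g[1])
  n <- length(shared)
  r <- p <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    x <- enhancer_rpkm[pairs$enhancer_id[i], shared]
    y <- gene_expr[pairs$gene_id[i], shared]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    r[i] <- stats::cor(x, y)
    tt <- r[i] * sqrt((n - 2) / pmax(1 - r[i]^2, .Machine$double.eps))
    p[i] <- min(2 * stats::pt(-abs(tt), df = n - 2), 1)
  }
  data.frame(enhancer_id = pairs$enhancer_id, gene_id = pairs$gene_id,
             pearson_r = r, p_value = p, n_samples = n, defined = !is.na(r),
             stringsAsFactors = FALSE, row.names = NULL)
}
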