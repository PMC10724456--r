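#' Median-of-ratios size factors
#'
#' Library scaling via the median, over features, of each library's ratio to
#' the per-feature geometric mean across libraries (the Anders & Huber
#' estimator). Only features with strictly positive counts in every sample
#' contribute to the median.
#'
#' @param counts feature x sample count matrix.
#' @return named numeric vector of positive per-sample factors. Dividing each
#'   column by its factor yields the normalized matrix.
#' @export
size_factors <- function(counts) {
  if (nrow(counts) == 0 || ncol(counts) == 0) stop("empty count matrix")
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use))
    stop("no feature has positive counts in all samples; size factors undefined")
  sf <- apply(counts, 2, function(cnt) {
    exp(stats::median((log(cnt) - loggeo)[use]))
  })
  stats::setNames(sf, colnames(counts))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; results returned in input order.
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Correlate expression with gestational age
#'
#' Per-gene Pearson correlation of expression against gestational age in
#' weeks, with the least-squares slope/intercept and a two-sided p-value from
#' the t transform t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 df. Genes are
#' classified `increasing` when r > `r_threshold` and p < alpha / m
#' (Bonferroni over the m non-constant, testable genes), `decreasing`
#' symmetrically, and `unclassified` otherwise. Constant-expression genes are
#' excluded from m and flagged untestable.
#'
#' @param expr gene x sample expression matrix (RPKM/FPKM scale).
#' @param samples sample sheet; `gestational_age_weeks` is the regressor.
#' @param r_threshold correlation magnitude cutoff (default 0.7).
#' @param alpha family-wise error target before Bonferroni division
#'   (default 0.05).
#' @return data.frame per gene: `gene_id`, `pearson_r`, `p_value`, `slope`,
#'   `intercept`, `class`, `tested`; attributes `m_tested` and
#'   `bonferroni_cutoff`.
#' @export
correlate_with_age <- function(expr, samples, r_threshold = 0.7, alpha = 0.05) {
  age <- samples$gestational_age_weeks[match(colnames(expr), samples$sample_id)]
  if (any(is.na(age))) stop("samples absent from sample sheet: ",
                            paste(colnames(expr)[is.na(age)][1:2], collapse = ", "))
  if (length(unique(age)) < 3) stop("need >= 3 distinct gestational ages")
  n <- ncol(expr)
  sd_g <- apply(expr, 1, stats::sd)
  tested <- sd_g > 0
  m <- sum(tested)
  cutoff <- alpha / m
  r <- rep(NA_real_, nrow(expr))
  r[tested] <- as.vector(stats::cor(t(expr[tested, , drop = FALSE]), age))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p <- pmin(p, 1)
  slope <- r * sd_g / stats::sd(age)
  intercept <- rowMeans(expr) - slope * mean(age)
  cls <- rep("unclassified", nrow(expr))
  cls[tested & r > r_threshold & p < cutoff] <- "increasing"
  cls[tested & r < -r_threshold & p < cutoff] <- "decreasing"
  out <- data.frame(gene_id = rownames(expr), pearson_r = r, p_value = p,
                    slope = slope, intercept = intercept, class = cls,
                    tested = tested, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "m_tested") <- m
  attr(out, "bonferroni_cutoff") <- cutoff
  out
}

#' Bonferroni cutoff for a family of m tests
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of tests.
#' @return alpha / m.
#' @export
bonferroni_cutoff <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Pairwise differential test between two sample groups
#'
#' Per-feature two-sample t-test (pooled-variance Student by default, Welch
#' optionally) with log2 fold change computed on pseudocounted group means:
#' log2FC = log2((mean_B + eps) / (mean_A + eps)). q-values are
#' Benjamini-Hochberg; a feature is flagged significant when
#' |log2FC| >= log2(`fc_threshold`) and q < `alpha`.
#'
#' @param expr feature x sample matrix.
#' @param group_a,group_b disjoint character vectors of sample ids (>= 2
#'   each). Fold changes are B relative to A.
#' @param fc_threshold linear fold-change cutoff (default 2).
#' @param alpha FDR cutoff (default 0.05).
#' @param pseudocount added to group means before the ratio (default 0.1).
#' @param var_equal pooled-variance t-test when TRUE (default), Welch when
#'   FALSE.
#' @return data.frame per feature: `feature_id`, `mean_a`, `mean_b`,
#'   `log2_fc`, `t`, `p_value`, `q_value`, `significant`.
#' @export
pairwise_differential <- function(expr, group_a, group_b, fc_threshold = 2,
                                  alpha = 0.05, pseudocount = 0.1,
                                  var_equal = TRUE) {
  if (length(intersect(group_a, group_b)))
    stop("sample groups overlap: ", intersect(group_a, group_b)[1])
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 samples")
  miss <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(miss)) stop("samples absent from matrix: ", miss[1])
  a <- expr[, group_a, drop = FALSE]
  b <- expr[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, nrow(expr))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  diff <- mb - ma
  tstat <- diff / se
  p <- 2 * stats::pt(-abs(tstat), df = df)
  # degenerate zero-variance features: identical groups are null, separated
  # groups are maximally significant
  degen <- !is.finite(tstat)
  tstat[degen] <- ifelse(diff[degen] == 0, 0, sign(diff[degen]) * Inf)
  p[degen] <- ifelse(diff[degen] == 0, 1, 0)
  q <- bh_adjust(p)
  log2_fc <- log2((mb + pseudocount) / (ma + pseudocount))
  data.frame(feature_id = rownames(expr), mean_a = ma, mean_b = mb,
             log2_fc = log2_fc, t = tstat, p_value = p, q_value = q,
             significant = abs(log2_fc) >= log2(fc_threshold) & q < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Gestational-age epoch bins
#'
#' Partitions samples into `n_bins` age-ordered groups of near-equal size;
#' earlier bins absorb the remainder (36 samples in 5 bins gives sizes
#' 8,7,7,7,7). Age ties are broken by sample id.
#'
#' @param samples sample sheet.
#' @param n_bins number of bins (default 5).
#' @return data.frame `sample_id`, `gestational_age_weeks`, `bin` (1 =
#'   youngest), in bin order.
#' @export
epoch_bins <- function(samples, n_bins = 5) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  n <- nrow(samples)
  if (n < n_bins) stop("fewer samples than bins")
  ord <- order(samples$gestational_age_weeks, samples$sample_id)
  base <- n %/% n_bins
  rem <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1, rem), rep(0, n_bins - rem))
  data.frame(sample_id = samples$sample_id[ord],
             gestational_age_weeks = samples$gestational_age_weeks[ord],
             bin = rep(seq_len(n_bins), times = sizes),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Z-score trends across gestational-age epochs
#'
#' Each gene's expression is z-scored across samples (mean 0, sd 1), samples
#' are partitioned into age-ordered epoch bins, and the distribution of
#' z-scores per bin is summarized (the box-plot view of rising or falling
#' expression programs). Constant genes are excluded with a warning.
#'
#' @param expr gene x sample matrix.
#' @param samples sample sheet.
#' @param n_bins number of epochs (default 5).
#' @return list with `z` (gene x sample z-score matrix), `bins` (from
#'   [epoch_bins()]) and `summary` (per-bin mean/quartiles of pooled
#'   z-scores).
#' @export
epoch_trends <- function(expr, samples, n_bins = 5) {
  samples <- samples[match(colnames(expr), samples$sample_id), , drop = FALSE]
  if (any(is.na(samples$sample_id))) stop("matrix samples absent from sample sheet")
  sd_g <- apply(expr, 1, stats::sd)
  if (any(sd_g == 0)) {
    warning(sum(sd_g == 0), " constant gene(s) excluded from z-score trends")
    expr <- expr[sd_g > 0, , drop = FALSE]
  }
  z <- t(scale(t(expr)))
  bins <- epoch_bins(samples, n_bins)
  summ <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    zs <- as.vector(z[, bins$sample_id[bins$bin == b], drop = FALSE])
    data.frame(bin = b, n_samples = sum(bins$bin == b),
               mean_z = mean(zs), median_z = stats::median(zs),
               q25 = stats::quantile(zs, 0.25, names = FALSE),
               q75 = stats::quantile(zs, 0.75, names = FALSE))
  }))
  list(z = z, bins = bins, summary = summ)
}

#' Cell-type signature scores across epochs
#'
#' Scores each sample for each named gene set as the mean expression over the
#' set's genes present in the matrix, then compares scores between sample
#' groups (e.g. trimesters) with the pairwise differential machinery.
#'
#' @param expr gene x sample matrix.
#' @param gene_sets named list of gene id vectors.
#' @param groups named list of sample id vectors to compare pairwise; NULL
#'   skips testing.
#' @param ... passed to [pairwise_differential()].
#' @return list with `scores` (set x sample matrix) and `tests` (one
#'   differential table per group pair, named "A_vs_B").
#' @export
signature_score <- function(expr, gene_sets, groups = NULL, ...) {
  if (is.null(names(gene_sets)) || any(names(gene_sets) == ""))
    stop("gene_sets must be named")
  scores <- do.call(rbind, lapply(names(gene_sets), function(nm) {
    present <- intersect(gene_sets[[nm]], rownames(expr))
    if (length(present) == 0)
      stop("gene set '", nm, "' has no genes present in the matrix")
    colMeans(expr[present, , drop = FALSE])
  }))
  rownames(scores) <- names(gene_sets)
  tests <- list()
  if (!is.null(groups) && length(groups) >= 2) {
    pairs <- utils::combn(names(groups), 2, simplify = FALSE)
    for (pr in pairs) {
      tests[[paste0(pr[1], "_vs_", pr[2])]] <-
        pairwise_differential(scores, groups[[pr[1]]], groups[[pr[2]]], ...)
    }
  }
  list(scores = scores, tests = tests)
}

#' Comparative fold change by the delta-delta Ct method
#'
#' 2^-((Ct_target_b - Ct_ref_b) - (Ct_target_a - Ct_ref_a)): the fold change
#' of the target transcript in condition b relative to condition a, each
#' normalized to a reference transcript.
#'
#' @param ct_target_a,ct_ref_a target and reference Ct in condition a.
#' @param ct_target_b,ct_ref_b target and reference Ct in condition b.
#' @return fold change (positive scalar or vector).
#' @export
fold_change_ddct <- function(ct_target_a, ct_ref_a, ct_target_b, ct_ref_b) {
  stopifnot(is.finite(ct_target_a), is.finite(ct_ref_a),
            is.finite(ct_target_b), is.finite(ct_ref_b))
  ddct <- (ct_target_b - ct_ref_b) - (ct_target_a - ct_ref_a)
  2^(-ddct)
}
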