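#' Min-max normalize a matrix
#'
#' (x - min) / (max - min) along the chosen axis; zero-range slices map to
#' all-zeros. This is the scaling used throughout the TFSEE computation to
#' put signals from different assays on a common \[0, 1\] scale.
#'
#' @param m numeric matrix.
#' @param axis "feature" (per row, across samples; default), "sample" (per
#'   column) or "global".
#' @return matrix of the same shape with entries in \[0, 1\].
#' @export
minmax_normalize <- function(m, axis = c("feature", "sample", "global")) {
  axis <- match.arg(axis)
  if (any(!is.finite(m))) stop("matrix entries must be finite")
  scale1 <- function(x) {
    rng <- max(x) - min(x)
    if (rng == 0) rep(0, length(x)) else (x - min(x)) / rng
  }
  out <- switch(axis,
    feature = t(apply(m, 1, scale1)),
    sample = apply(m, 2, scale1),
    global = matrix(scale1(as.vector(m)), nrow = nrow(m)))
  dimnames(out) <- dimnames(m)
  out
}

#' Enhancer activity from transcription and histone marks
#'
#' Activity integrates the eRNA signal with H3K27ac and H3K4me1 enrichment:
#' A = N(eRNA) * (N(K27ac) + N(K4me1)) / 2, where N is per-enhancer min-max
#' across samples and * is elementwise. eRNA is the defining signal: zero
#' (per-enhancer minimal) transcription forces zero activity regardless of
#' the marks. `combine = "product"` uses the full three-way product instead
#' of averaging the marks.
#'
#' @param erna,k27ac,k4me1 enhancer x sample matrices over the same index
#'   sets.
#' @param combine "mean_marks" (default) or "product".
#' @return enhancer x sample activity matrix, entries in \[0, 1\].
#' @export
enhancer_activity <- function(erna, k27ac, k4me1,
                              combine = c("mean_marks", "product")) {
  combine <- match.arg(combine)
  for (m in list(k27ac, k4me1)) {
    if (!identical(dimnames(m), dimnames(erna)))
      stop("eRNA and histone matrices must share identical feature and sample indices")
  }
  ne <- minmax_normalize(erna, "feature")
  n27 <- minmax_normalize(k27ac, "feature")
  n4 <- minmax_normalize(k4me1, "feature")
  a <- if (combine == "mean_marks") ne * (n27 + n4) / 2 else ne * n27 * n4
  a
}

#' Build the enhancer x TF motif matrix
#'
#' Per enhancer, the strongest `top_k` motif hits (by match strength,
#' -log10 of the motif match p-value; ties by tf then motif id) are kept.
#' M(e, t) is the maximum kept strength for that TF (strongest site
#' represents the TF; `reduce = "sum"` accumulates instead), then scaled per
#' TF across enhancers onto \[0, 1\]. Absent pairs are 0, which anchors the
#' scale's floor, so the scaling divides by the per-TF maximum.
#'
#' @param hits data.frame with columns `enhancer_id`, `tf_id`, `motif_id`,
#'   and either `match_p` or `match_strength`.
#' @param enhancer_ids,tf_ids row and column universes of the matrix.
#' @param top_k motif cap per enhancer (default 20).
#' @param reduce "max" (default) or "sum".
#' @return enhancer x TF matrix in \[0, 1\].
#' @export
build_motif_matrix <- function(hits, enhancer_ids, tf_ids, top_k = 20,
                               reduce = c("max", "sum")) {
  reduce <- match.arg(reduce)
  if (!"match_strength" %in% colnames(hits)) {
    if (!"match_p" %in% colnames(hits))
      stop("hits need a match_p or match_strength column")
    hits$match_strength <- -log10(hits$match_p)
  }
  if (any(hits$match_strength <= 0))
    stop("match strengths must be strictly positive")
  unknown <- setdiff(hits$tf_id, tf_ids)
  if (length(unknown)) stop("unknown tf_id in motif hits: ", unknown[1])
  unknown <- setdiff(hits$enhancer_id, enhancer_ids)
  if (length(unknown)) stop("unknown enhancer_id in motif hits: ", unknown[1])
  M <- matrix(0, nrow = length(enhancer_ids), ncol = length(tf_ids),
              dimnames = list(enhancer_ids, tf_ids))
  if (nrow(hits)) {
    ord <- order(hits$enhancer_id, -hits$match_strength, hits$tf_id,
                 hits$motif_id)
    hits <- hits[ord, , drop = FALSE]
    within_rank <- stats::ave(seq_len(nrow(hits)), hits$enhancer_id,
                              FUN = seq_along)
    kept <- hits[within_rank <= top_k, , drop = FALSE]
    agg_fun <- if (reduce == "max") max else sum
    agg <- tapply(kept$match_strength,
                  list(kept$enhancer_id, kept$tf_id), agg_fun)
    agg[is.na(agg)] <- 0
    M[rownames(agg), colnames(agg)] <- agg
  }
  # per-TF scaling across enhancers onto [0,1]; the floor of the strength
  # scale is the 0 of absent pairs, so scaling divides by the column maximum
  mx <- apply(M, 2, max)
  sweep(M, 2, ifelse(mx > 0, mx, 1), "/")
}

#' Per-sample TFSEE scores
#'
#' The Total Functional Score of Enhancer Elements: enhancer activity is
#' propagated to TFs through the motif matrix and integrated with TF
#' expression. I = t(A) M (samples x TFs); S_raw = I * N(E) with N the
#' per-TF min-max of expression across samples; S is S_raw min-max scaled
#' per TF across samples.
#'
#' @param activity enhancer x sample activity matrix (from
#'   [enhancer_activity()]).
#' @param motif_matrix enhancer x TF matrix (from [build_motif_matrix()]).
#' @param tf_expr TF x sample expression matrix.
#' @return sample x TF score matrix, entries in \[0, 1\].
#' @export
tfsee_scores <- function(activity, motif_matrix, tf_expr) {
  if (!identical(rownames(activity), rownames(motif_matrix)))
    stop("activity and motif matrix enhancer indices differ")
  if (!identical(colnames(motif_matrix), rownames(tf_expr)))
    stop("motif matrix and TF expression TF indices differ")
  if (!identical(colnames(activity), colnames(tf_expr)))
    stop("activity and TF expression sample indices differ")
  I <- t(activity) %*% motif_matrix            # samples x TFs
  NE <- t(minmax_normalize(tf_expr, "feature")) # samples x TFs
  S_raw <- I * NE
  minmax_normalize(t(S_raw), "feature") |> t()
}

#' Hierarchical clustering of samples by TFSEE profile
#'
#' Distance d(i, j) = 1 - Pearson(S_i, S_j) between sample score vectors;
#' agglomerative average linkage (UPGMA). The 2-clade partition is the cut at
#' the root.
#'
#' @param scores sample x TF score matrix.
#' @return list with `hclust`, `order` (leaf order, sample ids) and `clades`
#'   (named integer vector, 2 clusters).
#' @export
cluster_samples <- function(scores) {
  if (nrow(scores) < 2) stop("need >= 2 samples to cluster")
  sds <- apply(scores, 1, stats::sd)
  if (any(sds == 0))
    stop("constant score vector for sample: ",
         rownames(scores)[sds == 0][1])
  d <- stats::as.dist(1 - stats::cor(t(scores)))
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, order = rownames(scores)[hc$order],
       clades = stats::cutree(hc, k = 2))
}

#' Differential TFSEE between early and late pregnancy
#'
#' Per TF: delta = mean(S late) - mean(S early) with a two-sided two-sample
#' t-test; TFs ranked ascending by delta (most early-active first, most
#' late-active last).
#'
#' @param scores sample x TF score matrix.
#' @param early,late disjoint sample id vectors (>= 2 each).
#' @param alpha significance cutoff on the unadjusted p-value (default
#'   0.05).
#' @param var_equal pooled-variance t-test when TRUE (default).
#' @return data.frame ordered by `delta`: `tf_id`, `mean_early`,
#'   `mean_late`, `delta`, `t`, `p_value`, `significant`, `rank`.
#' @export
differential_tfsee <- function(scores, early, late, alpha = 0.05,
                               var_equal = TRUE) {
  if (length(intersect(early, late))) stop("early and late groups overlap")
  if (length(early) < 2 || length(late) < 2)
    stop("each group needs >= 2 samples")
  expr <- t(scores)  # TFs x samples
  tab <- pairwise_differential(expr, group_a = early, group_b = late,
                               fc_threshold = 1, alpha = alpha,
                               pseudocount = 0, var_equal = var_equal)
  out <- data.frame(tf_id = tab$feature_id, mean_early = tab$mean_a,
                    mean_late = tab$mean_b, delta = tab$mean_b - tab$mean_a,
                    t = tab$t, p_value = tab$p_value,
                    significant = tab$p_value < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$delta, out$tf_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Fit the TFSEE model
#'
#' End-to-end TFSEE: enhancer activity from eRNA and histone marks, motif
#' matrix from the hit table, per-sample TF scores, sample clustering, and
#' the early-versus-late differential ranking. "Early" is trimesters I and
#' II, "late" is trimester III, unless groups are given explicitly.
#'
#' @param erna,k27ac,k4me1 enhancer x sample matrices over the enhancer
#'   universe.
#' @param motif_hits motif hit table (see [build_motif_matrix()]).
#' @param tf_expr TF x sample expression matrix.
#' @param samples sample sheet covering the matrix samples.
#' @param early,late optional explicit sample groups; defaults derived from
#'   the sample sheet trimester.
#' @param top_k motif cap per enhancer (default 20).
#' @param alpha significance cutoff for the differential table.
#' @param combine activity combination rule (see [enhancer_activity()]).
#' @return object of class `tfsee`: list with `scores`, `activity`,
#'   `motif_matrix`, `clustering`, `differential`, `early`, `late`.
#' @export
tfsee <- function(erna, k27ac, k4me1, motif_hits, tf_expr, samples,
                  early = NULL, late = NULL, top_k = 20, alpha = 0.05,
                  combine = "mean_marks") {
  if (is.null(early) || is.null(late)) {
    tri <- samples$trimester[match(colnames(erna), samples$sample_id)]
    if (any(is.na(tri))) stop("matrix samples absent from sample sheet")
    early <- colnames(erna)[tri %in% c("I", "II")]
    late <- colnames(erna)[tri == "III"]
  }
  A <- enhancer_activity(erna, k27ac, k4me1, combine = combine)
  M <- build_motif_matrix(motif_hits, enhancer_ids = rownames(erna),
                          tf_ids = rownames(tf_expr), top_k = top_k)
  S <- tfsee_scores(A, M, tf_expr)
  cl <- cluster_samples(S)
  diff <- differential_tfsee(S, early = early, late = late, alpha = alpha)
  out <- list(scores = S, activity = A, motif_matrix = M, clustering = cl,
              differential = diff, early = early, late = late)
  class(out) <- "tfsee"
  out
}

#' @export
print.tfsee <- function(x, ...) {
  cat("TFSEE fit\n")
  cat(sprintf("  %d samples x %d TFs over %d enhancers\n",
              nrow(x$scores), ncol(x$scores), nrow(x$motif_matrix)))
  cat(sprintf("  early n=%d, late n=%d; %d TF(s) with p < alpha\n",
              length(x$early), length(x$late), sum(x$differential$significant)))
  top <- utils::head(x$differential, 3)
  bot <- utils::tail(x$differential, 3)
  cat("  most early-active: ", paste(top$tf_id, collapse = ", "), "\n")
  cat("  most late-active:  ", paste(rev(bot$tf_id), collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a TFSEE fit
#' @param object a `tfsee` object.
#' @param ... unused.
#' @method summary tfsee
#' @export
summary.tfsee <- function(object, ...) {
  d <- object$differential
  structure(list(differential = d,
                 n_significant = sum(d$significant),
                 clades = object$clustering$clades,
                 leaf_order = object$clustering$order),
            class = "summary.tfsee")
}

#' @export
print.summary.tfsee <- function(x, ...) {
  cat("Differential TFSEE (late - early), ranked:\n")
  print(utils::head(x$differential, 10), row.names = FALSE)
  if (nrow(x$differential) > 10) cat("  ...", nrow(x$differential) - 10, "more\n")
  cat(sprintf("%d significant TF(s); sample clades: %s\n", x$n_significant,
              paste(table(x$clades), collapse = " vs ")))
  invisible(x)
}

#' Heatmap of TFSEE scores with the sample dendrogram
#' @param x a `tfsee` object.
#' @param ... passed to [stats::heatmap()].
#' @method plot tfsee
#' @export
plot.tfsee <- function(x, ...) {
  stats::heatmap(t(x$scores), Colv = stats::as.dendrogram(x$clustering$hclust),
                 scale = "none", xlab = "samples", ylab = "TFs", ...)
  invisible(x)
}
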