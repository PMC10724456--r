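#' Analysis configuration with the pipeline's canonical defaults
#'
#' Collects every tunable threshold with its default: distal gap > 5000 bp,
#' RPKM >= 2 in >= 1 sample, Pearson |r| > 0.7, alpha 0.05, 2-fold change,
#' top 20 motifs per enhancer, 5 gestational-age bins.
#'
#' @param distal_min_gap_bp minimum enhancer-gene gap (strict).
#' @param rpkm_threshold inclusive expression cutoff.
#' @param min_samples samples required at or above the cutoff.
#' @param pearson_r_threshold age-correlation magnitude cutoff.
#' @param alpha significance level.
#' @param fold_change_threshold linear fold-change cutoff.
#' @param tfsee_top_k_motifs motif cap per enhancer.
#' @param n_epoch_bins gestational-age bins.
#' @param seed random seed.
#' @return validated list of class `analysis_config`.
#' @export
analysis_config <- function(distal_min_gap_bp = 5000, rpkm_threshold = 2.0,
                            min_samples = 1, pearson_r_threshold = 0.7,
                            alpha = 0.05, fold_change_threshold = 2.0,
                            tfsee_top_k_motifs = 20, n_epoch_bins = 5,
                            seed = 1) {
  cfg <- as.list(environment())
  for (nm in setdiff(names(cfg), "seed"))
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop(nm, " must be strictly positive")
  class(cfg) <- "analysis_config"
  cfg
}
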