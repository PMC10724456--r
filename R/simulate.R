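#' Configuration for the synthetic multi-omic study generator
#'
#' Defaults emulate the study design the pipeline targets: 36 placental
#' samples (12 per trimester) with eRNA (PRO-seq-like), H3K27ac/H3K4me1
#' (ChIP-seq-like) and RNA-seq-like gene/TF expression, plus a GWAS-style SNP
#' catalog. Planted structure: early-active and late-active enhancer
#' programs, early/late transcription factors with motifs in the matching
#' enhancer class, genes linear in gestational age, promoter-proximal decoy
#' TREs the distal filter must remove, and SNPs at elevated density inside
#' enhancers.
#'
#' @param n_chromosomes,chrom_length_bp genome layout.
#' @param n_genes,n_enhancers planted feature counts.
#' @param gene_length_bp,enhancer_length_bp feature sizes.
#' @param n_samples_per_trimester samples per trimester (default 12).
#' @param n_tfs_early,n_tfs_late,n_tfs_decoy TF program sizes.
#' @param effect_size_log2 mean log2 activity/expression difference between
#'   the favored and disfavored pregnancy phase for planted enhancers and
#'   TFs (default 2).
#' @param nb_dispersion negative-binomial dispersion of all counts.
#' @param frac_age_correlated_genes fraction of genes with expression linear
#'   in gestational age (half increasing, half decreasing).
#' @param age_fold_span linear fold change spanned by age-correlated genes
#'   from 6 to 39 weeks (default 6).
#' @param snp_enhancer_density_ratio SNP density multiplier inside enhancers.
#' @param n_snps background catalog size.
#' @param n_decoy_tres promoter-proximal decoy TREs (within 5 kb of a gene
#'   start).
#' @param motif_plant_prob probability a planted TF's motif lands in a
#'   matching-class enhancer.
#' @param n_background_motifs decoy-TF motif hits per enhancer.
#' @param library_size total mapped reads per library (for RPKM).
#' @param baseline_erna_mean,baseline_gene_mean,baseline_tf_mean count-scale
#'   baselines.
#' @param distal_min_gap_bp distal-filter gap the layout must respect.
#' @param seed master seed; every stochastic routine derives a fixed child
#'   seed from it, so identical config + seed gives byte-identical outputs.
#' @return a validated list of class `sim_config`.
#' @export
simulation_config <- function(n_chromosomes = 4, chrom_length_bp = 8e6,
                              n_genes = 2000, n_enhancers = 500,
                              gene_length_bp = 2000, enhancer_length_bp = 500,
                              n_samples_per_trimester = 12,
                              n_tfs_early = 5, n_tfs_late = 5,
                              n_tfs_decoy = 50, effect_size_log2 = 2,
                              nb_dispersion = 0.05,
                              frac_age_correlated_genes = 0.1,
                              age_fold_span = 6,
                              snp_enhancer_density_ratio = 3,
                              n_snps = 20000, n_decoy_tres = 100,
                              motif_plant_prob = 0.7,
                              n_background_motifs = 5,
                              library_size = 2e7,
                              baseline_erna_mean = 200,
                              baseline_gene_mean = 100,
                              baseline_tf_mean = 100,
                              distal_min_gap_bp = 5000, seed = 1) {
  cfg <- as.list(environment())
  num_pos <- c("n_chromosomes", "chrom_length_bp", "n_genes", "n_enhancers",
               "gene_length_bp", "enhancer_length_bp",
               "n_samples_per_trimester", "n_tfs_early", "n_tfs_late",
               "n_tfs_decoy", "nb_dispersion", "snp_enhancer_density_ratio",
               "n_snps", "library_size", "baseline_erna_mean",
               "baseline_gene_mean", "baseline_tf_mean", "distal_min_gap_bp")
  for (nm in num_pos) if (cfg[[nm]] <= 0) stop(nm, " must be strictly positive")
  if (cfg$effect_size_log2 < 0) stop("effect_size_log2 must be >= 0")
  if (cfg$frac_age_correlated_genes < 0 || cfg$frac_age_correlated_genes > 1)
    stop("frac_age_correlated_genes must lie in [0, 1]")
  if (cfg$n_tfs_early < 1 || cfg$n_tfs_late < 1)
    stop("need at least one early and one late TF")
  class(cfg) <- "sim_config"
  cfg
}

# deterministic child seed per stage, keeps values inside 32-bit range
child_seed <- function(seed, stage) {
  offs <- c(layout = 11, samples = 23, erna = 37, marks = 41, genes = 53,
            tfs = 67, motifs = 79, snps = 97, tres = 113)
  (as.numeric(seed) * 48271 + offs[[stage]]) %% 2147483647
}

rnb <- function(n, mu, dispersion) {
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Generate a complete synthetic placental multi-omic study
#'
#' Lays out genes and enhancers on a synthetic genome honoring the distal
#' filter, draws samples across the three trimesters, generates
#' negative-binomial count matrices with the planted trimester programs,
#' motif hits, TF expression, and a SNP catalog with enhancer-elevated
#' density, and records the ground truth needed to score every downstream
#' stage. Identical config + seed reproduce identical outputs byte for byte.
#'
#' @param config a [simulation_config()].
#' @param out_dir when non-NULL, all standard input files (gene BED, sample
#'   sheet, per-sample TRE BEDs, matrices, motif table, SNP catalog, library
#'   sizes, ground_truth.json) are written there.
#' @return list of class `placenta_sim` with elements `config`, `genes`,
#'   `enhancers` (with planted `class`), `decoy_tres`, `samples`,
#'   `tre_sets`, `counts_erna`, `k27ac`, `k4me1`, `counts_gene`, `fpkm_gene`,
#'   `tf_expr`, `motif_hits`, `snp_catalog`, `library_sizes`, `genome_size_bp`,
#'   `ground_truth`.
#' @export
simulate_dataset <- function(config = simulation_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config

  ## -- genome layout -------------------------------------------------------
  n_feat <- cfg$n_genes + cfg$n_enhancers
  per_chrom <- diff(round(seq(0, n_feat, length.out = cfg$n_chromosomes + 1)))
  min_gap <- cfg$distal_min_gap_bp + 1000  # guard beyond the strict >5 kb
  # feasibility before anything is drawn or written
  for (k in per_chrom) {
    need <- k * max(cfg$gene_length_bp, cfg$enhancer_length_bp) +
      (k + 1) * min_gap
    if (need > cfg$chrom_length_bp)
      stop("infeasible placement: chromosome of ", cfg$chrom_length_bp,
           " bp cannot hold ", k, " features with ", min_gap, " bp gaps")
  }
  set.seed(child_seed(cfg$seed, "layout"))
  types <- sample(rep(c("gene", "enhancer"),
                      times = c(cfg$n_genes, cfg$n_enhancers)))
  chrom_of <- rep(paste0("chr", seq_len(cfg$n_chromosomes)),
                  times = per_chrom)
  lens <- ifelse(types == "gene", cfg$gene_length_bp, cfg$enhancer_length_bp)
  start <- numeric(n_feat)
  idx <- 1
  for (ci in seq_len(cfg$n_chromosomes)) {
    k <- per_chrom[ci]
    if (k == 0) next
    rows <- idx:(idx + k - 1)
    slack <- cfg$chrom_length_bp - sum(lens[rows]) - (k + 1) * min_gap
    extras <- sample.int(3001, k + 1, replace = TRUE) - 1
    if (sum(extras) > slack) extras <- floor(extras * slack / sum(extras))
    gaps <- min_gap + extras
    pos <- cumsum(gaps[seq_len(k)] + c(0, lens[rows][-k]))
    start[rows] <- pos
    idx <- idx + k
  }
  is_gene <- types == "gene"
  gid <- sprintf("gene%04d", seq_len(cfg$n_genes))
  gstrand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  genes <- make_genes(chrom_of[is_gene], start[is_gene],
                      start[is_gene] + cfg$gene_length_bp, gstrand, gid)
  enh <- genomic_intervals(chrom_of[!is_gene], start[!is_gene],
                           start[!is_gene] + cfg$enhancer_length_bp)
  cls <- sample(rep_len(c("early-active", "late-active", "constitutive"),
                        cfg$n_enhancers))
  enhancers <- cbind(enh, class = cls, stringsAsFactors = FALSE)

  # promoter-proximal decoy TREs: 2 kb upstream of selected gene starts,
  # always within the distal-filter exclusion zone
  n_dec <- min(cfg$n_decoy_tres, cfg$n_genes)
  dec_genes <- sort(sample.int(cfg$n_genes, n_dec))
  decoy_tres <- genomic_intervals(genes$chrom[dec_genes],
                                  genes$start[dec_genes] - 2000,
                                  genes$start[dec_genes] - 1500)

  ## -- samples -------------------------------------------------------------
  set.seed(child_seed(cfg$seed, "samples"))
  npt <- cfg$n_samples_per_trimester
  n_samp <- 3 * npt
  ages <- c(round(stats::runif(npt, 6, 13), 1),
            round(stats::runif(npt, 14, 27), 1),
            rep(39, npt))
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n_samp)),
    gestational_age_weeks = ages,
    trimester = trimester_of(ages),
    sex = sample(c("M", "F"), n_samp, replace = TRUE),
    assays = "rnaseq,proseq,k27ac,k4me1",
    stringsAsFactors = FALSE)
  is_early <- samples$trimester %in% c("I", "II")

  ## -- per-sample TRE calls ------------------------------------------------
  set.seed(child_seed(cfg$seed, "tres"))
  active_in <- function(class, early) {
    class == "constitutive" | (class == "early-active" & early) |
      (class == "late-active" & !early)
  }
  decoy_member <- matrix(stats::runif(n_dec * n_samp) < 0.5, nrow = n_dec)
  tre_sets <- stats::setNames(lapply(seq_len(n_samp), function(s) {
    e <- enhancers[active_in(enhancers$class, is_early[s]),
                   c("chrom", "start", "end", "strand", "id")]
    d <- decoy_tres[decoy_member[, s], , drop = FALSE]
    out <- rbind(e, d)
    out[order(out$chrom, out$start), , drop = FALSE]
  }), samples$sample_id)

  # count features = every planted interval that appears in >= 1 TRE call
  seen_dec <- rowSums(decoy_member) > 0
  feat <- rbind(enhancers[, c("chrom", "start", "end", "strand", "id")],
                decoy_tres[seen_dec, , drop = FALSE])
  feat <- feat[order(feat$chrom, feat$start), , drop = FALSE]

  ## -- eRNA counts ---------------------------------------------------------
  set.seed(child_seed(cfg$seed, "erna"))
  mu0 <- stats::setNames(stats::rlnorm(nrow(feat), log(cfg$baseline_erna_mean),
                                       0.5), feat$id)
  fc <- 2^cfg$effect_size_log2
  klass <- stats::setNames(rep("constitutive", nrow(feat)), feat$id)
  klass[enhancers$id] <- enhancers$class
  mu_mat <- outer(mu0, rep(1, n_samp))
  dimnames(mu_mat) <- list(feat$id, samples$sample_id)
  mu_mat[klass == "early-active", !is_early] <-
    mu_mat[klass == "early-active", !is_early] / fc
  mu_mat[klass == "late-active", is_early] <-
    mu_mat[klass == "late-active", is_early] / fc
  counts_erna <- matrix(rnb(length(mu_mat), as.vector(mu_mat),
                            cfg$nb_dispersion),
                        nrow = nrow(mu_mat), dimnames = dimnames(mu_mat))

  ## -- histone marks: monotone noisy transforms of the eRNA means ----------
  set.seed(child_seed(cfg$seed, "marks"))
  k27ac <- matrix(rnb(length(mu_mat), as.vector(0.8 * mu_mat),
                      cfg$nb_dispersion),
                  nrow = nrow(mu_mat), dimnames = dimnames(mu_mat))
  k4me1 <- matrix(rnb(length(mu_mat), as.vector(0.6 * mu_mat),
                      cfg$nb_dispersion),
                  nrow = nrow(mu_mat), dimnames = dimnames(mu_mat))

  ## -- gene expression -----------------------------------------------------
  set.seed(child_seed(cfg$seed, "genes"))
  n_ac <- round(cfg$frac_age_correlated_genes * cfg$n_genes)
  n_up <- n_ac %/% 2
  n_down <- n_ac - n_up
  ac_idx <- sample.int(cfg$n_genes, n_ac)
  up_idx <- ac_idx[seq_len(n_up)]
  down_idx <- ac_idx[n_up + seq_len(n_down)]
  gmu0 <- stats::rlnorm(cfg$n_genes, log(cfg$baseline_gene_mean), 0.6)
  x <- (samples$gestational_age_weeks - 6) / 33  # 0 at 6 wk, 1 at 39 wk
  span <- cfg$age_fold_span
  gmu <- outer(gmu0, rep(1, n_samp))
  gmu[up_idx, ] <- gmu0[up_idx] %o% (1 + (span - 1) * x)
  gmu[down_idx, ] <- gmu0[down_idx] %o% (span - (span - 1) * x)
  dimnames(gmu) <- list(gid, samples$sample_id)
  counts_gene <- matrix(rnb(length(gmu), as.vector(gmu), cfg$nb_dispersion),
                        nrow = nrow(gmu), dimnames = dimnames(gmu))
  lib <- stats::setNames(rep(cfg$library_size, n_samp), samples$sample_id)
  fpkm_gene <- compute_rpkm(counts_gene,
                            stats::setNames(rep(cfg$gene_length_bp,
                                                cfg$n_genes), gid), lib)

  ## -- TF expression -------------------------------------------------------
  set.seed(child_seed(cfg$seed, "tfs"))
  early_tfs <- sprintf("TF_E%02d", seq_len(cfg$n_tfs_early))
  late_tfs <- sprintf("TF_L%02d", seq_len(cfg$n_tfs_late))
  decoy_tfs <- sprintf("TF_D%02d", seq_len(cfg$n_tfs_decoy))
  tf_ids <- c(early_tfs, late_tfs, decoy_tfs)
  tmu0 <- stats::rlnorm(length(tf_ids), log(cfg$baseline_tf_mean), 0.4)
  tmu <- outer(tmu0, rep(1, n_samp))
  dimnames(tmu) <- list(tf_ids, samples$sample_id)
  tmu[early_tfs, !is_early] <- tmu[early_tfs, !is_early] / fc
  tmu[late_tfs, is_early] <- tmu[late_tfs, is_early] / fc
  tf_expr <- matrix(rnb(length(tmu), as.vector(tmu), cfg$nb_dispersion),
                    nrow = nrow(tmu), dimnames = dimnames(tmu))

  ## -- motif hits ----------------------------------------------------------
  set.seed(child_seed(cfg$seed, "motifs"))
  hit_rows <- list()
  plant <- function(enh_ids, tfs) {
    grid <- expand.grid(enhancer_id = enh_ids, tf_id = tfs,
                        stringsAsFactors = FALSE)
    grid <- grid[stats::runif(nrow(grid)) < cfg$motif_plant_prob, ,
                 drop = FALSE]
    grid$match_p <- 10^-stats::runif(nrow(grid), 6, 12)
    grid
  }
  hit_rows$early <- plant(enhancers$id[enhancers$class == "early-active"],
                          early_tfs)
  hit_rows$late <- plant(enhancers$id[enhancers$class == "late-active"],
                         late_tfs)
  bg <- do.call(rbind, lapply(enhancers$id, function(e) {
    data.frame(enhancer_id = e,
               tf_id = sample(decoy_tfs, min(cfg$n_background_motifs,
                                             length(decoy_tfs))),
               stringsAsFactors = FALSE)
  }))
  bg$match_p <- 10^-stats::runif(nrow(bg), 2, 4)
  motif_hits <- rbind(hit_rows$early, hit_rows$late, bg)
  motif_hits$motif_id <- sprintf("motif_%05d", seq_len(nrow(motif_hits)))
  rownames(motif_hits) <- NULL

  ## -- SNP catalog ---------------------------------------------------------
  set.seed(child_seed(cfg$seed, "snps"))
  genome_size <- cfg$n_chromosomes * cfg$chrom_length_bp
  chrom_names <- paste0("chr", seq_len(cfg$n_chromosomes))
  bg_chrom <- sample(chrom_names, cfg$n_snps, replace = TRUE)
  bg_pos <- floor(stats::runif(cfg$n_snps, 0, cfg$chrom_length_bp))
  enh_bp <- sum(enhancers$end - enhancers$start)
  extra_n <- stats::rpois(1, (cfg$snp_enhancer_density_ratio - 1) *
                            (cfg$n_snps / genome_size) * enh_bp)
  which_enh <- sample.int(nrow(enhancers), extra_n, replace = TRUE)
  extra_pos <- floor(enhancers$start[which_enh] +
                       stats::runif(extra_n) *
                       (enhancers$end[which_enh] - enhancers$start[which_enh]))
  traits <- c("preeclampsia", "birth_weight", "gestational_diabetes",
              "preterm_birth", "blood_pressure")
  snp_catalog <- data.frame(
    snp_id = sprintf("rs%06d", seq_len(cfg$n_snps + extra_n)),
    chrom = c(bg_chrom, enhancers$chrom[which_enh]),
    pos = c(bg_pos, extra_pos),
    trait = sample(traits, cfg$n_snps + extra_n, replace = TRUE),
    stringsAsFactors = FALSE)
  in_enh <- annotate_snps_in_regions(snp_catalog, enhancers)$contained

  ## -- ground truth --------------------------------------------------------
  sig_up <- gid[up_idx][seq_len(min(30, n_up))]
  null_gid <- setdiff(gid, gid[ac_idx])
  sig_null <- null_gid[seq_len(min(30, length(null_gid)))]
  ground_truth <- list(
    early_tfs = early_tfs, late_tfs = late_tfs, decoy_tfs = decoy_tfs,
    enhancer_class = stats::setNames(enhancers$class, enhancers$id),
    age_up_genes = sort(gid[up_idx]), age_down_genes = sort(gid[down_idx]),
    decoy_tre_ids = decoy_tres$id,
    planted_snp_counts = list(inside_enhancers = sum(in_enh),
                              outside_enhancers = sum(!in_enh)),
    signature_sets = list(ST_like = sig_up, CTB_like = sig_null))
  stopifnot(length(intersect(early_tfs, late_tfs)) == 0,
            length(intersect(early_tfs, decoy_tfs)) == 0,
            length(intersect(late_tfs, decoy_tfs)) == 0)

  sim <- list(config = cfg, genes = genes, enhancers = enhancers,
              decoy_tres = decoy_tres, samples = samples,
              tre_sets = tre_sets, counts_erna = counts_erna,
              k27ac = k27ac, k4me1 = k4me1, counts_gene = counts_gene,
              fpkm_gene = fpkm_gene, tf_expr = tf_expr,
              motif_hits = motif_hits, snp_catalog = snp_catalog,
              library_sizes = lib, genome_size_bp = genome_size,
              ground_truth = ground_truth)
  class(sim) <- "placenta_sim"
  if (!is.null(out_dir)) write_simulation(sim, out_dir)
  sim
}

#' @export
print.placenta_sim <- function(x, ...) {
  cat("Synthetic placental multi-omic study\n")
  cat(sprintf("  %d samples (%s), %d genes, %d enhancers (+%d decoy TREs)\n",
              nrow(x$samples),
              paste(table(x$samples$trimester), collapse = "/"),
              nrow(x$genes), nrow(x$enhancers), nrow(x$decoy_tres)))
  cat(sprintf("  TFs: %d early, %d late, %d decoy; %d SNPs; seed %s\n",
              length(x$ground_truth$early_tfs),
              length(x$ground_truth$late_tfs),
              length(x$ground_truth$decoy_tfs), nrow(x$snp_catalog),
              format(x$config$seed)))
  invisible(x)
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' @param sim a `placenta_sim` object.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tre_dir <- file.path(out_dir, "tre_calls")
  dir.create(tre_dir, showWarnings = FALSE)
  write_bed(cbind(sim$genes[, c("chrom", "start", "end")],
                  id = sim$genes$gene_id, strand = sim$genes$strand),
            file.path(out_dir, "genes.bed"))
  utils::write.table(sim$samples, file.path(out_dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in names(sim$tre_sets))
    write_bed(sim$tre_sets[[s]], file.path(tre_dir, paste0(s, ".bed")))
  write_matrix(sim$counts_erna, file.path(out_dir, "erna_counts.tsv"))
  write_matrix(sim$k27ac, file.path(out_dir, "k27ac.tsv"))
  write_matrix(sim$k4me1, file.path(out_dir, "k4me1.tsv"))
  write_matrix(sim$counts_gene, file.path(out_dir, "gene_counts.tsv"),
               id_col = "gene_id")
  write_matrix(sim$fpkm_gene, file.path(out_dir, "gene_fpkm.tsv"),
               id_col = "gene_id")
  write_matrix(sim$tf_expr, file.path(out_dir, "tf_expr.tsv"),
               id_col = "tf_id")
  write_table(sim$motif_hits[, c("enhancer_id", "tf_id", "motif_id",
                                 "match_p")],
              file.path(out_dir, "motif_hits.tsv"))
  snp_out <- data.frame(snp_id = sim$snp_catalog$snp_id,
                        chrom = sim$snp_catalog$chrom,
                        pos_1based = sim$snp_catalog$pos + 1,
                        trait = sim$snp_catalog$trait)
  utils::write.table(snp_out, file.path(out_dir, "snp_catalog.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = names(sim$library_sizes),
                                library_size = sim$library_sizes),
                     file.path(out_dir, "library_sizes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- sim$ground_truth
  gt$enhancer_class <- as.list(gt$enhancer_class)
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Sensitivity and specificity of a predicted set against truth
#'
#' @param truth,predicted character vectors of ids, both subsets of
#'   `universe`.
#' @param universe the id universe.
#' @return list with `sensitivity`, `specificity`, `tp`, `fp`, `fn`, `tn`.
#' @export
recovery_metrics <- function(truth, predicted, universe) {
  bad <- setdiff(c(truth, predicted), universe)
  if (length(bad))
    stop("ids outside the universe: ",
         paste(utils::head(bad, 3), collapse = ", "))
  truth <- unique(truth); predicted <- unique(predicted)
  tp <- length(intersect(truth, predicted))
  fn <- length(setdiff(truth, predicted))
  fp <- length(setdiff(predicted, truth))
  tn <- length(universe) - tp - fn - fp
  list(sensitivity = if (length(truth)) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Score pipeline outputs against the generator's ground truth
#'
#' @param ground_truth the `ground_truth` element of a `placenta_sim`.
#' @param age_result optional output of [correlate_with_age()] on the
#'   simulated expression matrix.
#' @param tfsee_differential optional differential table from
#'   [differential_tfsee()].
#' @param gene_universe gene id universe for the age-class metrics.
#' @return list with per-set recovery metrics and, when the differential
#'   table is given, 1-based rank positions of the planted TFs in the
#'   delta ordering and in the |delta| ordering.
#' @export
truth_report <- function(ground_truth, age_result = NULL,
                         tfsee_differential = NULL, gene_universe = NULL) {
  out <- list()
  if (!is.null(age_result)) {
    if (is.null(gene_universe)) gene_universe <- age_result$gene_id
    out$age_up <- recovery_metrics(
      ground_truth$age_up_genes,
      age_result$gene_id[age_result$class == "increasing"], gene_universe)
    out$age_down <- recovery_metrics(
      ground_truth$age_down_genes,
      age_result$gene_id[age_result$class == "decreasing"], gene_universe)
  }
  if (!is.null(tfsee_differential)) {
    d <- tfsee_differential
    planted <- c(ground_truth$early_tfs, ground_truth$late_tfs)
    miss <- setdiff(planted, d$tf_id)
    if (length(miss)) stop("planted TFs missing from differential table: ",
                           paste(miss, collapse = ", "))
    abs_rank <- stats::setNames(rank(-abs(d$delta), ties.method = "first"),
                                d$tf_id)
    delta_rank <- stats::setNames(d$rank, d$tf_id)
    out$tf_ranks <- data.frame(
      tf_id = planted,
      program = rep(c("early", "late"),
                    c(length(ground_truth$early_tfs),
                      length(ground_truth$late_tfs))),
      delta = d$delta[match(planted, d$tf_id)],
      rank_by_delta = as.integer(delta_rank[planted]),
      rank_by_abs_delta = as.integer(abs_rank[planted]),
      stringsAsFactors = FALSE)
    out$tf_sign_correct <- all(
      out$tf_ranks$delta[out$tf_ranks$program == "early"] < 0) &&
      all(out$tf_ranks$delta[out$tf_ranks$program == "late"] > 0)
  }
  out
}
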