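#' Run the end-to-end analysis pipeline
#'
#' Orchestrates the stages simulate -> universe -> dynamics -> link -> tfsee
#' -> snps over a single output directory. Each stage reads the standard
#' files earlier stages wrote, so any suffix of the chain can be re-run
#' against an existing directory. A JSON run manifest records the config,
#' input checksums and per-stage status; identical config + seed reproduce
#' byte-identical outputs.
#'
#' @param out_dir working/output directory.
#' @param sim_config a [simulation_config()] (used by the simulate stage).
#' @param stages ordered subset of
#'   `c("simulate", "universe", "dynamics", "link", "tfsee", "snps")`.
#' @param rpkm_threshold,min_samples,min_gap_bp universe filter settings.
#' @param r_threshold,alpha dynamics settings.
#' @param top_k TFSEE motif cap.
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, sim_config = simulation_config(),
                         stages = c("simulate", "universe", "dynamics",
                                    "link", "tfsee", "snps"),
                         rpkm_threshold = 2, min_samples = 1,
                         min_gap_bp = 5000, r_threshold = 0.7, alpha = 0.05,
                         top_k = 20) {
  all_stages <- c("simulate", "universe", "dynamics", "link", "tfsee", "snps")
  stages <- all_stages[all_stages %in% stages]
  if (length(stages) == 0) stop("no valid stage requested")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    config = list(rpkm_threshold = rpkm_threshold, min_samples = min_samples,
                  min_gap_bp = min_gap_bp, r_threshold = r_threshold,
                  alpha = alpha, top_k = top_k,
                  seed = sim_config$seed,
                  sim_config = unclass(sim_config)),
    package_version = as.character(utils::packageVersion("gestenh")),
    stages = list(), input_checksums = list())
  need_file <- function(path, producer) {
    if (!file.exists(path))
      stop("missing input ", basename(path), "; run the '", producer,
           "' stage first")
    path
  }
  t0 <- Sys.time()
  for (stage in stages) {
    started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    status <- "ok"
    tryCatch({
      switch(stage,
        simulate = {
          simulate_dataset(sim_config, out_dir = out_dir)
        },
        universe = {
          samples <- read_sample_sheet(need_file(
            file.path(out_dir, "samples.tsv"), "simulate"))
          genes <- read_gene_annotation(need_file(
            file.path(out_dir, "genes.bed"), "simulate"))
          tre_files <- file.path(out_dir, "tre_calls",
                                 paste0(samples$sample_id, ".bed"))
          lapply(tre_files, need_file, producer = "simulate")
          tre_sets <- lapply(tre_files, read_bed)
          counts <- read_matrix(need_file(
            file.path(out_dir, "erna_counts.tsv"), "simulate"))
          counts <- reindex_samples(counts, samples)
          libs <- utils::read.delim(need_file(
            file.path(out_dir, "library_sizes.tsv"), "simulate"))
          lib <- stats::setNames(libs$library_size, libs$sample_id)
          uni <- enhancer_universe(tre_sets, genes, counts,
                                   library_sizes = lib,
                                   rpkm_threshold = rpkm_threshold,
                                   min_samples = min_samples,
                                   min_gap_bp = min_gap_bp)
          write_bed(uni$enhancers, file.path(out_dir, "universe.bed"))
          write_matrix(uni$rpkm, file.path(out_dir, "universe_rpkm.tsv"),
                       id_col = "enhancer_id")
          jsonlite::write_json(uni$provenance,
                               file.path(out_dir, "universe_provenance.json"),
                               auto_unbox = TRUE, pretty = TRUE)
        },
        dynamics = {
          samples <- read_sample_sheet(need_file(
            file.path(out_dir, "samples.tsv"), "simulate"))
          expr <- reindex_samples(read_matrix(need_file(
            file.path(out_dir, "gene_fpkm.tsv"), "simulate"),
            units = "RPKM"), samples)
          ac <- correlate_with_age(expr, samples, r_threshold = r_threshold,
                                   alpha = alpha)
          write_table(ac, file.path(out_dir, "age_correlation.tsv"))
          tri <- split(samples$sample_id, samples$trimester)
          for (pr in list(c("I", "II"), c("I", "III"), c("II", "III"))) {
            tab <- pairwise_differential(expr, tri[[pr[1]]], tri[[pr[2]]],
                                         alpha = alpha)
            write_table(tab, file.path(
              out_dir, sprintf("differential_%s_vs_%s.tsv", pr[1], pr[2])))
          }
          tr <- epoch_trends(expr, samples)
          write_table(tr$summary, file.path(out_dir, "epoch_trends.tsv"))
        },
        link = {
          samples <- read_sample_sheet(need_file(
            file.path(out_dir, "samples.tsv"), "simulate"))
          genes <- read_gene_annotation(need_file(
            file.path(out_dir, "genes.bed"), "simulate"))
          universe <- read_bed(need_file(file.path(out_dir, "universe.bed"),
                                         "universe"))
          links <- nearest_gene(universe, genes)
          write_table(links, file.path(out_dir, "links.tsv"))
          write_table(enhancers_per_gene(links),
                      file.path(out_dir, "enhancers_per_gene.tsv"))
          rpkm <- reindex_samples(read_matrix(need_file(
            file.path(out_dir, "universe_rpkm.tsv"), "universe"),
            units = "RPKM"), samples)
          expr <- reindex_samples(read_matrix(need_file(
            file.path(out_dir, "gene_fpkm.tsv"), "simulate"),
            units = "RPKM"), samples)
          pairs <- links[links$linked, c("enhancer_id", "gene_id")]
          corr <- enhancer_gene_correlation(rpkm, expr, pairs)
          write_table(corr, file.path(out_dir, "enh_gene_correlation.tsv"))
        },
        tfsee = {
          samples <- read_sample_sheet(need_file(
            file.path(out_dir, "samples.tsv"), "simulate"))
          rpkm <- reindex_samples(read_matrix(need_file(
            file.path(out_dir, "universe_rpkm.tsv"), "universe"),
            units = "RPKM"), samples)
          k27 <- reindex_samples(read_matrix(need_file(
            file.path(out_dir, "k27ac.tsv"), "simulate")), samples)
          k4 <- reindex_samples(read_matrix(need_file(
            file.path(out_dir, "k4me1.tsv"), "simulate")), samples)
          k27 <- k27[rownames(rpkm), , drop = FALSE]
          k4 <- k4[rownames(rpkm), , drop = FALSE]
          tf_expr <- reindex_samples(read_matrix(need_file(
            file.path(out_dir, "tf_expr.tsv"), "simulate")), samples)
          hits <- utils::read.delim(need_file(
            file.path(out_dir, "motif_hits.tsv"), "simulate"),
            stringsAsFactors = FALSE)
          hits <- hits[hits$enhancer_id %in% rownames(rpkm), , drop = FALSE]
          fit <- tfsee(rpkm, k27, k4, hits, tf_expr, samples, top_k = top_k,
                       alpha = alpha)
          write_matrix(t(fit$scores), file.path(out_dir, "tfsee_scores.tsv"),
                       id_col = "tf_id")
          write_table(fit$differential,
                      file.path(out_dir, "differential_tfsee.tsv"))
          hc <- fit$clustering$hclust
          jsonlite::write_json(
            list(merge = apply(hc$merge, 1, as.list),
                 height = hc$height, labels = hc$labels,
                 leaf_order = fit$clustering$order,
                 clades = as.list(fit$clustering$clades)),
            file.path(out_dir, "linkage.json"), auto_unbox = TRUE,
            pretty = TRUE, digits = NA)
        },
        snps = {
          catalog <- read_snp_catalog(need_file(
            file.path(out_dir, "snp_catalog.tsv"), "simulate"))
          universe <- read_bed(need_file(file.path(out_dir, "universe.bed"),
                                         "universe"))
          genes <- read_gene_annotation(need_file(
            file.path(out_dir, "genes.bed"), "simulate"))
          genome_size <- sim_config$n_chromosomes * sim_config$chrom_length_bp
          gene_regions <- genomic_intervals(genes$chrom, genes$start,
                                            genes$end, id = genes$gene_id)
          dens <- snp_density(catalog,
                              list(enhancers = universe,
                                   genes = gene_regions), genome_size)
          write_table(as.data.frame(dens),
                      file.path(out_dir, "snp_density.tsv"))
          ann <- annotate_snps_in_regions(catalog, universe)
          write_table(ann[ann$contained, , drop = FALSE],
                      file.path(out_dir, "snps_in_enhancers.tsv"))
        })
    }, error = function(e) {
      status <<- paste0("failed: ", conditionMessage(e))
    })
    manifest$stages[[stage]] <- list(started = started, status = status)
    if (status != "ok") {
      manifest$failed_at <- stage
      write_manifest(manifest, out_dir)
      stop("pipeline stage '", stage, "' failed: ", sub("^failed: ", "", status))
    }
  }
  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  write_manifest(manifest, out_dir)
  invisible(manifest)
}

# matrices are reindexed to the sample sheet's column order on load; the
# sheet is the sample-ordering authority
reindex_samples <- function(m, samples) {
  miss <- setdiff(samples$sample_id, colnames(m))
  if (length(miss)) stop("matrix lacks samples from the sample sheet: ",
                         miss[1])
  m[, samples$sample_id, drop = FALSE]
}

write_manifest <- function(manifest, out_dir) {
  inputs <- list.files(out_dir, pattern = "\\.(tsv|bed)$", full.names = TRUE)
  sums <- tools::md5sum(inputs)
  manifest$input_checksums <- as.list(stats::setNames(unname(sums),
                                                      basename(inputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
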