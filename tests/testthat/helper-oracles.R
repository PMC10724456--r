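# Brute-force reference implementations used as independent oracles.
# Each works on a base-pair or element-wise representation, deliberately
# ignorant of the interval algebra the package uses.

# union of covered bases -> maximal runs (0-based half-open), adjacency merges
oracle_merge <- function(intervals) {
  out <- list()
  for (chr in sort(unique(intervals$chrom))) {
    sub <- intervals[intervals$chrom == chr, , drop = FALSE]
    covered <- rep(FALSE, max(sub$end) + 1)
    for (i in seq_len(nrow(sub)))
      covered[(sub$start[i] + 1):(sub$end[i])] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    if (length(keep))
      out[[chr]] <- data.frame(chrom = chr, start = starts[keep] - 1,
                               end = ends[keep], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# pairwise gap: 0 on overlap, else bases strictly between nearest edges
oracle_gap <- function(s1, e1, s2, e2) {
  if (e1 <= s2) s2 - e1 else if (e2 <= s1) s1 - e2 else 0
}

oracle_filter_distal <- function(enh, genes, min_gap = 5000) {
  keep <- vapply(seq_len(nrow(enh)), function(i) {
    g <- genes[genes$chrom == enh$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return(TRUE)
    gaps <- vapply(seq_len(nrow(g)), function(j)
      oracle_gap(enh$start[i], enh$end[i], g$start[j], g$end[j]), numeric(1))
    all(gaps > min_gap)
  }, logical(1))
  enh[keep, , drop = FALSE]
}

oracle_nearest_tss <- function(enh, genes) {
  vapply(seq_len(nrow(enh)), function(i) {
    g <- genes[genes$chrom == enh$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return(NA_character_)
    gaps <- vapply(seq_len(nrow(g)), function(j)
      oracle_gap(enh$start[i], enh$end[i], g$tss[j], g$tss[j] + 1),
      numeric(1))
    cand <- g$gene_id[gaps == min(gaps)]
    sort(cand)[1]
  }, character(1))
}

# textbook step-up BH, computed on the sorted vector then mapped back
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, m * p[o] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# exhaustive hypergeometric upper tail by enumerating all draws of B
oracle_hyper_enum <- function(universe, A, B_size, k_obs) {
  draws <- utils::combn(universe, B_size, simplify = FALSE)
  mean(vapply(draws, function(B) length(intersect(A, B)) >= k_obs,
              logical(1)))
}

# per-SNP containment by scanning every region
oracle_contain <- function(catalog, regions) {
  vapply(seq_len(nrow(catalog)), function(i) {
    hit <- which(regions$chrom == catalog$chrom[i] &
                   regions$start <= catalog$pos[i] &
                   catalog$pos[i] < regions$end)
    if (length(hit)) regions$id[hit[1]] else NA_character_
  }, character(1))
}

random_intervals <- function(n, chroms = c("chrA", "chrB"), max_bp = 5000,
                             max_len = 400) {
  start <- sample.int(max_bp, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + len, stringsAsFactors = FALSE)
}

make_test_genes <- function(chrom, start, end, strand, gene_id) {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             gene_id = gene_id, tss = ifelse(strand == "+", start, end - 1),
             stringsAsFactors = FALSE)
}

# small fast generator settings shared across tests
tiny_config <- function(seed = 1, ...) {
  simulation_config(n_chromosomes = 2, chrom_length_bp = 2e6, n_genes = 100,
                    n_enhancers = 60, n_samples_per_trimester = 4,
                    n_tfs_decoy = 10, n_snps = 2000, n_decoy_tres = 20,
                    seed = seed, ...)
}
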