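test_that("interval merge unions overlapping and bookended calls", {
  expect_equal(nrow(merge_intervals(list())), 0)
  iv <- genomic_intervals(rep("chr1", 3), c(0, 50, 200), c(100, 150, 300))
  m <- merge_intervals(iv)
  expect_equal(m$start, c(0, 200))
  expect_equal(m$end, c(150, 300))
  expect_equal(m$id, c("chr1:0-150", "chr1:200-300"))
  # bookended (gap 0) merges; gap 1 does not
  book <- genomic_intervals(c("chr1", "chr1"), c(0, 100), c(100, 200))
  expect_equal(merge_intervals(book)$end, 200)
  apart <- genomic_intervals(c("chr1", "chr1"), c(0, 101), c(100, 200))
  expect_equal(nrow(merge_intervals(apart)), 2)
})

test_that("interval merge equals the base-coverage oracle on random sets", {
  set.seed(42)
  for (rep in 1:20) {
    iv <- random_intervals(sample(2:40, 1))
    iv$strand <- "*"; iv$id <- sprintf("x%d", seq_len(nrow(iv)))
    got <- merge_intervals(iv)
    want <- oracle_merge(iv)
    expect_equal(got[, c("chrom", "start", "end")], want,
                 ignore_attr = TRUE)
  }
})

test_that("distal filter keeps only elements > min gap from any gene span", {
  genes <- make_test_genes("chr1", 10000, 20000, "+", "g1")
  kept <- genomic_intervals("chr1", 26000, 26500)      # gap 6000
  removed <- genomic_intervals("chr1", 24000, 24500)   # gap 4000
  inside <- genomic_intervals("chr1", 15000, 15200)    # overlap, gap 0
  boundary <- genomic_intervals("chr1", 25000, 25400)  # gap exactly 5000
  expect_equal(nrow(filter_distal(kept, genes)), 1)
  expect_equal(nrow(filter_distal(removed, genes)), 0)
  expect_equal(nrow(filter_distal(inside, genes)), 0)
  expect_equal(nrow(filter_distal(boundary, genes)), 0)  # strict > 5 kb
  expect_error(filter_distal(kept, genes[0, ]), "empty gene set")
})

test_that("distal filter equals the all-pairs gap oracle on random sets", {
  set.seed(7)
  for (rep in 1:10) {
    genes <- random_intervals(30, max_bp = 50000, max_len = 3000)
    genes$gene_id <- sprintf("g%d", seq_len(nrow(genes)))
    enh <- random_intervals(80, max_bp = 60000, max_len = 500)
    enh <- genomic_intervals(enh$chrom, enh$start, enh$end,
                             id = sprintf("e%d", seq_len(nrow(enh))))
    got <- filter_distal(enh, genes, min_gap_bp = 2000)
    want <- oracle_filter_distal(enh, genes, min_gap = 2000)
    expect_equal(got$id, want$id)
  }
})

test_that("distal filter warns on disjoint chromosome namespaces", {
  genes <- make_test_genes("chr1", 0, 1000, "+", "g1")
  enh <- genomic_intervals("1", 50000, 50100)
  expect_warning(filter_distal(enh, genes), "no chromosome names")
})

test_that("RPKM follows counts / (kb * millions of reads)", {
  counts <- matrix(c(10, 0, 4), nrow = 3,
                   dimnames = list(c("a", "b", "c"), "s1"))
  r <- compute_rpkm(counts, lengths = c(a = 500, b = 500, c = 1000),
                    library_sizes = c(s1 = 1e6))
  expect_equal(unname(r["a", 1]), 20)
  expect_equal(unname(r["b", 1]), 0)
  r2 <- compute_rpkm(counts, c(a = 500, b = 500, c = 1000), c(s1 = 2e6))
  expect_equal(unname(r2["c", 1]), 2)
  expect_error(compute_rpkm(counts, c(a = 500, b = 500, c = 1000),
                            c(s1 = 0)), "positive")
})

test_that("universe expression filter is inclusive and row-wise", {
  enh <- genomic_intervals(rep("chr1", 3), c(0, 1000, 2000),
                           c(500, 1500, 2500), id = c("e1", "e2", "e3"))
  rpkm <- matrix(c(2.5, 0, 1.9, 1.9, 0, 3.0), nrow = 3, byrow = TRUE,
                 dimnames = list(c("e1", "e2", "e3"), c("s1", "s2")))
  u <- build_universe(enh, rpkm, rpkm_threshold = 2, min_samples = 1)
  expect_equal(u$enhancers$id, c("e1", "e3"))
  # exactly at the threshold is retained (">= 2" is inclusive)
  rpkm2 <- matrix(2.0, 1, 1, dimnames = list("e1", "s1"))
  u2 <- build_universe(enh[1, ], rpkm2)
  expect_equal(nrow(u2$enhancers), 1)
  expect_warning(build_universe(enh[1, ], rpkm2 * 0.5), "empty universe")
  expect_error(build_universe(enh[1, ], rpkm2, rpkm_threshold = 0), "positive")
})

test_that("raising the RPKM threshold never adds enhancers", {
  set.seed(11)
  enh <- genomic_intervals(rep("chr1", 50), (0:49) * 1000, (0:49) * 1000 + 500)
  rpkm <- matrix(stats::rexp(50 * 6, rate = 0.3), nrow = 50,
                 dimnames = list(enh$id, paste0("s", 1:6)))
  prev <- Inf
  for (thr in c(0.5, 1, 2, 4, 8)) {
    n <- tryCatch(nrow(suppressWarnings(
      build_universe(enh, rpkm, rpkm_threshold = thr))$enhancers),
      error = function(e) 0)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("region overlap accounting is consistent", {
  A <- genomic_intervals(c("chr1", "chr1"), c(0, 20), c(10, 30))
  B <- genomic_intervals("chr1", 5, 6)
  s <- region_overlap_summary(A, B)
  expect_equal(s$n_A_overlapping_B, 1)
  expect_equal(s$n_A_unique, 1)
  expect_equal(s$n_A, s$n_A_overlapping_B + s$n_A_unique)
  expect_equal(region_overlap_summary(A, A)$n_A_unique, 0)
  expect_equal(region_overlap_summary(A, B[0, ])$n_A_unique, 2)
})

test_that("universe construction on synthetic data keeps exactly the planted distal enhancers", {
  sim <- simulate_dataset(tiny_config(seed = 3))
  uni <- enhancer_universe(sim$tre_sets, sim$genes, sim$counts_erna,
                           library_sizes = sim$library_sizes)
  # which planted enhancers are expressed above threshold, from the matrix
  feats <- rbind(sim$enhancers[, c("start", "end", "id")],
                 sim$decoy_tres[, c("start", "end", "id")])
  lens <- stats::setNames(feats$end - feats$start, feats$id)
  rpkm <- compute_rpkm(sim$counts_erna, lens[rownames(sim$counts_erna)],
                       sim$library_sizes)
  expressed <- rownames(rpkm)[rowSums(rpkm >= 2) >= 1]
  want <- sort(intersect(sim$enhancers$id, expressed))
  expect_equal(sort(uni$enhancers$id), want)
  # every promoter-proximal decoy was removed
  expect_length(intersect(uni$enhancers$id,
                          sim$ground_truth$decoy_tre_ids), 0)
})
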