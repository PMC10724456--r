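test_that("min-max normalization maps slices to [0,1] with zero-range to zeros", {
  m <- matrix(c(1, 3, 5, 2, 2, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  n <- minmax_normalize(m, "feature")
  expect_equal(unname(n["a", ]), c(0, 0.5, 1))
  expect_equal(unname(n["b", ]), c(0, 0, 0))
  set.seed(3)
  r <- matrix(rnorm(40), 5)
  nr <- minmax_normalize(r, "feature")
  expect_equal(unname(apply(nr, 1, min)), rep(0, 5))
  expect_equal(unname(apply(nr, 1, max)), rep(1, 5))
  expect_error(minmax_normalize(matrix(c(1, NA), 1)), "finite")
})

test_that("enhancer activity follows the eRNA-gated mark average", {
  dn <- list("e1", c("s1", "s2"))
  erna <- matrix(c(0, 4), 1, dimnames = dn)
  k27 <- matrix(c(2, 2), 1, dimnames = dn)
  k4 <- matrix(c(0, 10), 1, dimnames = dn)
  a <- enhancer_activity(erna, k27, k4)
  # N(eRNA)=(0,1); N(k27) constant -> zeros; N(k4)=(0,1) => A=(0, 0.5)
  expect_equal(unname(a[1, ]), c(0, 0.5))
  # sample at its per-enhancer max in eRNA and both marks scores 1
  dn2 <- list(c("e1", "e2"), c("s1", "s2"))
  up <- matrix(c(1, 5, 2, 9), 2, dimnames = dn2)
  a2 <- enhancer_activity(up, up, up)
  expect_equal(unname(a2[, "s2"]), c(1, 1))
  expect_equal(unname(a2[, "s1"]), c(0, 0))  # eRNA at min forces 0
  bad <- up; rownames(bad) <- c("e1", "eX")
  expect_error(enhancer_activity(up, bad, up), "identical")
})

test_that("motif matrix keeps the strongest top-k hits and scales per TF", {
  hits <- data.frame(enhancer_id = "e1", tf_id = "t1", motif_id = "m1",
                     match_p = 1e-8)
  M <- build_motif_matrix(hits, enhancer_ids = c("e1", "e2"),
                          tf_ids = c("t1", "t2"))
  expect_equal(M["e1", "t1"], 1)
  expect_equal(sum(M), 1)
  # 25 hits in one enhancer: exactly 20 retained, the 5 weakest dropped
  hits25 <- data.frame(enhancer_id = "e1",
                       tf_id = sprintf("t%02d", 1:25),
                       motif_id = sprintf("m%02d", 1:25),
                       match_p = 10^-(30:6))
  M25 <- build_motif_matrix(hits25, "e1", sprintf("t%02d", 1:25), top_k = 20)
  expect_equal(sum(M25 > 0), 20)
  expect_true(all(M25[1, sprintf("t%02d", 21:25)] == 0))  # weakest p dropped
  # equal-strength ties within the cap both retained
  tie <- data.frame(enhancer_id = "e1", tf_id = c("ta", "tb"),
                    motif_id = c("m1", "m2"), match_p = c(1e-5, 1e-5))
  Mt <- build_motif_matrix(tie, "e1", c("ta", "tb"), top_k = 20)
  expect_true(all(Mt["e1", ] > 0))
  expect_error(build_motif_matrix(hits, "e1", "tX"), "unknown tf_id")
})

test_that("TFSEE scores reproduce the worked matrix-product example", {
  # 1 enhancer, 1 TF, 2 samples
  A1 <- matrix(c(0, 1), 1, dimnames = list("e1", c("s1", "s2")))
  M1 <- matrix(1, 1, 1, dimnames = list("e1", "t1"))
  E1 <- matrix(c(0, 5), 1, dimnames = list("t1", c("s1", "s2")))
  S1 <- tfsee_scores(A1, M1, E1)
  expect_equal(unname(S1[, "t1"]), c(0, 1))
  # 2x2 worked case (A rows = samples in the hand computation)
  A <- t(matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("e1", "e2"))))
  M <- matrix(c(1, 0, 1, 1), 2, byrow = TRUE,
              dimnames = list(c("e1", "e2"), c("t1", "t2")))
  E <- t(matrix(c(2, 1, 4, 3), 2, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("t1", "t2"))))
  S <- tfsee_scores(A, M, E)
  expect_equal(unname(S), matrix(c(0, 1, 0, 1), 2),
               tolerance = 1e-12)
  # zero-expression TF scores zero everywhere
  E0 <- E; E0["t2", ] <- 0
  expect_equal(unname(tfsee_scores(A, M, E0)[, "t2"]), c(0, 0))
  expect_error(tfsee_scores(A, M, E[, 1, drop = FALSE]), "sample indices")
})

test_that("TFSEE scores are invariant to rescaling one enhancer's eRNA row", {
  set.seed(41)
  dn <- list(paste0("e", 1:6), paste0("s", 1:5))
  erna <- matrix(rexp(30), 6, dimnames = dn)
  k27 <- matrix(rexp(30), 6, dimnames = dn)
  k4 <- matrix(rexp(30), 6, dimnames = dn)
  hits <- data.frame(enhancer_id = rep(paste0("e", 1:6), 2),
                     tf_id = rep(c("t1", "t2"), each = 6),
                     motif_id = paste0("m", 1:12),
                     match_p = 10^-runif(12, 3, 9))
  E <- matrix(rexp(10), 2, dimnames = list(c("t1", "t2"), dn[[2]]))
  M <- build_motif_matrix(hits, dn[[1]], c("t1", "t2"))
  S <- tfsee_scores(enhancer_activity(erna, k27, k4), M, E)
  erna2 <- erna; erna2["e3", ] <- erna2["e3", ] * 57.3
  S2 <- tfsee_scores(enhancer_activity(erna2, k27, k4), M, E)
  expect_equal(S, S2, tolerance = 1e-12)
})

test_that("sample clustering is UPGMA on 1 - Pearson distance", {
  # duplicated sample merges first at height 0
  S <- rbind(s1 = c(1, 2, 3, 1), s2 = c(1, 2, 3, 1), s3 = c(3, 1, 0, 5),
             s4 = c(3.1, 1, 0, 5.2))
  cl <- cluster_samples(S)
  expect_equal(sort(cl$hclust$labels[-cl$hclust$merge[1, ]]), c("s1", "s2"))
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)
  # two well-separated pairs: root cut recovers the pairs
  expect_equal(unname(cl$clades), c(1, 1, 2, 2))
  # 3-leaf manual UPGMA arithmetic
  S3 <- rbind(a = c(1, 2, 4), b = c(1, 2, 5), c = c(5, 1, 0))
  d <- 1 - cor(t(S3))
  cl3 <- cluster_samples(S3)
  expect_equal(cl3$hclust$height[1], d["a", "b"], tolerance = 1e-12)
  expect_equal(cl3$hclust$height[2],
               mean(c(d["a", "c"], d["b", "c"])), tolerance = 1e-12)
  Sc <- rbind(s1 = c(1, 1, 1), s2 = c(1, 2, 3))
  expect_error(cluster_samples(Sc), "constant score vector.*s1")
})

test_that("differential TFSEE is antisymmetric and null on label permutations", {
  set.seed(47)
  S <- matrix(runif(8 * 5), 8, dimnames = list(paste0("s", 1:8),
                                               paste0("t", 1:5)))
  early <- paste0("s", 1:4); late <- paste0("s", 5:8)
  d <- differential_tfsee(S, early, late)
  expect_equal(d$rank, seq_len(5))
  expect_false(is.unsorted(d$delta))
  swap <- differential_tfsee(S, late, early)
  expect_equal(swap$delta[match(d$tf_id, swap$tf_id)], -d$delta)
  # identical groups via duplicated values
  S2 <- rbind(S[1:4, ], S[1:4, ])
  rownames(S2) <- paste0("s", 1:8)
  d2 <- differential_tfsee(S2, paste0("s", 1:4), paste0("s", 5:8))
  expect_equal(d2$delta, rep(0, 5))
  expect_equal(d2$p_value, rep(1, 5))
  expect_error(differential_tfsee(S, early, c(early[1], late)), "overlap")
})

test_that("the tfsee fit recovers the planted programs on synthetic data", {
  sim <- simulate_dataset(tiny_config(seed = 2))
  uni <- enhancer_universe(sim$tre_sets, sim$genes, sim$counts_erna,
                           library_sizes = sim$library_sizes)
  ids <- rownames(uni$rpkm)
  fit <- tfsee(uni$rpkm, sim$k27ac[ids, ], sim$k4me1[ids, ],
               sim$motif_hits, sim$tf_expr, sim$samples)
  expect_s3_class(fit, "tfsee")
  expect_true(all(fit$scores >= 0 & fit$scores <= 1))
  rep <- truth_report(sim$ground_truth, tfsee_differential = fit$differential)
  expect_true(rep$tf_sign_correct)
  out <- capture.output(print(fit))
  expect_match(out[1], "TFSEE fit")
  s <- summary(fit)
  expect_s3_class(s, "summary.tfsee")
})
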