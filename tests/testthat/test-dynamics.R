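test_that("size factors are median ratios to per-feature geometric means", {
  m <- matrix(c(4, 8, 1, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  sf <- size_factors(m)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(unname(sf[1]), 1 / sqrt(2))
  # identical libraries
  m2 <- matrix(rep(c(3, 7, 11), 4), nrow = 3,
               dimnames = list(letters[1:3], paste0("s", 1:4)))
  expect_equal(unname(size_factors(m2)), rep(1, 4))
  # elementwise doubling doubles the ratio
  m3 <- cbind(s1 = c(5, 9), s2 = c(10, 18))
  rownames(m3) <- c("a", "b")
  sf3 <- size_factors(m3)
  expect_equal(unname(sf3["s2"] / sf3["s1"]), 2)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2,
                                   dimnames = list(c("a", "b"), c("x", "y")))),
               "no feature")
})

test_that("size factors are relative: global scaling cancels, per-library scaling shows", {
  set.seed(5)
  m <- matrix(rpois(60, 50) + 1, nrow = 10,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  # a common constant across all libraries cancels in the geometric mean
  expect_equal(size_factors(m * 3), size_factors(m))
  # scaling one library by c scales its factor ratio to any other by c
  m2 <- m; m2[, "s1"] <- m2[, "s1"] * 5
  sf <- size_factors(m); sf2 <- size_factors(m2)
  expect_equal(unname(sf2["s1"] / sf2["s2"]), unname(5 * sf["s1"] / sf["s2"]))
})

test_that("size factors agree with the DESeq reference estimator", {
  set.seed(9)
  m <- matrix(rnbinom(200 * 8, mu = 100, size = 10) + 1, nrow = 200,
              dimnames = list(paste0("f", 1:200), paste0("s", 1:8)))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(size_factors(m)), unname(ref), tolerance = 1e-10)
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
})

test_that("q-values are monotone in p rank and bounded by p from below at the minimum", {
  set.seed(8)
  p <- runif(100)
  q <- bh_adjust(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
  expect_gte(q[which.min(p)], min(p))
})

test_that("age correlation matches the direct covariance formula and classifies", {
  sheet <- data.frame(sample_id = paste0("S", 1:5),
                      gestational_age_weeks = c(8, 12, 20, 30, 39),
                      trimester = c("I", "I", "II", "III", "III"),
                      sex = "F", assays = "rnaseq")
  x <- c(2.0, 3.5, 3.1, 6.0, 7.2)
  expr <- rbind(gene_lin = 1 + 2 * sheet$gestational_age_weeks,
                gene_x = x, gene_const = rep(5, 5))
  colnames(expr) <- sheet$sample_id
  res <- correlate_with_age(expr, sheet)
  expect_equal(res$pearson_r[1], 1, tolerance = 1e-12)
  expect_equal(res$class[1], "increasing")
  a <- sheet$gestational_age_weeks
  r_oracle <- sum((x - mean(x)) * (a - mean(a))) /
    sqrt(sum((x - mean(x))^2) * sum((a - mean(a))^2))
  expect_equal(res$pearson_r[2], r_oracle, tolerance = 1e-12)
  expect_false(res$tested[3])
  expect_equal(res$class[3], "unclassified")
  expect_equal(attr(res, "m_tested"), 2)  # constant gene excluded from m
  sheet2 <- sheet; sheet2$gestational_age_weeks <- rep(c(8, 39), c(3, 2))
  sheet2$trimester <- trimester_of(sheet2$gestational_age_weeks)
  expect_error(correlate_with_age(expr, sheet2), "3 distinct")
})

test_that("Bonferroni cutoff for 23 000 tested associations is 2.17e-6", {
  expect_equal(signif(bonferroni_cutoff(0.05, 23000), 3), 2.17e-6)
})

test_that("pairwise differential testing is antisymmetric and calibrated on constants", {
  set.seed(13)
  expr <- matrix(rnorm(20 * 8, mean = 50, sd = 3), nrow = 20,
                 dimnames = list(paste0("f", 1:20), paste0("s", 1:8)))
  expr["f1", ] <- 42
  ga <- paste0("s", 1:4); gb <- paste0("s", 5:8)
  tab <- pairwise_differential(expr, ga, gb)
  expect_equal(tab$log2_fc[tab$feature_id == "f1"], 0)
  expect_false(tab$significant[tab$feature_id == "f1"])
  swapped <- pairwise_differential(expr, gb, ga)
  expect_equal(swapped$log2_fc, -tab$log2_fc)
  expect_equal(swapped$p_value, tab$p_value)
  expect_error(pairwise_differential(expr, ga, c(ga[1], gb)), "overlap")
  expect_error(pairwise_differential(expr, ga[1], gb), ">= 2")
})

test_that("a planted 4-fold difference is called at log2FC near 2", {
  set.seed(21)
  base <- matrix(rnorm(30 * 12, 100, 2), nrow = 30,
                 dimnames = list(paste0("f", 1:30), paste0("s", 1:12)))
  base[1:5, 7:12] <- base[1:5, 7:12] * 4
  tab <- pairwise_differential(base, paste0("s", 1:6), paste0("s", 7:12))
  expect_true(all(tab$significant[1:5]))
  expect_equal(tab$log2_fc[1:5], rep(2, 5), tolerance = 0.2)
})

test_that("epoch bins split 36 samples as 8,7,7,7,7 and z-trends track monotone genes", {
  sheet <- data.frame(sample_id = sprintf("S%02d", 1:36),
                      gestational_age_weeks = seq(6, 39, length.out = 36),
                      sex = "F", assays = "rnaseq")
  sheet$trimester <- trimester_of(sheet$gestational_age_weeks)
  bins <- epoch_bins(sheet, 5)
  expect_equal(as.integer(table(bins$bin)), c(8, 7, 7, 7, 7))
  set.seed(2)
  expr <- rbind(up = 1 + sheet$gestational_age_weeks,
                noise = rnorm(36, 10),
                flat = rep(3, 36))
  colnames(expr) <- sheet$sample_id
  expect_warning(epoch_trends(expr, sheet), "constant")
  tr <- suppressWarnings(epoch_trends(expr, sheet))
  expect_equal(rowMeans(tr$z), c(up = 0, noise = 0), tolerance = 1e-12)
  up_by_bin <- vapply(1:5, function(b)
    mean(tr$z["up", tr$bins$sample_id[tr$bins$bin == b]]), numeric(1))
  expect_true(all(diff(up_by_bin) > 0))
})

test_that("signature scores are set means and planted signatures test out", {
  expr <- matrix(1:12, nrow = 3,
                 dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  sc <- signature_score(expr, list(one = "g1", dup = "g1",
                                   both = c("g1", "g2")))
  expect_equal(sc$scores["one", ], expr["g1", ])
  expect_equal(sc$scores["one", ], sc$scores["dup", ])
  expect_equal(sc$scores["both", ], colMeans(expr[c("g1", "g2"), ]))
  expect_error(signature_score(expr, list(bad = "gX")), "'bad'")

  sim <- simulate_dataset(tiny_config(seed = 12))
  tri <- split(sim$samples$sample_id, sim$samples$trimester)
  out <- signature_score(sim$fpkm_gene, sim$ground_truth$signature_sets,
                         groups = list(I = tri$I, III = tri$III))
  st <- out$tests$I_vs_III
  row <- st[st$feature_id == "ST_like", ]
  expect_true(row$significant)
  expect_gte(row$log2_fc, 1)  # >= 2-fold increase at term
})

test_that("delta-delta Ct fold changes follow 2^-ddCt", {
  expect_equal(fold_change_ddct(20, 18, 22, 20), 1)
  expect_equal(fold_change_ddct(20, 18, 21, 20), 2)
  expect_equal(fold_change_ddct(20, 20, 22, 20), 0.25)
})
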