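test_that("qc_filter removes undetected cells and genes", {
  m <- matrix(c(0, 0, 0, 0, 5, 2, 1, 0, 3), 3L, 3L, byrow = TRUE,
              dimnames = list(paste0("c", 1:3), paste0("g", 1:3)))
  f <- qc_filter(m, min_genes_per_cell = 1L, min_cells_per_gene = 1L)
  expect_identical(rownames(f), c("c2", "c3"))
  expect_equal(attr(f, "cells_removed"), 1L)
  # thresholds 0,0 = identity
  expect_equal(unclass(qc_filter(m, 0L, 0L))[, ], m)
  expect_error(qc_filter(m * 0, 1L, 1L), "all cells removed")
  # planted empty cells are removed exactly
  ex <- simulate_expression(n_genes = 300L, n_groups = 2L,
                            cells_per_group = 20L, n_empty_cells = 10L,
                            seed = 31)
  f2 <- qc_filter(ex$counts)
  expect_equal(nrow(ex$counts) - nrow(f2), 10L)
})

test_that("normalization and z-scoring follow their definitions", {
  m <- matrix(c(9999, 1), 1L, 2L,
              dimnames = list("c1", c("g1", "g2")))
  nm <- normalize_log(m)
  expect_equal(nm[1L, 1L], log2(1 + 9999), tolerance = 1e-12)
  expect_error(normalize_log(rbind(m, 0)), "zero total")
  set.seed(37)
  r <- matrix(rpois(600L, 5), 20L, 30L,
              dimnames = list(paste0("c", 1:20), paste0("g", 1:30)))
  z <- zscore_rows(normalize_log(r + 1L))
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 2L, sd) - 1) < 1e-9 |
                    apply(z, 2L, sd) == 0))
  # constant gene -> all-zero z row
  r2 <- cbind(r, const = 7L)
  z2 <- zscore_rows(r2)
  expect_true(all(z2[, "const"] == 0))
})

test_that("well-separated blobs are clustered perfectly and stably", {
  set.seed(41)
  centers <- matrix(rnorm(2L * 50L, sd = 3), 2L, 50L)
  m <- do.call(rbind, lapply(1:2, function(g)
    matrix(rnorm(30L * 50L), 30L, 50L) +
      matrix(centers[g, ], 30L, 50L, byrow = TRUE)))
  dimnames(m) <- list(paste0("c", 1:60), paste0("g", 1:50))
  cl <- cluster_cells(m, k_range = 2:5, n_bootstrap = 20L, seed = 41,
                      n_var_genes = 50L)
  expect_equal(cl$k, 2L)
  expect_true(cl$stable)
  truth <- rep(1:2, each = 30L)
  expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1)
  # labels invariant to cell permutation (up to relabeling)
  perm <- sample(60L)
  cl2 <- cluster_cells(m[perm, ], k_range = 2:5, n_bootstrap = 20L,
                       seed = 41, n_var_genes = 50L)
  expect_equal(mclust::adjustedRandIndex(cl2$labels, truth[perm]), 1)
  expect_error(cluster_cells(m, k_range = 2:60), "k_range")
})

test_that("a homogeneous blob is flagged as having no stable structure", {
  set.seed(42)
  m <- matrix(rnorm(60L * 80L), 60L, 80L,
              dimnames = list(paste0("c", 1:60), paste0("g", 1:80)))
  cl <- cluster_cells(m, k_range = 2:6, n_bootstrap = 20L, seed = 1,
                      n_var_genes = 80L)
  expect_false(cl$stable)
  expect_true(max(cl$stability) < 0.5)
})

test_that("rank_genes matches exact enumeration and calls by threshold", {
  m <- matrix(0, 6L, 3L, dimnames = list(paste0("c", 1:6),
                                         c("flat", "up", "down")))
  m[, "flat"] <- 2
  m[4:6, "up"] <- 8
  m[1:3, "down"] <- 8
  r <- rank_genes(m, cells_a = 1:3, cells_b = 4:6)
  flat <- r[r$gene == "flat", ]
  expect_equal(flat$log2_fc, 0)
  expect_equal(flat$p, 1)
  expect_identical(flat$call, "ns")
  up <- r[r$gene == "up", ]
  expect_equal(up$p, 0.1)                     # exact floor for 3 vs 3
  expect_equal(up$p, ranksum_brute(m[1:3, "up"], m[4:6, "up"]))
  expect_gt(up$log2_fc, 1)
  expect_identical(up$call, "ns")             # 0.1 cannot clear FDR 0.05
  expect_lt(r[r$gene == "down", "log2_fc"], -1)
  expect_error(rank_genes(m, 1:2, 3:6), ">= 3 cells")
})

test_that("rank_genes is calibrated under the null", {
  set.seed(59)
  m <- matrix(rnbinom(60L * 2000L, size = 2.5, mu = 20), 60L, 2000L,
              dimnames = list(paste0("c", 1:60), paste0("g", 1:2000)))
  nm <- normalize_log(qc_filter(m))
  r <- rank_genes(nm, cells_a = 1:30, cells_b = 31:60)
  frac <- mean(r$p < 0.05)
  expect_gte(frac, 0.035)
  expect_lte(frac, 0.065)
})

test_that("the running-sum score matches hand enumeration and its bounds", {
  stats <- setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  es <- gsea_es(stats, c("g1", "g3"), weight = 0)
  expect_equal(es$running, c(0.5, 0.5 - 1/3, 0.5 - 1/3 + 0.5,
                             2/3 - 1/3, 0), tolerance = 1e-12)
  expect_equal(es$es, 2/3, tolerance = 1e-12)
  # signature = top genes -> ES exactly 1
  expect_equal(gsea_es(stats, c("g1", "g2"), weight = 0)$es, 1)
  # running sum conservation at weight 0, |ES| <= 1, reversal flips sign
  set.seed(61)
  for (i in 1:25) {
    s <- setNames(sample(seq(-3, 3, length.out = 40L)), paste0("x", 1:40))
    sig <- sample(names(s), sample(2:10, 1L))
    e <- gsea_es(s, sig, weight = 0)
    expect_lt(abs(e$running[40L]), 1e-12)
    expect_lte(abs(e$es), 1)
    rev_s <- setNames(-s, names(s))
    e_rev <- gsea_es(rev_s, sig, weight = 0)$es
    expect_equal(abs(e_rev), abs(e$es), tolerance = 1e-12)
    run <- e$running
    if (abs(max(run) + min(run)) > 1e-9) {   # sign is tie-free
      expect_equal(e_rev, -e$es, tolerance = 1e-12)
    }
  }
  expect_error(gsea_es(stats, c("zz")), "not represented")
})

test_that("gsea agrees with an established implementation", {
  skip_if_not_installed("fgsea")
  set.seed(67)
  stats <- setNames(rnorm(100L), paste0("g", 1:100))
  sig <- sample(names(stats), 12L)
  es <- gsea_es(stats, sig, weight = 1)$es
  ref <- fgsea::calcGseaStat(sort(stats, decreasing = TRUE),
                             which(names(sort(stats, decreasing = TRUE))
                                   %in% sig), gseaParam = 1)
  expect_equal(es, ref, tolerance = 1e-6)
})

test_that("gsea returns seeded, reproducible permutation statistics", {
  set.seed(5)
  stats <- setNames(rnorm(80L), paste0("g", 1:80))
  sig <- paste0("g", 1:8)
  a <- gsea(stats, sig, n_permutations = 200L, seed = 7)
  b <- gsea(stats, sig, n_permutations = 200L, seed = 7)
  expect_identical(a$null_es, b$null_es)
  expect_true(a$p > 0 && a$p <= 1)
  expect_true(all(a$leading_edge %in% sig))
})

test_that("signature scores are dropout-tolerant where single genes fail", {
  # planted module shift between two conditions
  set.seed(73)
  n <- 25L; genes <- paste0("g", 1:200)
  module <- genes[1:20]
  mu <- rep(30, 200L)
  mk <- function(shift) t(vapply(seq_len(n), function(i) {
    m <- mu; m[1:20] <- m[1:20] * shift
    rnbinom(200L, size = 2.5, mu = m)
  }, numeric(200L)))
  m <- rbind(mk(1.6), mk(1))
  dimnames(m) <- list(paste0("c", 1:(2 * n)), genes)
  # 40% random zero-masking of signature genes per cell
  mask <- matrix(runif(2 * n * 20L) < 0.4, 2 * n, 20L)
  m[, 1:20][mask] <- 0
  nm <- normalize_log(qc_filter(m))
  sc <- score_signature(nm, module)
  p_sig <- wilcox.test(sc$score[1:n], sc$score[(n + 1):(2 * n)])$p.value
  expect_lt(p_sig, 0.01)
  p_gene <- vapply(module, function(g)
    suppressWarnings(wilcox.test(nm[1:n, g],
                                 nm[(n + 1):(2 * n), g])$p.value),
    numeric(1))
  expect_gte(mean(p_gene >= 0.05), 0.5)
})

test_that("signature scoring is invariant to non-signature genes", {
  set.seed(67)
  m <- matrix(rpois(300L, 10), 20L, 15L,
              dimnames = list(paste0("c", 1:20), paste0("g", 1:15)))
  nm <- normalize_log(m)
  sig <- paste0("g", 1:5)
  s1 <- score_signature(nm, sig)
  extra <- cbind(nm, matrix(rnorm(40L, 5), 20L, 2L,
                            dimnames = list(rownames(nm), c("h1", "h2"))))
  s2 <- score_signature(extra, sig)
  expect_equal(s1$score, s2$score)
  # constant gene -> zero contribution
  cm <- cbind(nm[, 1:3], const = 4)
  expect_true(all(score_signature(cm, "const")$score == 0))
  expect_error(score_signature(nm, "absent"), "not represented")
})

test_that("planted condition shift is detected by the signature score", {
  ex <- simulate_expression(n_genes = 600L, n_groups = 2L,
                            cells_per_group = 30L, module_fold = 2,
                            seed = 67)
  nm <- normalize_log(qc_filter(ex$counts))
  sc <- score_signature(nm, ex$modules[[1L]])
  g1 <- ex$annotations$group == "G1"
  expect_gt(mean(sc$score[g1]), mean(sc$score[!g1]))
  expect_lt(wilcox.test(sc$score[g1], sc$score[!g1])$p.value, 0.01)
})

test_that("over-representation follows the hypergeometric tail", {
  uni <- paste0("u", 1:1000)
  sig <- list(s = uni[1:20])
  r <- overrepresentation(uni[1:20], sig, uni)
  expect_equal(r$p, 1 / choose(1000, 20), tolerance = 1e-9)
  expect_lt(r$p, 1e-30)
  r2 <- overrepresentation(uni[21:60], sig, uni)
  expect_equal(r2$p, 1)
  expect_error(overrepresentation(uni[1:5], sig, character(0)), "universe")
  expect_error(overrepresentation("other", sig, uni), "outside")
})

test_that("knockdown targets are called down-regulated at the thresholds", {
  ex <- simulate_expression(n_genes = 800L, n_groups = 2L,
                            cells_per_group = 30L, knockdown_fold = 4,
                            seed = 97)
  nm <- normalize_log(qc_filter(ex$counts))
  tgt <- ex$truth$target_genes[["module_G1"]]
  r <- rank_genes(nm, cells_a = which(ex$annotations$group == "G2"),
                  cells_b = which(ex$annotations$group == "G1"))
  row <- r[r$gene == tgt, ]
  expect_lt(row$log2_fc, -1)
  expect_lt(row$fdr, 0.05)
  expect_identical(row$call, "down")
})
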