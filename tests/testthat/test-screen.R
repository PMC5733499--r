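test_that("demultiplex routes by exact barcode prefix and conserves reads", {
  map <- c(ACT = "s1", GGA = "s2")
  reads <- c("ACTGGGTTTTAAAA", "NNNTACGTACGTAC", "GGACCCCGGGGAAA", "AC")
  dm <- demultiplex(reads, map)
  expect_equal(nrow(dm$samples$s1), 1L)
  expect_identical(dm$samples$s1$seq, "GGGTTTTAAAA")   # barcode trimmed
  expect_equal(nrow(dm$samples$s2), 1L)
  expect_equal(nrow(dm$unassigned), 2L)                # no match + too short
  expect_equal(sum(vapply(dm$samples, nrow, 1L)) + nrow(dm$unassigned),
               length(reads))
  expect_error(demultiplex(reads, character(0)), "empty")
})

test_that("demultiplex recovers planted per-sample counts exactly", {
  set.seed(11)
  bcs <- c(AAA = "w", CCC = "x", GGG = "y", TTT = "z")
  planted <- c(w = 400L, x = 300L, y = 200L, z = 100L)
  reads <- paste0(rep(names(bcs), planted), random_dna(1000L, 40L))
  reads <- reads[sample.int(1000L)]
  dm <- demultiplex(reads, bcs)
  expect_identical(vapply(dm$samples, nrow, 1L)[names(planted)], planted)
  expect_equal(nrow(dm$unassigned), 0L)
})

test_that("count_shrnas counts unique best hits and discards ties", {
  lib <- tiny_library()
  # read = revcomp(guide + 10 nt of downstream scaffold) -> one count for s1
  r1 <- revcomp(hairpin_read(lib, 1L, left = 0L, right = 10L))
  cc <- count_shrnas(r1, lib, max_mismatch = 1L)
  expect_identical(unname(cc$counts), c(1L, 0L, 0L))

  # guides at Hamming distance 2 (positions 14 and 20, so both keep a
  # seed-length clean run): a read midway between them is ambiguous
  g1 <- "ACGTACGTACGTAGGTACGTAC"
  g2 <- "ACGTACGTACGTATGTACGAAC"           # differs at 14 and 20
  lib2 <- shrna_library(data.frame(
    shrna_id = c("a", "b"), gene_symbol = c("GA", "GB"),
    guide_sequence = c(g1, g2), stringsAsFactors = FALSE))
  mid <- "ACGTACGTACGTATGTACGTAC"          # 1 mismatch from each
  cc2 <- count_shrnas(revcomp(mid), lib2, max_mismatch = 1L)
  expect_identical(unname(cc2$counts), c(0L, 0L))
  expect_equal(cc2$ambiguous, 1L)
  expect_equal(cc2$assigned + cc2$ambiguous + cc2$unmatched, cc2$total)
})

test_that("counting recovers planted multinomial abundances from reads", {
  sim <- simulate_screen(n_shrnas = 200L, n_enriched = 0L, n_screens = 1L,
                         n_replicates = 1L, nb_mean = 125, mode = "reads",
                         seed = 3)
  dm <- demultiplex(sim$reads,
                    stats::setNames(sim$samples$sample_id,
                                    sim$samples$barcode))
  total <- sum(vapply(dm$samples, nrow, 1L)) + nrow(dm$unassigned)
  expect_equal(total, nrow(sim$reads))
  for (sid in sim$samples$sample_id) {
    cc <- count_shrnas(dm$samples[[sid]], sim$lib, max_mismatch = 1L)
    expect_gte(cc$assigned / cc$total, 0.95)
    planted <- sim$counts[, sid]
    # recovered counts track planted expectations within Poisson noise
    # (retention < 1 because multi-error reads are dropped)
    retention <- sum(cc$counts) / sum(planted)
    expect_gt(retention, 0.9)
    dev <- abs(cc$counts - retention * planted)
    expect_true(all(dev <= 5 * sqrt(pmax(planted, 1)) + 5))
    expect_gt(cor(cc$counts, planted), 0.99)
  }
})

test_that("TMM factors are 1 under symmetry and match the brute force", {
  cnt <- matrix(rep(c(10L, 50L, 200L, 35L), 2L), 4L, 2L)
  expect_equal(tmm_factors(cnt), c(1, 1))
  # doubled depth, identical composition: M-values all zero
  cnt2 <- cbind(a = c(10L, 50L, 200L, 35L), b = 2L * c(10L, 50L, 200L, 35L))
  f <- tmm_factors(cnt2)
  expect_equal(f[1] / f[2], 1, tolerance = 1e-12)
  expect_error(tmm_factors(cbind(c(0L, 0L), c(1L, 2L))), "zero total")

  set.seed(5)
  base <- rnbinom(500L, size = 5, mu = 200)
  y <- rnbinom(500L, size = 10, mu = base + 1)
  yr <- rnbinom(500L, size = 10, mu = base + 1)
  up <- sample.int(500L, 50L)            # 10% of shRNAs 8-fold enriched in y
  y[up] <- y[up] * 8L
  f2 <- tmm_factors(cbind(y, yr), ref = 2L)
  expect_equal(f2[1] / f2[2], tmm_brute(y, yr), tolerance = 0.03)
})

test_that("TMM agrees with the established implementation on planted data", {
  skip_if_not_installed("edgeR")
  set.seed(5)
  y <- matrix(rnbinom(2000L, size = 5, mu = 150), 500L, 4L)
  y[1:50, 2L] <- y[1:50, 2L] * 6L
  f_pkg <- tmm_factors(y, ref = 1L)
  f_edger <- edgeR::calcNormFactors(y, method = "TMM", refColumn = 1L)
  f_edger <- f_edger / exp(mean(log(f_edger)))
  expect_equal(f_pkg, unname(f_edger), tolerance = 0.03)
})

test_that("NB exact test reduces to the binomial at dispersion zero", {
  expect_equal(nb_exact_test(2L, 8L, 1L, 1L, 0),
               binom.test(8L, 10L, 0.5)$p.value)
  # a grid of splits against binom.test
  for (s in c(10L, 25L)) {
    for (a in 0:s) {
      expect_equal(nb_exact_test(a, s - a, 1L, 1L, 0),
                   binom.test(a, s, 0.5)$p.value, tolerance = 1e-12)
    }
  }
  # equal counts -> p ~ 1, and all-zero rows are flagged
  lib <- tiny_library()
  cnt <- matrix(c(30L, 40L, 0L, 30L, 40L, 0L, 30L, 40L, 0L, 30L, 40L, 0L),
                3L, 4L, dimnames = list(c("s1", "s2", "s3"),
                                        c("a0", "b0", "a37", "b37")))
  samp <- data.frame(sample_id = colnames(cnt), barcode = NA,
                     day = c(0L, 0L, 37L, 37L), replicate = c(1L, 2L, 1L, 2L),
                     screen = 1L)
  res <- test_enrichment(cnt, samp)
  expect_equal(res$log2_fc, c(0, 0, 0))
  expect_true(all(res$p_combined[1:2] > 0.9))
  expect_true(res$all_zero[3L])
  expect_equal(res$p_combined[3L], 1)
})

test_that("fisher_combine matches the closed form and is monotone", {
  expect_equal(fisher_combine(c(1, 1)), 1)
  x <- -2 * sum(log(c(0.05, 0.05)))
  expect_equal(fisher_combine(c(0.05, 0.05)), exp(-x / 2) * (1 + x / 2))
  expect_equal(fisher_combine(c(0.05, 0.05)), 0.01747866, tolerance = 1e-6)
  expect_equal(fisher_combine(c(0.01, 0.5)), 0.03149159, tolerance = 1e-6)
  expect_warning(p0 <- fisher_combine(c(0, 0.5)), "clamped")
  expect_lt(p0, 1e-100)
  # monotone: decreasing any input never increases the combined p
  set.seed(19)
  for (i in 1:50) {
    p <- runif(3)
    j <- sample(3L, 1L)
    p2 <- p; p2[j] <- p[j] * runif(1)
    expect_lte(fisher_combine(p2), fisher_combine(p))
  }
})

test_that("BH adjustment matches hand step-up and dominates p", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_identical(adjust_fdr(numeric(0)), numeric(0))
  set.seed(23)
  p <- runif(40)
  expect_true(all(adjust_fdr(p) >= p))
  expect_equal(adjust_fdr(p), bh_brute(p))
})

test_that("hit calling applies the screen thresholds", {
  lib <- tiny_library()
  res <- data.frame(
    shrna_id = c("s1", "s2", "s3"),
    log2_fc = c(1.5, 1.2, 0.3),
    p_combined = c(0.04, 0.04, 0.01),
    fdr = c(0.20, 0.30, 0.10))
  h <- call_hits(res, lib)
  expect_true(h$shrna_hits$hit[1L])          # p = .04, fdr = .20 -> hit
  expect_false(h$shrna_hits$hit[2L])         # fdr = .30 -> not a hit
  # gene candidate needs >= 2 hit shRNAs with lfc > 1
  res2 <- data.frame(
    shrna_id = c("s1", "s2", "s3"),
    log2_fc = c(1.5, 1.2, 0.3),
    p_combined = c(0.01, 0.01, 0.01),
    fdr = c(0.05, 0.05, 0.05))
  h2 <- call_hits(res2, lib)
  ga <- h2$gene_hits[h2$gene_hits$gene_symbol == "GENEA", ]
  expect_true(ga$candidate)
  expect_equal(ga$n_shrnas_enriched, 2L)
  gb <- h2$gene_hits[h2$gene_hits$gene_symbol == "GENEB", ]
  expect_false(gb$candidate)
})

test_that("planted enrichment is recovered across two screen batches", {
  sim <- simulate_screen(n_shrnas = 400L, n_enriched = 10L, seed = 77)
  res <- test_enrichment(sim$counts, sim$samples)
  h <- call_hits(res, sim$lib)$shrna_hits
  called <- h$shrna_id[h$hit & h$log2_fc > 1]
  tp <- sum(called %in% sim$truth$enriched_ids)
  expect_gte(tp / 10L, 0.9)
  expect_gte(tp / length(called), 0.9)
})
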