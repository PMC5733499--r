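test_that("hairpin calls require scaffold-anchored guide matches", {
  lib <- tiny_library()
  # 15 nt of flank5 + full guide: anchored, counted
  r <- hairpin_read(lib, 1L, left = 15L, right = 0L)
  cc <- call_shrna_reads(r, lib)
  expect_identical(unname(cc$counts), c(1L, 0L, 0L))
  # same guide embedded in random sequence: endogenous-transcript mimic,
  # never counted, but tallied as an unmatched hairpin candidate
  set.seed(2)
  decoy <- paste0(random_dna(1L, 15L), lib$records$guide_sequence[1L],
                  random_dna(1L, 15L))
  cc2 <- call_shrna_reads(decoy, lib)
  expect_identical(sum(cc2$counts), 0L)
  expect_equal(cc2$unmatched_hairpin, 1L)
  # reverse-complement reads are found too
  cc3 <- call_shrna_reads(revcomp(r), lib)
  expect_identical(unname(cc3$counts), c(1L, 0L, 0L))
  # antisense-arm coverage (loop + revcomp(guide) + flank3 window) counts
  ref <- lib$expressed_refs[2L]
  arm2 <- substr(ref, nchar(ref) - 70L, nchar(ref))
  cc4 <- call_shrna_reads(arm2, lib)
  expect_identical(unname(cc4$counts), c(0L, 1L, 0L))
})

test_that("planted hairpin reads are recovered under sequencing error", {
  lib <- simulate_library(20L, seed = 9)
  set.seed(9)
  reads <- mirescreen:::.mutate_reads(
    vapply(1:40, function(i) hairpin_read(lib, 7L,
                                          left = sample(0:15, 1L),
                                          right = sample(12:25, 1L)),
           character(1)), 0.01)
  cc <- call_shrna_reads(reads, lib)
  expect_gte(cc$counts[["sh0007"]], 36L)
  expect_lte(cc$counts[["sh0007"]], 40L)
  expect_identical(sum(cc$counts[-7L]), 0L)
})

test_that("assign_cells encodes the >10-read cutoff", {
  counts <- data.frame(
    cell_id = c("c1", "c2", "c3", "c3"),
    shrna_id = c("s1", "s1", "s1", "s2"),
    reads = c(10L, 11L, 12L, 40L))
  a <- assign_cells(counts, cells = c("c1", "c2", "c3", "c4"))
  expect_identical(a$status, c("none", "single", "multiple", "none"))
  expect_identical(a$shrna_ids[2L], "s1")
  expect_identical(a$shrna_ids[3L], "s2,s1")   # ordered by support
  # raising the threshold never moves a cell away from "none"
  for (thr in c(12L, 20L, 41L)) {
    a2 <- assign_cells(counts, min_reads = thr,
                       cells = c("c1", "c2", "c3", "c4"))
    expect_true(all(a2$status[a$status == "none"] == "none"))
  }
})

test_that("occurrence_summary aggregates assignment structure", {
  a <- assign_cells(data.frame(
    cell_id = c("c2", "c3", "c3"),
    shrna_id = c("s1", "s1", "s2"),
    reads = c(20L, 15L, 30L)), cells = c("c1", "c2", "c3"))
  s <- occurrence_summary(a)
  expect_equal(s$fraction_detected, 2 / 3)
  expect_equal(s$per_shrna_cells[["s1"]], 2L)
  expect_equal(s$per_shrna_cells[["s2"]], 1L)
  expect_equal(sum(s$multiplicity), 3L)
  # all-none edge
  s0 <- occurrence_summary(assign_cells(
    data.frame(cell_id = character(0), shrna_id = character(0),
               reads = integer(0)), cells = c("c1", "c2")))
  expect_equal(s0$fraction_detected, 0)
  expect_length(s0$per_shrna_cells, 0L)
})

test_that("multiplicity histogram matches the planted infection model", {
  sim <- simulate_sc_reads(n_cells = 300L, n_background = 50L, seed = 17)
  truth_m <- lengths(sim$truth$assigned)
  # planted: 18% capture failure, otherwise 1 + Poisson(0.15)
  p0 <- mean(truth_m == 0L)
  expect_lt(abs(p0 - 0.18), 3 * sqrt(0.18 * 0.82 / 300))
  p2 <- mean(truth_m[truth_m > 0L] > 1L)
  expect_lt(abs(p2 - (1 - dpois(0L, 0.15))), 3 * sqrt(0.14 * 0.86 / 250))
})

test_that("never-transduced control cells yield zero calls", {
  sim <- simulate_sc_reads(n_cells = 3L, n_controls = 20L,
                           n_background = 100L, seed = 23)
  ctrl <- sim$manifest$cell_id[sim$manifest$condition == "control"]
  rep <- negative_control_check(sim$cells[ctrl], sim$lib)
  expect_identical(rep$shrna_reads, rep(0L, 20L))
  expect_false(any(rep$flagged))
  # decoy-only cells (guide without scaffold) assign to nothing
  sim2 <- simulate_sc_reads(n_cells = 10L, capture_fail = 1,
                            n_decoys = 15L, n_background = 20L, seed = 23)
  cc <- lapply(sim2$cells, function(r) call_shrna_reads(r, sim2$lib))
  expect_true(all(vapply(cc, function(x) sum(x$counts), 0L) == 0L))
})

test_that("hairpin read counts scale with cell depth", {
  sim <- simulate_sc_reads(n_cells = 200L, capture_fail = 0,
                           extra_lambda = 0, n_background = 30L, seed = 29)
  det <- vapply(names(sim$cells), function(cid)
    sum(call_shrna_reads(sim$cells[[cid]], sim$lib)$counts), 0L)
  tot <- vapply(sim$cells, nrow, 0L)
  expect_gt(cor(det, tot, method = "spearman"), 0)
})

test_that("single-shRNA cells are assigned correctly across seeds", {
  for (seed in 1:5) {
    sim <- simulate_sc_reads(n_cells = 60L, extra_lambda = 0,
                             n_background = 50L, seed = seed)
    cc <- call_cells_from_memory(sim)
    a <- assign_cells(cc, cells = sim$manifest$cell_id)
    ok <- 0L; tot <- 0L; wrong <- 0L
    for (i in seq_len(nrow(a))) {
      cid <- a$cell_id[i]
      truth <- sim$truth$planted_reads[[cid]]
      det <- strsplit(a$shrna_ids[i], ",")[[1L]]
      wrong <- wrong + sum(!det %in% names(truth))
      if (length(truth) == 1L && truth >= 11L) {
        tot <- tot + 1L
        if (identical(det, names(truth))) ok <- ok + 1L
      }
    }
    expect_gte(ok / tot, 0.95)
    expect_equal(wrong, 0L)
  }
})

test_that("call_cells over a written manifest matches in-memory calls", {
  dir <- tempfile()
  sim <- simulate_sc_reads(n_cells = 4L, n_background = 30L, seed = 41,
                           out_dir = dir)
  mf <- read_manifest(file.path(dir, "manifest.tsv"))
  cc <- call_cells(mf, sim$lib)
  a <- assign_cells(cc)
  expect_identical(sort(attr(cc, "cells")), sort(sim$manifest$cell_id))
  for (cid in names(sim$cells)) {
    mem <- call_shrna_reads(sim$cells[[cid]], sim$lib)$counts
    got <- cc[cc$cell_id == cid, ]
    expect_identical(sum(got$reads), sum(mem))
  }
})
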