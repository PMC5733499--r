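# Screen enrichment: from barcoded amplicon reads to per-shRNA and per-gene
# enrichment statistics over the culture time course. The count test is a
# negative-binomial exact-style conditional test with tagwise dispersions
# shrunk toward a common value by weighted conditional likelihood;
# per-screen p-values are combined with Fisher's method and adjusted by
# Benjamini-Hochberg.

#' Demultiplex barcoded screen reads
#'
#' Routes each read by an exact match of its first `barcode_length` bases and
#' trims the barcode from routed reads. Reads shorter than the barcode or
#' with an unknown prefix go to the unassigned stream; read counts are
#' conserved.
#'
#' @param reads `data.frame(id, seq, qual)` as returned by [read_fastq()], or
#'   a character vector of sequences.
#' @param barcode_map Named character vector `barcode -> sample_id`, or a data
#'   frame with columns `barcode`, `sample_id`.
#' @return List with `samples` (named list of read data frames, barcode
#'   trimmed) and `unassigned` (untrimmed).
#' @export
demultiplex <- function(reads, barcode_map) {
  if (is.data.frame(barcode_map)) {
    barcode_map <- stats::setNames(barcode_map$sample_id, barcode_map$barcode)
  }
  if (length(barcode_map) == 0L) stop("empty barcode map")
  bc <- names(barcode_map)
  bl <- unique(nchar(bc))
  if (length(bl) != 1L) stop("barcodes must have equal length")
  if (anyDuplicated(bc)) stop("duplicate barcodes")
  if (any(grepl("[^ACGT]", bc))) stop("barcodes must be over ACGT")
  if (is.character(reads)) {
    reads <- data.frame(id = paste0("r", seq_along(reads)), seq = reads,
                        qual = strrep("I", nchar(reads)))
  }
  pre <- substr(reads$seq, 1L, bl)
  pre[nchar(reads$seq) < bl] <- NA_character_
  sample <- unname(barcode_map[match(pre, bc)])
  assigned <- !is.na(sample)
  out <- lapply(unique(unname(barcode_map)), function(s) {
    df <- reads[assigned & sample == s, , drop = FALSE]
    df$seq <- substr(df$seq, bl + 1L, nchar(df$seq))
    df$qual <- substr(df$qual, bl + 1L, nchar(df$qual))
    rownames(df) <- NULL
    df
  })
  names(out) <- unique(unname(barcode_map))
  una <- reads[!assigned, , drop = FALSE]
  rownames(una) <- NULL
  list(samples = out, unassigned = una)
}

#' Count shRNAs in one sample's amplicon reads
#'
#' The reverse complement of each read is matched against the library guides
#' by exact k-mer seeding and extension; a read is counted for the unique
#' best-matching shRNA with at most `max_mismatch` mismatches over the guide.
#' Ambiguous best hits (ties between distinct shRNAs) are discarded and
#' tallied.
#'
#' @param reads Read data frame or character vector of sequences (barcode
#'   already trimmed).
#' @param lib A [shrna_library()] index.
#' @param max_mismatch 0, 1 or 2 mismatches allowed over the guide.
#' @return List: `counts` (named integer vector over all library shRNAs),
#'   `assigned`, `ambiguous`, `unmatched`, `total`.
#' @export
count_shrnas <- function(reads, lib, max_mismatch = 1L) {
  stopifnot(inherits(lib, "shrna_library"))
  if (!max_mismatch %in% 0:2) stop("max_mismatch must be 0, 1 or 2")
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  ids <- lib$records$shrna_id
  counts <- stats::setNames(integer(length(ids)), ids)
  if (length(seqs) == 0L) {
    return(list(counts = counts, assigned = 0L, ambiguous = 0L,
                unmatched = 0L, total = 0L))
  }
  m <- .match_reads(seqs, lib, max_mismatch = max_mismatch, orient = "revcomp")
  tab <- table(factor(m$assign, levels = seq_along(ids)))
  counts[] <- as.integer(tab)
  list(counts = counts,
       assigned = sum(!is.na(m$assign)),
       ambiguous = sum(m$ambiguous),
       unmatched = sum(is.na(m$assign) & !m$ambiguous),
       total = length(seqs))
}

#' Trimmed mean of M-values normalization factors
#'
#' Composition-robust scale factors for count columns: log-ratios (M) and
#' average abundances (A) against a reference sample are doubly trimmed and
#' the remaining M-values averaged with precision weights; factors are
#' rescaled to geometric mean 1.
#'
#' @param counts shRNA x sample count matrix (>= 2 samples, positive totals).
#' @param logratio_trim Fraction of extreme M-values trimmed (two-sided
#'   total; default 0.30).
#' @param abs_trim Fraction of extreme A-values trimmed (default 0.05).
#' @param ref Reference column index; default is the highest-depth sample.
#' @return Numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, abs_trim = 0.05,
                        ref = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs >= 2 samples")
  N <- colSums(counts)
  if (any(N <= 0)) stop("sample with zero total count")
  if (is.null(ref)) ref <- which.max(N)
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    .tmm_pair(counts[, j], counts[, ref], N[j], N[ref],
              logratio_trim, abs_trim)
  }, numeric(1))
  f / exp(mean(log(f)))
}

.tmm_pair <- function(y, yr, N, Nr, logratio_trim, abs_trim) {
  keep <- y > 0 & yr > 0
  y <- y[keep]; yr <- yr[keep]
  if (!length(y)) return(1)
  M <- log2((y / N) / (yr / Nr))
  A <- 0.5 * log2((y / N) * (yr / Nr))
  # asymptotic variance of M (delta method), used as inverse weight
  v <- (N - y) / (N * y) + (Nr - yr) / (Nr * yr)
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; v <- v[fin]
  n <- length(M)
  if (!n) return(1)
  loM <- floor(n * logratio_trim / 2) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * abs_trim / 2) + 1
  hiA <- n + 1 - loA
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) return(1)
  2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
}

# Conditional (quantile-adjusted) negative-binomial log-likelihood of a
# dispersion value, per shRNA, given equal-depth replicate counts split into
# two groups. `groups` is a list of count matrices (shRNA x replicates).
.cond_loglik <- function(groups, phi) {
  r <- 1 / phi
  ll <- 0
  for (g in groups) {
    n <- ncol(g)
    z <- rowSums(g)
    ll <- ll + rowSums(lgamma(g + r)) - n * lgamma(r) +
      lgamma(n * r) - lgamma(z + n * r)
  }
  ll
}

#' Estimate shrunken tagwise dispersions
#'
#' Common dispersion by maximizing the summed conditional log-likelihood on
#' a grid; tagwise dispersions maximize the per-shRNA conditional
#' log-likelihood plus `prior_weight` times the average (empirical-Bayes
#' shrinkage toward the common value).
#'
#' @param groups List of shRNA x replicate count matrices (depth-equalized),
#'   one per condition.
#' @param prior_weight Shrinkage weight in units of "equivalent shRNAs"
#'   (default 20; larger = stronger shrinkage toward the common trend).
#' @param grid Dispersion grid (default logarithmic over 1e-4 .. 5).
#' @return List with `common` (scalar) and `tagwise` (vector).
#' @export
estimate_dispersion <- function(groups, prior_weight = 20,
                                grid = 10^seq(-4, log10(5), length.out = 60)) {
  ngene <- nrow(groups[[1L]])
  ll <- vapply(grid, function(phi) .cond_loglik(groups, phi),
               numeric(ngene))
  if (ngene == 1L) ll <- matrix(ll, nrow = 1L)
  avg <- colMeans(ll)
  common <- grid[which.max(avg)]
  wl <- ll + prior_weight * matrix(avg, ngene, length(grid), byrow = TRUE)
  tagwise <- grid[max.col(wl, ties.method = "first")]
  list(common = common, tagwise = tagwise)
}

#' Negative-binomial exact-style conditional test
#'
#' Two-sided test for a difference in mean between two groups of
#' depth-equalized counts, conditional on the row total: with `n1` and `n2`
#' replicates summed to `z1` and `z2`, the conditional split distribution is
#' computed from NB(size = n/phi) masses and the p-value sums all splits at
#' most as probable as the observed one. At `phi = 0` this reduces to the
#' two-sided exact binomial test.
#'
#' @param z1,z2 Integer vectors of group count sums.
#' @param n1,n2 Replicate counts per group.
#' @param phi Dispersion (scalar or per-row vector).
#' @return Vector of two-sided p-values.
#' @export
nb_exact_test <- function(z1, z2, n1, n2, phi) {
  stopifnot(length(z1) == length(z2))
  phi <- rep_len(phi, length(z1))
  vapply(seq_along(z1), function(i) {
    .nb_exact_one(z1[i], z2[i], n1, n2, phi[i])
  }, numeric(1))
}

.nb_exact_one <- function(z1, z2, n1, n2, phi) {
  s <- z1 + z2
  if (s == 0L) return(1)
  ks <- 0:s
  if (phi < 1e-8) {
    p <- stats::dbinom(ks, s, n1 / (n1 + n2))
  } else {
    mu <- s / (n1 + n2)                      # per-replicate mean under null
    p1 <- stats::dnbinom(ks, size = n1 / phi, mu = n1 * mu)
    p2 <- stats::dnbinom(s - ks, size = n2 / phi, mu = n2 * mu)
    p <- p1 * p2
    tot <- sum(p)
    if (tot <= 0 || !is.finite(tot)) return(1)
    p <- p / tot
  }
  pobs <- p[z1 + 1L]
  min(1, sum(p[p <= pobs * (1 + 1e-7)]))
}

#' Fisher's combined probability test
#'
#' Combines independent p-values bearing on the same hypothesis:
#' `X = -2 * sum(log(p))` is referred to a chi-square distribution with `2k`
#' degrees of freedom.
#'
#' @param p_values Numeric vector of p-values in (0, 1]. Zeros are clamped to
#'   the smallest positive double with a warning. `NA`s are dropped.
#' @return Combined p-value.
#' @export
fisher_combine <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) return(NA_real_)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("p-value of 0 clamped to smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  x <- -2 * sum(log(p))
  stats::pchisq(x, df = 2 * length(p), lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`stats::p.adjust`, method "BH"); order-preserving
#' with the input.
#'
#' @param p_values Numeric vector of p-values between 0 and 1.
#' @return Vector of q-values.
#' @export
adjust_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  stats::p.adjust(p_values, method = "BH")
}

#' Test shRNA enrichment over the time course
#'
#' For each screen batch separately: TMM + depth normalization, dispersion
#' estimation with empirical-Bayes shrinkage and the NB exact-style test of
#' the late timepoint against day 0. Per-screen p-values are Fisher-combined
#' and BH-adjusted; log2 fold changes (pseudocount 0.5 on normalized counts)
#' are averaged across screens.
#'
#' @param counts shRNA x sample count matrix (column names = sample ids).
#' @param samples Data frame with columns `sample_id`, `day`, `replicate`,
#'   `screen`; both contrast days must be present within every screen.
#' @param contrast Length-2 integer vector `c(reference_day, test_day)`
#'   (default `c(0, 37)`).
#' @param prior_weight Dispersion shrinkage weight, see
#'   [estimate_dispersion()].
#' @param dispersion Optional fixed dispersion overriding estimation.
#' @return Data frame (one row per shRNA): `shrna_id`, `log2_fc`, one
#'   `p_screen.<id>` column per screen, `p_combined`, `fdr`, `all_zero`.
#' @export
test_enrichment <- function(counts, samples, contrast = c(0L, 37L),
                            prior_weight = 20, dispersion = NULL) {
  counts <- as.matrix(counts)
  miss <- setdiff(samples$sample_id, colnames(counts))
  if (length(miss)) stop("samples missing from count matrix: ",
                         paste(miss, collapse = ", "))
  screens <- unique(samples$screen)
  pmat <- matrix(NA_real_, nrow(counts), length(screens),
                 dimnames = list(rownames(counts), screens))
  lfc <- matrix(NA_real_, nrow(counts), length(screens))
  for (si in seq_along(screens)) {
    sm <- samples[samples$screen == screens[si], , drop = FALSE]
    a <- sm$sample_id[sm$day == contrast[1L]]
    b <- sm$sample_id[sm$day == contrast[2L]]
    if (!length(a) || !length(b)) {
      stop("screen ", screens[si], " lacks samples at day ", contrast[1L],
           " or ", contrast[2L])
    }
    y <- counts[, c(a, b), drop = FALSE]
    f <- tmm_factors(y)
    eff <- colSums(y) * f
    target <- exp(mean(log(eff)))
    norm <- sweep(y, 2L, target / eff, `*`)
    eq <- round(norm)
    ga <- eq[, seq_along(a), drop = FALSE]
    gb <- eq[, length(a) + seq_along(b), drop = FALSE]
    phi <- if (!is.null(dispersion)) dispersion else {
      estimate_dispersion(list(ga, gb), prior_weight = prior_weight)$tagwise
    }
    pmat[, si] <- nb_exact_test(rowSums(ga), rowSums(gb),
                                length(a), length(b), phi)
    lfc[, si] <- log2((rowMeans(norm[, length(a) + seq_along(b),
                                     drop = FALSE]) + 0.5) /
                      (rowMeans(norm[, seq_along(a), drop = FALSE]) + 0.5))
  }
  all_zero <- rowSums(counts[, samples$sample_id, drop = FALSE]) == 0L
  p_combined <- apply(pmat, 1L, fisher_combine)
  log2_fc <- rowMeans(lfc)
  p_combined[all_zero] <- 1
  log2_fc[all_zero] <- 0
  res <- data.frame(shrna_id = rownames(counts), log2_fc = log2_fc,
                    stringsAsFactors = FALSE)
  for (si in seq_along(screens)) {
    res[[paste0("p_screen.", screens[si])]] <- pmat[, si]
  }
  res$p_combined <- p_combined
  res$fdr <- adjust_fdr(p_combined)
  res$all_zero <- all_zero
  rownames(res) <- NULL
  res
}

#' Call shRNA hits and multi-shRNA gene candidates
#'
#' An shRNA is a hit when `p_combined < p_threshold` and
#' `fdr < fdr_threshold`; a gene is a multi-shRNA candidate when at least two
#' of its hit shRNAs additionally have `log2_fc > lfc_threshold`. Defaults
#' follow the screen's reported thresholds (P < 0.05, FDR < 0.25,
#' log2 fold change > 1).
#'
#' @param results Data frame from [test_enrichment()].
#' @param lib A [shrna_library()] mapping shRNAs to genes.
#' @param p_threshold,fdr_threshold,lfc_threshold Hit-calling thresholds.
#' @return List: `shrna_hits` (results rows with `hit` flag) and `gene_hits`
#'   (`gene_symbol`, `n_shrnas_enriched`, `shrna_ids`, `candidate`).
#' @export
call_hits <- function(results, lib, p_threshold = 0.05, fdr_threshold = 0.25,
                      lfc_threshold = 1) {
  stopifnot(inherits(lib, "shrna_library"))
  gene <- lib$records$gene_symbol[match(results$shrna_id,
                                        lib$records$shrna_id)]
  if (anyNA(gene)) stop("results contain shRNAs absent from the library")
  results$gene_symbol <- gene
  results$hit <- results$p_combined < p_threshold &
    results$fdr < fdr_threshold
  strong <- results$hit & results$log2_fc > lfc_threshold
  gh <- do.call(rbind, lapply(split(seq_len(nrow(results)), gene),
                              function(i) {
    n <- sum(strong[i])
    data.frame(gene_symbol = gene[i][1L],
               n_shrnas_enriched = n,
               shrna_ids = paste(results$shrna_id[i][strong[i]],
                                 collapse = ","),
               candidate = n >= 2L,
               stringsAsFactors = FALSE)
  }))
  rownames(gh) <- NULL
  list(shrna_hits = results, gene_hits = gh)
}
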