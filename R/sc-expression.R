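# Single-cell expression analytics. Matrices are oriented cells x genes
# throughout (see read_matrix() for file orientation handling).

#' Filter cells and genes by detection
#'
#' Removes cells detecting fewer than `min_genes_per_cell` genes and then
#' genes detected in fewer than `min_cells_per_gene` cells.
#'
#' @param mat Raw count matrix, cells x genes.
#' @param min_genes_per_cell,min_cells_per_gene Detection thresholds
#'   (nonzero entries).
#' @return Filtered matrix; the numbers removed are attached as attributes
#'   `cells_removed` / `genes_removed`.
#' @export
qc_filter <- function(mat, min_genes_per_cell = 1L, min_cells_per_gene = 1L) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("qc_filter expects a raw (nonnegative) layer")
  keep_c <- rowSums(mat > 0) >= min_genes_per_cell
  if (!any(keep_c)) stop("all cells removed by qc_filter")
  out <- mat[keep_c, , drop = FALSE]
  keep_g <- colSums(out > 0) >= min_cells_per_gene
  out <- out[, keep_g, drop = FALSE]
  structure(out, cells_removed = sum(!keep_c), genes_removed = sum(!keep_g))
}

#' Depth-normalized log expression
#'
#' `log2(1 + count * 1e4 / cell_total)`: counts-per-10k scaling followed by a
#' log2 transform.
#'
#' @param mat Raw count matrix, cells x genes.
#' @param scale_factor Per-cell target total (default 1e4).
#' @return Normalized matrix of the same shape.
#' @export
normalize_log <- function(mat, scale_factor = 1e4) {
  mat <- as.matrix(mat)
  tot <- rowSums(mat)
  if (any(tot == 0)) {
    stop("cell with zero total count; run qc_filter first")
  }
  log2(1 + mat * (scale_factor / tot))
}

#' Row-normalize genes to Z-scores
#'
#' Standardizes each gene (heat-map row) to mean 0, sd 1 across cells; genes
#' with zero variance are set to 0.
#'
#' @param mat Matrix, cells x genes (normalized layer).
#' @return Z-scored matrix of the same shape.
#' @export
zscore_rows <- function(mat) {
  mat <- as.matrix(mat)
  mu <- colMeans(mat)
  sd <- apply(mat, 2L, stats::sd)
  z <- sweep(mat, 2L, mu, `-`)
  pos <- sd > 0
  z[, pos] <- sweep(z[, pos, drop = FALSE], 2L, sd[pos], `/`)
  z[, !pos] <- 0
  z
}

.top_variable_genes <- function(mat, n) {
  v <- apply(mat, 2L, stats::var)
  ord <- order(v, decreasing = TRUE)
  ord[seq_len(min(n, ncol(mat)))]
}

# Run expr with a locally seeded RNG, restoring the caller's state.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Hierarchical clustering with bootstrap stability
#'
#' Clusters cells by average-linkage hierarchical clustering on correlation
#' distance over the top variable genes (row z-scored, as the heat maps
#' consume). For each candidate `k`, stability is the mean adjusted Rand
#' index between the full-data labels and labels recomputed on
#' `n_bootstrap` gene-resampled replicates; the chosen `k` maximizes
#' stability (ties go to the smaller `k`).
#'
#' @param mat Normalized matrix, cells x genes.
#' @param k_range Candidate cluster numbers (default `2:8`).
#' @param n_bootstrap Gene-resampling replicates per `k` (default 50).
#' @param seed RNG seed for the bootstrap.
#' @param n_var_genes Number of top-variance genes used (default 500).
#' @param linkage Agglomeration method (default "average").
#' @param stable_min Mean-ARI floor under which the result is flagged as
#'   having no stable structure (default 0.5).
#' @return Object of class `cluster_result`: `labels` (chosen k), `k`,
#'   `stability` (named by k), `stable` flag, `hclust` tree, parameters.
#' @export
cluster_cells <- function(mat, k_range = 2:8, n_bootstrap = 50L, seed = NULL,
                          n_var_genes = 500L, linkage = "average",
                          stable_min = 0.5) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 2L) stop("need >= 2 cells")
  if (min(k_range) < 2L || max(k_range) > n - 1L) {
    stop("k_range must lie within [2, n_cells - 1]")
  }
  sel <- .top_variable_genes(mat, n_var_genes)
  z <- zscore_rows(mat[, sel, drop = FALSE])
  cl_of <- function(zz) {
    d <- stats::as.dist(1 - stats::cor(t(zz)))
    stats::hclust(d, method = linkage)
  }
  hc <- cl_of(z)
  labs <- lapply(k_range, function(k) stats::cutree(hc, k = k))
  names(labs) <- k_range
  stability <- .with_seed(seed, {
    boots <- lapply(seq_len(n_bootstrap), function(b) {
      gs <- sample.int(ncol(z), replace = TRUE)
      cl_of(z[, gs, drop = FALSE])
    })
    vapply(seq_along(k_range), function(ki) {
      mean(vapply(boots, function(bh) {
        mclust::adjustedRandIndex(labs[[ki]],
                                  stats::cutree(bh, k = k_range[ki]))
      }, numeric(1)))
    }, numeric(1))
  })
  names(stability) <- k_range
  best <- k_range[which.max(stability)]     # which.max takes the first max
  structure(list(labels = labs[[as.character(best)]], k = best,
                 stability = stability,
                 stable = max(stability) >= stable_min,
                 hclust = hc, linkage = linkage,
                 distance = "correlation", n_var_genes = length(sel),
                 n_bootstrap = n_bootstrap, seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: k = %d over %d cells (%s linkage, %s distance)\n",
              x$k, length(x$labels), x$linkage, x$distance))
  cat("stability by k:\n")
  print(round(x$stability, 3))
  if (!x$stable) cat("flag: no stable structure detected\n")
  invisible(x)
}

#' Rank genes between two cell groups
#'
#' Per-gene two-sided rank-sum test on normalized values (exact midrank
#' permutation null for small groups, normal approximation otherwise) plus
#' log2 fold change of group means with pseudocount 1. The fold change is
#' computed on the linear (de-logged) normalized scale, `2^x - 1`, so that a
#' k-fold planted shift yields a log2 fold change near `log2(k)`. P-values
#' are BH-adjusted and genes are called up/down at the stated thresholds.
#'
#' @param mat Normalized matrix, cells x genes.
#' @param cells_a,cells_b Row indices or names of the two groups (>= 3 cells
#'   each); fold changes are `b` over `a`.
#' @param fdr_threshold,lfc_threshold Call thresholds (defaults 0.05 and 1:
#'   down-regulated means log2 fold change < -1 and FDR < 0.05).
#' @param exact_max Use the exact permutation null when the total group size
#'   is at most this (default 12).
#' @return Data frame ranked by the signed statistic (descending): `gene`,
#'   `stat`, `log2_fc`, `p`, `fdr`, `call` in `up`/`down`/`ns`.
#' @export
rank_genes <- function(mat, cells_a, cells_b, fdr_threshold = 0.05,
                       lfc_threshold = 1, exact_max = 12L) {
  mat <- as.matrix(mat)
  a <- mat[cells_a, , drop = FALSE]
  b <- mat[cells_b, , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  if (na < 3L || nb < 3L) stop("both groups need >= 3 cells")
  res <- vapply(seq_len(ncol(mat)), function(j) {
    .ranksum_test(a[, j], b[, j], exact_max)
  }, numeric(2))
  p <- res[1L, ]; z <- res[2L, ]
  lfc <- log2((colMeans(2^b - 1) + 1) / (colMeans(2^a - 1) + 1))
  fdr <- adjust_fdr(p)
  call <- rep("ns", ncol(mat))
  call[fdr < fdr_threshold & lfc > lfc_threshold] <- "up"
  call[fdr < fdr_threshold & lfc < -lfc_threshold] <- "down"
  out <- data.frame(gene = colnames(mat), stat = z, log2_fc = lfc, p = p,
                    fdr = fdr, call = call, stringsAsFactors = FALSE)
  out[order(-out$stat), , drop = FALSE]
}

# Two-sided rank-sum test of b vs a on midranks. Returns c(p, z) where z is
# the standardized rank-sum statistic (positive = higher in b).
.ranksum_test <- function(x, y, exact_max) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[(n1 + 1):n])
  mu <- n2 * (n + 1) / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sig2 > 0) (w - mu) / sqrt(sig2) else 0
  if (n <= exact_max) {
    combs <- utils::combn(n, n2)
    ws <- colSums(matrix(r[combs], nrow = n2))
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
  } else {
    p <- if (sig2 > 0) 2 * stats::pnorm(-abs(z)) else 1
  }
  c(min(1, p), z)
}

#' Per-cell signature score
#'
#' Mean of gene-wise z-scored normalized expression over the signature's
#' genes detected in the cell: a pathway-centric readout designed to
#' tolerate dropout, since stochastic dropout is unlikely to silence all
#' genes of a pathway in the same cell. Undetected (zero) signature genes
#' are treated as missing data rather than as low expression, so a dropped
#' gene removes one term from the average instead of dragging the score
#' down; a cell detecting no signature gene scores 0.
#'
#' @param mat Normalized matrix, cells x genes.
#' @param signature Character vector of gene ids.
#' @return Data frame: `cell_id`, `score`, `n_genes_detected` (signature
#'   genes with nonzero value in that cell); the number of signature genes
#'   present in the matrix is attached as attribute `n_genes_used`.
#' @export
score_signature <- function(mat, signature) {
  mat <- as.matrix(mat)
  genes <- intersect(unique(signature), colnames(mat))
  if (!length(genes)) stop("signature not represented in the matrix")
  sub <- mat[, genes, drop = FALSE]
  z <- zscore_rows(sub)
  det <- sub > 0
  score <- rowSums(z * det) / pmax(rowSums(det), 1L)
  out <- data.frame(cell_id = rownames(mat),
                    score = score,
                    n_genes_detected = rowSums(det),
                    row.names = NULL)
  attr(out, "n_genes_used") <- length(genes)
  out
}

#' Hypergeometric over-representation of gene sets
#'
#' One-sided hypergeometric tail probability of the overlap between a gene
#' list and each signature, within a stated universe; BH-adjusted.
#'
#' @param gene_list Character vector (subset of `universe`).
#' @param signatures Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector of all assayed genes.
#' @param midp Use the mid-p correction (`P(X > q) + P(X = q)/2`). The
#'   classic tail probability (default) is conservative because the overlap
#'   is discrete; the mid-p variant is approximately uniform under the null
#'   and is what calibration assessments should use.
#' @return Data frame: `signature`, `overlap`, `set_size`, `list_size`,
#'   `p`, `fdr`.
#' @export
overrepresentation <- function(gene_list, signatures, universe,
                               midp = FALSE) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% universe)) {
    stop("gene_list contains genes outside the universe")
  }
  k <- length(gene_list)
  res <- lapply(names(signatures), function(nm) {
    sig <- intersect(unique(signatures[[nm]]), universe)
    q <- length(intersect(gene_list, sig))
    m <- length(sig); nn <- length(universe) - m
    p <- stats::phyper(q - 1L, m, nn, k, lower.tail = FALSE)
    if (midp) p <- p - stats::dhyper(q, m, nn, k) / 2
    data.frame(signature = nm, overlap = q, set_size = length(sig),
               list_size = k, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- adjust_fdr(out$p)
  out
}
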