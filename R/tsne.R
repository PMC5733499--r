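# Exact t-distributed stochastic neighbor embedding. Deliberately the exact
# O(n^2) formulation (no Barnes-Hut approximation): the cell numbers this
# package targets (hundreds of wells) make the exact gradients affordable,
# and determinism for a fixed seed is part of the contract.

#' 2-D t-SNE embedding of cells
#'
#' Principal components (default 20) of the normalized matrix are embedded
#' by exact t-SNE: Gaussian input affinities calibrated per cell to the
#' target perplexity by bisection, symmetrized; Student-t output kernel;
#' gradient descent with momentum, adaptive gains and an early-exaggeration
#' phase. Deterministic for a fixed seed.
#'
#' @param mat Normalized matrix, cells x genes (or any numeric feature
#'   matrix).
#' @param perplexity Target perplexity (default 30, auto-reduced to
#'   `floor((n - 1) / 3)` when the cell count is small; an explicitly
#'   supplied perplexity violating `n > 3 * perplexity` is an error).
#' @param seed RNG seed for the initial coordinates.
#' @param iterations Gradient-descent iterations (default 1000).
#' @param n_pcs Number of principal components fed to t-SNE (default 20).
#' @return Object of class `tsne_embedding`: `coords` (n x 2, rownames kept),
#'   `kl` (Kullback-Leibler divergence trace), `perplexity`, `seed`,
#'   `iterations`.
#' @export
embed_tsne <- function(mat, perplexity = NULL, seed = NULL,
                       iterations = 1000L, n_pcs = 20L) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 4L) stop("need at least 4 cells")
  auto <- is.null(perplexity)
  if (auto) perplexity <- min(30, floor((n - 1) / 3))
  if (n <= 3 * perplexity) {
    stop("perplexity too large: need n_cells > 3 * perplexity, i.e. ",
         "perplexity < ", n / 3)
  }
  keep <- apply(mat, 2L, stats::sd) > 0
  pcs <- stats::prcomp(mat[, keep, drop = FALSE], center = TRUE,
                       scale. = FALSE)
  X <- pcs$x[, seq_len(min(n_pcs, ncol(pcs$x))), drop = FALSE]

  P <- .tsne_affinities(X, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, .Machine$double.eps)
  P <- P / sum(P)

  Y <- .with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2L))
  momentum <- 0.5; final_momentum <- 0.8; eta <- 200
  exag <- 12; exag_iter <- min(100L, max(50L, iterations %/% 4L))
  gains <- matrix(1, n, 2L)
  inc <- matrix(0, n, 2L)
  kl <- numeric(iterations)
  for (it in seq_len(iterations)) {
    Pit <- if (it <= exag_iter) P * exag else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q <- pmax(Q, .Machine$double.eps)
    L <- (Pit - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    if (it == 250L) momentum <- final_momentum
    inc <- momentum * inc - eta * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2L, colMeans(Y), `-`)
    kl[it] <- sum(P * log(P / Q))
  }
  structure(list(coords = `rownames<-`(Y, rownames(mat)), kl = kl,
                 perplexity = perplexity, seed = seed,
                 iterations = iterations, n_pcs = ncol(X)),
            class = "tsne_embedding")
}

# Per-point Gaussian bandwidths by bisection on the Shannon entropy so each
# row of the conditional affinity matrix has the target perplexity.
.tsne_affinities <- function(X, perplexity, tol = 1e-5, max_iter = 50L) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    Di <- D[i, -i]
    for (iter in seq_len(max_iter)) {
      p <- exp(-Di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 } else {
        H <- log(sp) + beta * sum(Di * p) / sp
        p <- p / sp
      }
      if (abs(H - target) < tol) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P
}

#' @export
print.tsne_embedding <- function(x, ...) {
  cat(sprintf("t-SNE embedding: %d cells, perplexity %g, %d iterations, final KL %.4f\n",
              nrow(x$coords), x$perplexity, x$iterations,
              x$kl[length(x$kl)]))
  invisible(x)
}
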