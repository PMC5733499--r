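# Gene-set enrichment by the running-sum statistic with a gene-label
# permutation null.

#' Running-sum enrichment score
#'
#' Walking a ranked gene list from top to bottom, the running sum increases
#' by `|stat|^weight / sum(|stat|^weight over signature hits)` at signature
#' genes and decreases by `1/(N - n_sig)` otherwise. The enrichment score is
#' the signed maximum deviation from zero. With `weight = 0` the running sum
#' ends exactly at zero.
#'
#' @param stats Named numeric vector of ranking statistics; sorted in
#'   decreasing order internally.
#' @param signature Character vector of gene ids.
#' @param weight 0 (unweighted) or 1 (statistic-weighted).
#' @return List: `es`, `running` (the running sum), `hits` (logical vector
#'   along the ranking), `order` (gene names in ranked order).
#' @export
gsea_es <- function(stats, signature, weight = 1) {
  if (!weight %in% c(0, 1)) stop("weight must be 0 or 1")
  if (is.null(names(stats))) stop("stats must be a named vector")
  ord <- order(stats, decreasing = TRUE)
  s <- stats[ord]
  genes <- names(s)
  hits <- genes %in% signature
  n <- length(s); nh <- sum(hits)
  if (nh == 0L) stop("signature not represented in the ranking")
  if (nh == n) stop("signature covers the entire ranking")
  w <- abs(s)^weight
  inc <- numeric(n)
  inc[hits] <- w[hits] / sum(w[hits])
  inc[!hits] <- -1 / (n - nh)
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  list(es = es, running = running, hits = hits, order = genes)
}

#' Gene-set enrichment with a permutation null
#'
#' Computes the running-sum enrichment score of a signature in a ranked
#' list, a gene-label permutation null (random signatures of the same size),
#' the normalized enrichment score (ES divided by the mean magnitude of
#' same-sign null scores) and a nominal permutation p-value. The leading
#' edge contains the signature genes at or before the score extremum (after
#' it for negative scores).
#'
#' @inheritParams gsea_es
#' @param n_permutations Number of permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return Data-frame-friendly list of class `gsea_result`: `es`, `nes`,
#'   `p`, `leading_edge`, `n_signature`, plus the null scores.
#' @export
gsea <- function(stats, signature, n_permutations = 1000L, seed = NULL,
                 weight = 1) {
  obs <- gsea_es(stats, signature, weight = weight)
  n <- length(stats); nh <- sum(obs$hits)
  s_sorted <- sort(stats, decreasing = TRUE)
  w <- abs(s_sorted)^weight
  null_es <- .with_seed(seed, vapply(seq_len(n_permutations), function(b) {
    hit <- logical(n)
    hit[sample.int(n, nh)] <- TRUE
    inc <- numeric(n)
    inc[hit] <- w[hit] / sum(w[hit])
    inc[!hit] <- -1 / (n - nh)
    run <- cumsum(inc)
    run[which.max(abs(run))]
  }, numeric(1)))
  same <- null_es[sign(null_es) == sign(obs$es)]
  nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
  peak <- which.max(abs(obs$running))
  le <- if (obs$es >= 0) obs$order[seq_len(peak)][obs$hits[seq_len(peak)]]
        else obs$order[peak:n][obs$hits[peak:n]]
  structure(list(es = obs$es, nes = nes, p = p, leading_edge = le,
                 n_signature = nh, null_es = null_es,
                 n_permutations = n_permutations, weight = weight),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA: ES = %.3f, NES = %.3f, p = %.4g (%d signature genes, %d permutations)\n",
              x$es, x$nes, x$p, x$n_signature, x$n_permutations))
  invisible(x)
}

#' GSEA over a signature collection
#'
#' Runs [gsea()] for each signature of a collection and BH-adjusts the
#' nominal p-values across signatures. Signatures with no gene in the
#' ranking are skipped with a warning.
#'
#' @inheritParams gsea
#' @param signatures Named list of character vectors (e.g. [read_gmt()]).
#' @return Data frame: `signature`, `es`, `nes`, `p`, `fdr`,
#'   `leading_edge` (comma-separated), `n_signature`.
#' @export
gsea_collection <- function(stats, signatures, n_permutations = 1000L,
                            seed = NULL, weight = 1) {
  rows <- lapply(names(signatures), function(nm) {
    if (!any(names(stats) %in% signatures[[nm]]) ||
        all(names(stats) %in% signatures[[nm]])) {
      warning("signature '", nm, "' not testable in the ranking; skipped")
      return(NULL)
    }
    g <- gsea(stats, signatures[[nm]], n_permutations = n_permutations,
              seed = seed, weight = weight)
    data.frame(signature = nm, es = g$es, nes = g$nes, p = g$p,
               leading_edge = paste(g$leading_edge, collapse = ","),
               n_signature = g$n_signature, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable signature in the collection")
  out$fdr <- adjust_fdr(out$p)
  out[, c("signature", "es", "nes", "p", "fdr", "leading_edge",
          "n_signature")]
}
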