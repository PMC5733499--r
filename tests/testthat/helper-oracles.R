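# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementations they check.

# Step-up FDR by direct evaluation of the definition:
# q_(i) = min_{j >= i} p_(j) * m / j, mapped back to input order.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  q[order(o)]
}

# Running-sum enrichment score, weight 0, by explicit walking.
es_brute <- function(ranking, signature) {
  n <- length(ranking)
  nh <- sum(ranking %in% signature)
  run <- 0
  best <- 0
  for (g in ranking) {
    run <- run + if (g %in% signature) 1 / nh else -1 / (n - nh)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Trimmed-mean-of-M-values factor for sample y against reference yr, by the
# definition: doubly trim M and A, precision-weighted mean of retained M.
tmm_brute <- function(y, yr, logratio_trim = 0.30, abs_trim = 0.05) {
  N <- sum(y); Nr <- sum(yr)
  keep <- y > 0 & yr > 0
  y <- y[keep]; yr <- yr[keep]
  M <- log2((y / N) / (yr / Nr))
  A <- 0.5 * log2((y / N) * (yr / Nr))
  w <- 1 / ((N - y) / (N * y) + (Nr - yr) / (Nr * yr))
  n <- length(M)
  loM <- floor(n * logratio_trim / 2) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abs_trim / 2) + 1; hiA <- n + 1 - loA
  rM <- rank(M, ties.method = "first"); rA <- rank(A, ties.method = "first")
  sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  2^(sum(M[sel] * w[sel]) / sum(w[sel]))
}

# Exact two-sided rank-sum p-value by complete enumeration on midranks.
ranksum_brute <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[(n1 + 1):n])
  mu <- n2 * (n + 1) / 2
  ws <- combn(n, n2, function(i) sum(r[i]))
  mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
}
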