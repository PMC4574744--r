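# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own code paths.

# Welch two-sample t from the textbook formula.
oracle_welch_t <- function(x1, x0) {
  n1 <- length(x1); n0 <- length(x0)
  (mean(x1) - mean(x0)) / sqrt(var(x1) / n1 + var(x0) / n0)
}

# One-sided Fisher exact p by hypergeometric enumeration with choose().
oracle_fisher_greater <- function(a, b, c_, d) {
  K <- a + b          # draws (group size)
  M <- a + c_         # successes in population
  N <- a + b + c_ + d
  js <- max(0, K - (N - M)):min(K, M)
  probs <- choose(M, js) * choose(N - M, K - js) / choose(N, K)
  sum(probs[js >= a])
}

# BH step-up computed literally from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# AUC by exhaustive concordant-pair counting (ties count 1/2).
oracle_auc <- function(scores, y) {
  pos <- scores[y]
  neg <- scores[!y]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Small expression fixture: k genes x n samples, positive values.
make_expression <- function(k = 6, n = 8, seed = 1, base = 1000) {
  set.seed(seed)
  X <- matrix(exp(rnorm(k * n, log(base), 0.5)), k, n,
              dimnames = list(sprintf("g%02d", 1:k), sprintf("s%02d", 1:n)))
  X
}
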