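#' @importFrom stats median phyper plogis pt quantile rbinom rnorm runif sd
#'   p.adjust fisher.test var
NULL

# Internal: coerce sensitivity labels to logical (TRUE = sensitive).
as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("sensitive", "insensitive"))
    if (length(bad) > 0) {
      stop("labels must be 'sensitive'/'insensitive'; found: ",
           paste(bad, collapse = ", "))
    }
    return(labels == "sensitive")
  }
  if (is.numeric(labels)) return(labels != 0)
  stop("unsupported label type")
}

#' Area under the ROC curve with midrank tie handling
#'
#' Computes AUC as the Mann-Whitney concordance probability: the rank-sum
#' statistic of the positive-class scores, with ties resolved by midranks.
#' This equals the trapezoidal area under the ROC curve traced over score
#' thresholds.
#'
#' @param scores Numeric vector of prediction scores (higher = more likely
#'   sensitive).
#' @param labels Labels; either logical (TRUE = sensitive) or character
#'   `"sensitive"`/`"insensitive"`.
#' @return AUC in \[0, 1\].
#' @export
auc_roc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  stopifnot(length(scores) == length(y), !anyNA(scores), !anyNA(y))
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("AUC requires both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

#' One-sided Fisher exact p-value for a 2x2 table
#'
#' Exact hypergeometric tail probability for the table
#' \code{rbind(c(a, b), c(c, d))} with rows = group membership and columns =
#' outcome. \code{alternative = "greater"} tests enrichment of the first
#' outcome in the first group. Vectorized over table entries.
#'
#' @param a,b,c_,d Non-negative integer cell counts.
#' @param alternative `"greater"` or `"less"`.
#' @return p-value(s) in \[0, 1\].
#' @export
fisher_exact_p <- function(a, b, c_, d, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(a >= 0, b >= 0, c_ >= 0, d >= 0)
  # a ~ Hypergeometric(m = a+c_, n = b+d, k = a+b)
  if (alternative == "greater") {
    phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
  } else {
    phyper(a, a + c_, b + d, a + b, lower.tail = TRUE)
  }
}

# Internal: vectorized two-sample t statistics for a feature matrix.
# V: features x samples; y: logical, TRUE = sensitive (first group).
# Sign convention: positive t means higher values in sensitives.
# var_equal = FALSE gives the Welch statistic, TRUE the pooled-variance one.
# Zero-variance handling: if the standard error is 0 and the means are
# equal, t = 0; if means differ with zero error, t = +/-Inf.
t_stats_matrix <- function(V, y, var_equal = FALSE) {
  V <- rbind(V)
  n1 <- sum(y)
  n0 <- sum(!y)
  stopifnot(n1 >= 2, n0 >= 2)
  m1 <- rowMeans(V[, y, drop = FALSE])
  m0 <- rowMeans(V[, !y, drop = FALSE])
  ss1 <- rowSums((V[, y, drop = FALSE] - m1)^2)
  ss0 <- rowSums((V[, !y, drop = FALSE] - m0)^2)
  v1 <- ss1 / (n1 - 1)
  v0 <- ss0 / (n0 - 1)
  if (var_equal) {
    sp2 <- (ss1 + ss0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
  }
  d <- m1 - m0
  t <- d / se
  zero <- se == 0
  if (any(zero)) t[zero] <- ifelse(d[zero] == 0, 0, sign(d[zero]) * Inf)
  t
}

# Internal: Welch-Satterthwaite two-sided p-values matching t_stats_matrix
# with var_equal = FALSE.
welch_p_matrix <- function(V, y) {
  V <- rbind(V)
  n1 <- sum(y)
  n0 <- sum(!y)
  m1 <- rowMeans(V[, y, drop = FALSE])
  m0 <- rowMeans(V[, !y, drop = FALSE])
  v1 <- rowSums((V[, y, drop = FALSE] - m1)^2) / (n1 - 1)
  v0 <- rowSums((V[, !y, drop = FALSE] - m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  t <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v0^2 / (n0^2 * (n0 - 1)))
  p <- 2 * pt(-abs(t), df)
  p[se2 == 0] <- ifelse(m1[se2 == 0] == m0[se2 == 0], 1, 0)
  p
}

# Internal: t statistics for B label permutations, all features at once.
# Labels are permuted jointly across features so inter-feature correlation
# is preserved. Returns a features x B matrix. Uses the current RNG stream.
perm_t_matrix <- function(V, y, B, var_equal = FALSE) {
  V <- rbind(V)
  n <- ncol(V)
  n1 <- sum(y)
  n0 <- n - n1
  # indicator matrix of permuted "sensitive" memberships
  Y <- matrix(0, n, B)
  for (b in seq_len(B)) Y[sample.int(n, n1), b] <- 1
  S1 <- V %*% Y                        # per-perm group-1 sums
  Q1 <- (V^2) %*% Y                    # per-perm group-1 sums of squares
  tot <- rowSums(V)
  tot2 <- rowSums(V^2)
  m1 <- S1 / n1
  m0 <- (tot - S1) / n0
  ss1 <- Q1 - n1 * m1^2
  ss0 <- (tot2 - Q1) - n0 * m0^2
  ss1[ss1 < 0] <- 0                    # guard tiny negative rounding
  ss0[ss0 < 0] <- 0
  if (var_equal) {
    se <- sqrt(((ss1 + ss0) / (n1 + n0 - 2)) * (1 / n1 + 1 / n0))
  } else {
    se <- sqrt(ss1 / (n1 * (n1 - 1)) + ss0 / (n0 * (n0 - 1)))
  }
  d <- m1 - m0
  t <- d / se
  zero <- se == 0
  if (any(zero)) t[zero] <- ifelse(d[zero] == 0, 0, sign(d[zero]) * Inf)
  t
}

# Internal: number of elements of a sorted numeric vector >= each x.
count_ge <- function(sorted_vec, x) {
  length(sorted_vec) - findInterval(x, sorted_vec, left.open = TRUE)
}

# Internal: ridge-penalized logistic regression by Newton/IRLS.
# Z: n x p design (no intercept column); y: 0/1. Penalty lambda/2 * ||beta||^2
# on slopes only. Returns list(intercept, coef, converged).
ridge_logistic <- function(Z, y, lambda = 1, max_iter = 200, tol = 1e-12) {
  Z <- cbind(Z)
  n <- length(y)
  p <- ncol(Z)
  X <- cbind(`(Intercept)` = 1, Z)
  pen <- diag(c(0, rep(lambda, p)), p + 1)
  beta <- numeric(p + 1)
  beta[1] <- stats::qlogis(min(max(mean(y), 1 / (n + 1)), n / (n + 1)))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-12)
    grad <- drop(crossprod(X, y - mu)) - pen %*% beta
    H <- crossprod(X * w, X) + pen
    step <- solve(H, grad)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  list(intercept = beta[1], coef = beta[-1],
       converged = max(abs(step)) < sqrt(tol))
}

# Internal: deterministic stratified k-fold assignment.
# Returns integer fold id per sample. Uses current RNG stream.
stratified_folds <- function(y, k) {
  n <- length(y)
  fold <- integer(n)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k) stop("class too small for ", k, "-fold stratification")
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
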