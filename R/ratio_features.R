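#' Configuration for ratio feature selection and model fitting
#'
#' Bundles the tunable parameters of the ratio pipeline. Defaults follow
#' the method's standard settings: pseudocount 32 expression units (below
#' the MAS5-like baseline of 150, damping low-expression noise), 100 label
#' permutations, FDR cutoff 0.1.
#'
#' @param pseudocount Constant `c` added to numerator and denominator
#'   before the log transform (expression units, > 0 normally; 0 gives
#'   exactly scale-invariant ratios).
#' @param n_permutations Number of sample-label permutations (>= 20).
#' @param fdr_cutoff q-value threshold for significant ratios.
#' @param var_equal Use pooled-variance t statistics instead of Welch.
#' @param p_mode Permutation p counting: `"per_feature"` (default;
#'   +1-smoothed, minimum attainable p = 1/(B+1)) or `"pooled"` across the
#'   whole feature family for finer resolution.
#' @param pct75_min,iqr_min Gene filter thresholds (see [filter_genes()]).
#' @param ap_damping,ap_max_iter,ap_convergence_window,ap_preference
#'   Affinity propagation controls (see [affinity_propagation()]). The
#'   pipeline preference defaults to 0.5, a correlation floor: ratios
#'   correlated below it count as distinct evidence and stay in separate
#'   clusters, while the generic [affinity_propagation()] default (median
#'   similarity) would merge weakly correlated informative ratios whenever
#'   the significant set is small.
#' @param ridge_lambda L2 penalty of the logistic classifier (0 = none,
#'   with separation detection).
#' @param threshold Probability cutoff for the sensitive call.
#' @param seed Integer seed governing permutations and fold assignment.
#' @return A list of class `grep_config`.
#' @export
grep_config <- function(pseudocount = 32, n_permutations = 100,
                        fdr_cutoff = 0.1, var_equal = FALSE,
                        p_mode = c("per_feature", "pooled"),
                        pct75_min = 250, iqr_min = 500,
                        ap_damping = 0.9, ap_max_iter = 1000,
                        ap_convergence_window = 50, ap_preference = 0.5,
                        ridge_lambda = 1, threshold = 0.5, seed = 1) {
  p_mode <- match.arg(p_mode)
  stopifnot(pseudocount >= 0, n_permutations >= 20, fdr_cutoff > 0,
            fdr_cutoff < 1, ap_damping >= 0.5, ap_damping < 1,
            ridge_lambda >= 0, threshold > 0, threshold < 1)
  structure(list(
    pseudocount = pseudocount, n_permutations = as.integer(n_permutations),
    fdr_cutoff = fdr_cutoff, var_equal = var_equal, p_mode = p_mode,
    pct75_min = pct75_min, iqr_min = iqr_min,
    ap_damping = ap_damping, ap_max_iter = as.integer(ap_max_iter),
    ap_convergence_window = as.integer(ap_convergence_window),
    ap_preference = ap_preference,
    ridge_lambda = ridge_lambda, threshold = threshold,
    seed = as.integer(seed)), class = "grep_config")
}

#' Pairwise log-ratio features
#'
#' For every unordered pair of available genes in `gene_set`, computes the
#' per-sample feature
#' \deqn{v_s = \log\frac{x_{num,s} + c}{x_{den,s} + c}}
#' (natural log). Pairs are canonically oriented with the lexicographically
#' smaller gene as numerator; orientation is revisited after association
#' testing. For k available genes there are exactly k(k-1)/2 features.
#'
#' @param X Expression matrix (genes x samples).
#' @param gene_set Character vector of genes to pair; genes absent from `X`
#'   are skipped with a message.
#' @param pseudocount Constant `c` >= 0 added to both numerator and
#'   denominator.
#' @return An object of class `ratio_set`: list with `values` (features x
#'   samples matrix of log-ratios), `pairs` (data frame `gene_num`,
#'   `gene_den`), `pseudocount`.
#' @export
compute_log_ratios <- function(X, gene_set, pseudocount = 32) {
  validate_expression_matrix(X)
  stopifnot(pseudocount >= 0)
  gene_set <- unique(gene_set)
  missing <- setdiff(gene_set, rownames(X))
  if (length(missing) > 0) {
    message("skipping ", length(missing), " gene(s) absent from the matrix")
  }
  genes <- sort(intersect(gene_set, rownames(X)))
  k <- length(genes)
  if (k < 2) stop("fewer than 2 genes available for ratio computation")
  G <- X[genes, , drop = FALSE] + pseudocount
  idx <- utils::combn(k, 2)
  # quotient-then-log (not difference of logs): matches prediction-time
  # arithmetic and keeps c = 0 features exactly invariant under power-of-two
  # per-sample rescaling
  values <- log(G[idx[1, ], , drop = FALSE] / G[idx[2, ], , drop = FALSE])
  pairs <- data.frame(gene_num = genes[idx[1, ]], gene_den = genes[idx[2, ]],
                      stringsAsFactors = FALSE)
  rownames(values) <- paste(pairs$gene_num, pairs$gene_den, sep = "/")
  structure(list(values = values, pairs = pairs, pseudocount = pseudocount),
            class = "ratio_set")
}

#' @export
print.ratio_set <- function(x, ...) {
  cat(sprintf("ratio_set: %d log-ratio features x %d samples (c = %g)\n",
              nrow(x$values), ncol(x$values), x$pseudocount))
  invisible(x)
}

#' Class-association t statistics for ratio features
#'
#' Two-sample t statistic per feature, sensitive minus insensitive, so a
#' positive statistic means the ratio runs higher in sensitive samples.
#' The Welch (unequal-variance) form is the default; `var_equal = TRUE`
#' gives the pooled-variance form. A feature with zero variance in both
#' classes and equal means gets t = 0.
#'
#' @param ratios A `ratio_set` (or plain features x samples matrix).
#' @param labels Sample labels (`"sensitive"`/`"insensitive"` or logical).
#' @param var_equal Pooled-variance variant flag.
#' @return Numeric vector of t statistics, one per feature.
#' @export
ratio_t_stats <- function(ratios, labels, var_equal = FALSE) {
  V <- if (inherits(ratios, "ratio_set")) ratios$values else ratios
  y <- as_binary_labels(labels)
  stopifnot(ncol(V) == length(y))
  if (sum(y) < 2 || sum(!y) < 2) stop("need >= 2 samples per class")
  t_stats_matrix(V, y, var_equal = var_equal)
}

#' Permutation p-values and q-values for ratio features
#'
#' Permutes the sample labels jointly across all features (preserving
#' inter-gene correlation) `n_permutations` times and recomputes the t
#' statistics. Per-feature p-values use +1-smoothed counting,
#' \eqn{p = (1 + \#\{|t_{perm}| \ge |t_{obs}|\}) / (1 + B)}; the pooled
#' mode counts exceedances across the whole feature family. q-values follow
#' the permutation plug-in estimator: expected null exceedances over
#' observed exceedances at each feature's |t|, clipped to \[0, 1\] with
#' monotonicity in |t| enforced.
#'
#' @param ratios A `ratio_set` with `values`, or a features x samples
#'   matrix.
#' @param labels Sample labels.
#' @param config A [grep_config()] (uses `n_permutations`, `var_equal`,
#'   `p_mode`, `seed`).
#' @return Data frame with columns `t`, `p`, `q` (one row per feature).
#' @export
permutation_significance <- function(ratios, labels, config = grep_config()) {
  V <- if (inherits(ratios, "ratio_set")) ratios$values else rbind(ratios)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("labels are degenerate (single class)")
  B <- config$n_permutations
  t_obs <- t_stats_matrix(V, y, var_equal = config$var_equal)
  T_perm <- withr::with_seed(config$seed,
    perm_t_matrix(V, y, B, var_equal = config$var_equal))
  abs_obs <- abs(t_obs)
  abs_perm <- abs(T_perm)
  f <- length(t_obs)
  pool <- sort(as.vector(abs_perm))
  if (config$p_mode == "per_feature") {
    exceed <- rowSums(abs_perm >= abs_obs)
    p <- (1 + exceed) / (1 + B)
  } else {
    p <- (1 + count_ge(pool, abs_obs)) / (1 + length(pool))
  }
  # q: E[#null >= t*] / #obs >= t*, monotone non-increasing in t*
  sorted_obs <- sort(abs_obs)
  R_obs <- count_ge(sorted_obs, abs_obs)        # observed exceedances
  E_null <- count_ge(pool, abs_obs) / B         # mean null exceedances
  fdr <- pmin(E_null / pmax(R_obs, 1), 1)
  ord <- order(abs_obs, decreasing = TRUE)
  q <- numeric(f)
  q[ord] <- rev(cummin(rev(fdr[ord])))          # q_i = min over t* <= |t_i|
  data.frame(t = t_obs, p = p, q = q)
}

#' Select and orient significant ratios
#'
#' Keeps features with q below the FDR cutoff and re-orients each retained
#' pair so its t statistic is positive (numerator gene up in sensitives),
#' negating the stored log-ratio values accordingly.
#'
#' @param ratios A `ratio_set`.
#' @param stats Data frame from [permutation_significance()].
#' @param fdr_cutoff q-value threshold (default 0.1).
#' @return A `ratio_set` whose `pairs` gains columns `t`, `p`, `q`,
#'   `oriented_positive` (all `TRUE`); may contain zero features.
#' @export
select_significant <- function(ratios, stats, fdr_cutoff = 0.1) {
  stopifnot(inherits(ratios, "ratio_set"),
            nrow(stats) == nrow(ratios$values))
  keep <- which(stats$q < fdr_cutoff)
  values <- ratios$values[keep, , drop = FALSE]
  pairs <- ratios$pairs[keep, , drop = FALSE]
  st <- stats[keep, , drop = FALSE]
  flip <- st$t < 0
  if (any(flip)) {
    values[flip, ] <- -values[flip, , drop = FALSE]
    tmp <- pairs$gene_num[flip]
    pairs$gene_num[flip] <- pairs$gene_den[flip]
    pairs$gene_den[flip] <- tmp
    st$t[flip] <- -st$t[flip]
  }
  pairs$t <- st$t
  pairs$p <- st$p
  pairs$q <- st$q
  pairs$oriented_positive <- rep(TRUE, nrow(pairs))
  rownames(values) <- paste(pairs$gene_num, pairs$gene_den, sep = "/")
  rownames(pairs) <- NULL
  structure(list(values = values, pairs = pairs,
                 pseudocount = ratios$pseudocount),
            class = "ratio_set")
}

#' Write a selected-ratio table as delimited text
#'
#' @param sig A selected `ratio_set` (with association columns), optionally
#'   carrying `cluster_id` / `is_exemplar` columns from clustering.
#' @param path Output path (tab-delimited).
#' @export
write_ratio_table <- function(sig, path) {
  utils::write.table(sig$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
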