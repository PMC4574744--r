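#' Pairwise similarity of ratio features
#'
#' Pearson correlation between the per-sample log-ratio vectors of every
#' pair of features; the similarity input to affinity propagation. A
#' zero-variance feature gets similarity 0 against all others (flagged via
#' a message).
#'
#' @param ratios A `ratio_set` or features x samples matrix (>= 2 features,
#'   >= 3 samples).
#' @return Symmetric similarity matrix in \[-1, 1\] with unit diagonal.
#' @export
ratio_similarity <- function(ratios) {
  V <- if (inherits(ratios, "ratio_set")) ratios$values else rbind(ratios)
  if (nrow(V) < 2) stop("need at least 2 features")
  if (ncol(V) < 3) stop("need at least 3 samples")
  sds <- apply(V, 1, sd)
  S <- matrix(0, nrow(V), nrow(V), dimnames = list(rownames(V), rownames(V)))
  ok <- sds > 0
  if (any(!ok)) message(sum(!ok), " zero-variance feature(s): similarity set to 0")
  if (sum(ok) >= 2) S[ok, ok] <- stats::cor(t(V[ok, , drop = FALSE]))
  diag(S) <- 1
  S
}

#' Affinity propagation clustering
#'
#' Message-passing exemplar clustering: responsibilities and availabilities
#' are exchanged between points until the exemplar set is stable. The
#' preference (self-similarity) defaults to the median off-diagonal
#' similarity. Ties are broken deterministically in favor of the
#' lower-indexed point (a vanishing index-ordered perturbation of the
#' preferences replaces the random jitter of the reference algorithm). If
#' the exemplar set does not stabilize within `max_iter` iterations, every
#' point becomes its own exemplar and the result is flagged unconverged.
#'
#' @param S Square symmetric similarity matrix (finite entries).
#' @param preference Self-similarity value(s); scalar or length-n. Default
#'   `NULL` = median of off-diagonal similarities.
#' @param damping Message damping factor in \[0.5, 1).
#' @param max_iter Maximum iterations.
#' @param convergence_window Consecutive iterations with an unchanged
#'   exemplar set required to declare convergence.
#' @return List of class `ap_result`: `cluster` (integer cluster id per
#'   point, numbered by exemplar order), `exemplars` (point indices),
#'   `assignment` (exemplar index per point), `converged`, `iterations`,
#'   `preference`.
#' @export
affinity_propagation <- function(S, preference = NULL, damping = 0.9,
                                 max_iter = 1000, convergence_window = 50) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (any(!is.finite(S))) stop("similarity matrix must be finite")
  if (max(abs(S - t(S))) > 1e-8) stop("similarity matrix must be symmetric")
  stopifnot(damping >= 0.5, damping < 1)
  n <- nrow(S)
  if (n == 1L) {
    return(structure(list(cluster = 1L, exemplars = 1L, assignment = 1L,
                          converged = TRUE, iterations = 0L,
                          preference = if (is.null(preference)) S[1, 1] else preference),
                     class = "ap_result"))
  }
  off <- S[row(S) != col(S)]
  if (is.null(preference)) preference <- median(off)
  pref <- rep_len(preference, n)
  W <- S
  # deterministic low-index tie-breaking: vanishing, strictly decreasing
  # perturbation of the preferences
  scale <- max(diff(range(c(off, pref))), 1e-12)
  diag(W) <- pref - (seq_len(n) - 1) * scale * 1e-9

  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  stable <- 0L
  prev_ex <- integer(0)
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    AS <- A + W
    max_idx <- max.col(AS, ties.method = "first")
    max1 <- AS[cbind(seq_len(n), max_idx)]
    AS[cbind(seq_len(n), max_idx)] <- -Inf
    max2 <- AS[cbind(seq_len(n), max.col(AS, ties.method = "first"))]
    Rnew <- W - max1
    Rnew[cbind(seq_len(n), max_idx)] <- W[cbind(seq_len(n), max_idx)] - max2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- rep(cs, each = n) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew

    ex <- which(diag(R) + diag(A) > 0)
    if (length(ex) > 0 && identical(ex, prev_ex)) {
      stable <- stable + 1L
      if (stable >= convergence_window) {
        converged <- TRUE
        break
      }
    } else {
      stable <- 0L
    }
    prev_ex <- ex
  }

  if (!converged || length(prev_ex) == 0) {
    # conservative fallback: no feature merging
    return(structure(list(cluster = seq_len(n), exemplars = seq_len(n),
                          assignment = seq_len(n), converged = FALSE,
                          iterations = it, preference = preference),
                     class = "ap_result"))
  }
  ex <- prev_ex
  # assignment: most similar exemplar (ties -> lowest exemplar index);
  # exemplars assign to themselves
  Sx <- W[, ex, drop = FALSE]
  assignment <- ex[max.col(Sx, ties.method = "first")]
  assignment[ex] <- ex
  cluster <- match(assignment, ex)
  structure(list(cluster = cluster, exemplars = ex, assignment = assignment,
                 converged = TRUE, iterations = it, preference = preference),
            class = "ap_result")
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("affinity propagation: %d points, %d cluster(s), %s in %d iterations\n",
              length(x$cluster), length(x$exemplars),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Cluster significant ratios and keep one exemplar per cluster
#'
#' Runs affinity propagation on the Pearson similarity of the selected
#' ratios and returns the exemplar features, ordered by descending |t|.
#'
#' @param sig A selected `ratio_set` (from [select_significant()]).
#' @param config A [grep_config()] supplying the AP controls.
#' @return A `ratio_set` of exemplars; `pairs` gains `cluster_id` and
#'   `cluster_size`; attribute `"ap"` holds the full `ap_result` and
#'   attribute `"clustered_pairs"` the per-feature cluster report.
#' @export
cluster_exemplars <- function(sig, config = grep_config()) {
  stopifnot(inherits(sig, "ratio_set"))
  nf <- nrow(sig$values)
  if (nf == 0) stop("no features to cluster")
  if (nf == 1) {
    ex <- sig
    ex$pairs$cluster_id <- 1L
    ex$pairs$cluster_size <- 1L
    full <- sig$pairs
    full$cluster_id <- 1L
    full$is_exemplar <- TRUE
    full$similarity_to_exemplar <- 1
    attr(ex, "ap") <- NULL
    attr(ex, "clustered_pairs") <- full
    return(ex)
  }
  S <- ratio_similarity(sig)
  ap <- affinity_propagation(S, preference = config$ap_preference,
                             damping = config$ap_damping,
                             max_iter = config$ap_max_iter,
                             convergence_window = config$ap_convergence_window)
  select_exemplars(sig, ap, similarity = S)
}

#' Extract exemplar features from a clustering
#'
#' @param sig The clustered `ratio_set`.
#' @param ap An `ap_result` for its features.
#' @param similarity Optional similarity matrix (for the cluster report).
#' @return A `ratio_set` of one exemplar per cluster, ordered by
#'   descending |t| (association strength).
#' @export
select_exemplars <- function(sig, ap, similarity = NULL) {
  stopifnot(inherits(sig, "ratio_set"), length(ap$cluster) == nrow(sig$values))
  ex_idx <- ap$exemplars
  tvals <- sig$pairs$t[ex_idx]
  ord <- order(-abs(tvals))
  ex_idx <- ex_idx[ord]
  out <- list(values = sig$values[ex_idx, , drop = FALSE],
              pairs = sig$pairs[ex_idx, , drop = FALSE],
              pseudocount = sig$pseudocount)
  out$pairs$cluster_id <- seq_along(ex_idx)
  out$pairs$cluster_size <- as.integer(table(ap$cluster)[as.character(ap$cluster[ex_idx])])
  rownames(out$pairs) <- NULL
  class(out) <- "ratio_set"
  full <- sig$pairs
  full$cluster_id <- match(ap$assignment, ex_idx)
  full$is_exemplar <- seq_len(nrow(full)) %in% ex_idx
  full$similarity_to_exemplar <- if (is.null(similarity)) NA_real_ else
    similarity[cbind(seq_len(nrow(full)), ap$assignment)]
  attr(out, "ap") <- ap
  attr(out, "clustered_pairs") <- full
  out
}

#' Write the per-feature cluster report
#'
#' @param exemplars Result of [cluster_exemplars()].
#' @param path Output path (tab-delimited: feature, cluster_id,
#'   is_exemplar, similarity_to_exemplar).
#' @export
write_cluster_report <- function(exemplars, path) {
  rep <- attr(exemplars, "clustered_pairs")
  if (is.null(rep)) stop("no cluster report attached")
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
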