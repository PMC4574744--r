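#' Differential association of features with sensitivity
#'
#' Numeric features (expression, copy number) are tested with a two-sample
#' t-test (Welch), binary/categorical features (mutation, lineage
#' membership) with a two-sided Fisher's exact test; all p-values within
#' the call are adjusted by Benjamini-Hochberg.
#'
#' @param features Features x samples numeric matrix (binary features coded
#'   0/1).
#' @param labels Sample labels.
#' @param kinds Character vector per feature: `"expression"`,
#'   `"copy_number"` (numeric path) or `"mutation"`, `"lineage"` (Fisher
#'   path). Default all `"expression"`.
#' @return Data frame: `feature_id`, `feature_kind`, `statistic` (t or odds
#'   ratio), `p_value`, `bh_fdr`, ranked by p. Constant features get p = 1
#'   and are flagged in `degenerate`.
#' @export
differential_association <- function(features, labels, kinds = NULL) {
  V <- rbind(features)
  y <- as_binary_labels(labels)
  stopifnot(ncol(V) == length(y))
  f <- nrow(V)
  if (is.null(kinds)) kinds <- rep("expression", f)
  stopifnot(length(kinds) == f)
  numeric_kind <- kinds %in% c("expression", "copy_number")
  stat <- p <- rep(NA_real_, f)
  degenerate <- logical(f)
  if (any(numeric_kind)) {
    Vn <- V[numeric_kind, , drop = FALSE]
    stat[numeric_kind] <- t_stats_matrix(Vn, y)
    p[numeric_kind] <- welch_p_matrix(Vn, y)
    const <- apply(Vn, 1, function(v) var(v) == 0)
    p[numeric_kind][const] <- 1
    stat[numeric_kind][const] <- 0
    degenerate[numeric_kind] <- const
  }
  for (i in which(!numeric_kind)) {
    v <- V[i, ] != 0
    if (length(unique(v)) < 2) {
      p[i] <- 1
      stat[i] <- NA_real_
      degenerate[i] <- TRUE
      next
    }
    tab <- table(factor(v, c(TRUE, FALSE)), factor(y, c(TRUE, FALSE)))
    ft <- fisher.test(tab)
    p[i] <- ft$p.value
    stat[i] <- unname(ft$estimate)
  }
  out <- data.frame(
    feature_id = if (is.null(rownames(V))) as.character(seq_len(f)) else rownames(V),
    feature_kind = kinds, statistic = stat, p_value = p,
    bh_fdr = p.adjust(p, method = "BH"), degenerate = degenerate,
    stringsAsFactors = FALSE)
  out[order(out$p_value), ]
}

#' Two-gene median-threshold classifier
#'
#' Calls a sample sensitive when both genes are strictly above their
#' per-gene training medians (e.g. the DR5 + CASP8 rule). For ranking, the
#' continuous score is `min(x_a - median_a, x_b - median_b)`: it crosses 0
#' exactly at the binary decision boundary and orders samples by how far
#' they clear both thresholds.
#'
#' @param X Training expression matrix.
#' @param labels Training labels.
#' @param gene_a,gene_b The two genes (default `"TNFRSF10B"`, `"CASP8"`).
#' @return Object of class `two_gene_model` with `genes`, `medians`; use
#'   [predict.two_gene_model()].
#' @export
two_gene_classifier <- function(X, labels, gene_a = "TNFRSF10B",
                                gene_b = "CASP8") {
  validate_expression_matrix(X)
  missing <- setdiff(c(gene_a, gene_b), rownames(X))
  if (length(missing) > 0) {
    stop("gene(s) absent: ", paste(missing, collapse = ", "))
  }
  structure(list(genes = c(gene_a, gene_b),
                 medians = c(median(X[gene_a, ]), median(X[gene_b, ]))),
            class = "two_gene_model")
}

#' @export
#' @rdname two_gene_classifier
#' @param object A `two_gene_model`.
#' @param newdata Expression matrix to score.
#' @param ... Unused.
predict.two_gene_model <- function(object, newdata, ...) {
  validate_expression_matrix(newdata)
  a <- newdata[object$genes[1], ] - object$medians[1]
  b <- newdata[object$genes[2], ] - object$medians[2]
  score <- pmin(a, b)
  data.frame(sample_id = colnames(newdata), score = unname(score),
             call = ifelse(score > 0, "sensitive", "insensitive"),
             stringsAsFactors = FALSE)
}

# Internal: single-gene log-expression feature set shaped like a ratio_set,
# so the selection/clustering/regression pipeline applies unchanged.
gene_feature_set <- function(X, genes, pseudocount) {
  genes <- sort(intersect(genes, rownames(X)))
  if (length(genes) < 1) stop("no genes available")
  values <- log(X[genes, , drop = FALSE] + pseudocount)
  structure(list(values = values,
                 pairs = data.frame(gene_num = genes,
                                    gene_den = rep("", length(genes)),
                                    stringsAsFactors = FALSE),
                 pseudocount = pseudocount), class = "ratio_set")
}

# Internal: fit one ablation variant on training data; returns an object
# with a predict_prob(X_new) closure so cv loops stay uniform.
fit_variant <- function(X, y, hypothesis_genes, config, variant) {
  if (variant == "grep") {
    m <- fit_grep(X, y, hypothesis_genes, config)
    return(list(predict_prob = function(Xn) predict(m, Xn)$probability,
                model = m))
  }
  if (variant == "two_gene") {
    # data-driven gene choice: top-2 genes by differential expression on
    # the training samples (mirrors picking the two top-ranked genes)
    Xf <- filter_genes(X, config$pct75_min, config$iqr_min)
    da <- differential_association(log(Xf + config$pseudocount), y)
    top <- da$feature_id[1:2]
    m <- two_gene_classifier(X, y, top[1], top[2])
    return(list(predict_prob = function(Xn) {
      sc <- predict(m, Xn)$score
      plogis(sc / max(stats::mad(sc), 1e-8))  # monotone squashing to [0,1]
    }, model = m))
  }
  # single-gene-feature pipelines
  Xf <- tryCatch(filter_genes(X, config$pct75_min, config$iqr_min),
                 error = function(e) NULL)
  intercept_only <- function() {
    p0 <- mean(y)
    list(predict_prob = function(Xn) rep(p0, ncol(Xn)), model = NULL)
  }
  if (is.null(Xf)) return(intercept_only())
  genes <- switch(variant,
    gene_all = rownames(Xf),
    gene_hyp = intersect(hypothesis_genes, rownames(Xf)),
    ratio_select_gene = intersect(hypothesis_genes, rownames(Xf)),
    stop("unknown variant ", variant))
  if (length(genes) < 2) return(intercept_only())

  if (variant == "ratio_select_gene") {
    # ratio-based feature selection, single-gene classification
    ratios <- compute_log_ratios(Xf, genes, config$pseudocount)
    st <- permutation_significance(ratios, y, config)
    sig <- select_significant(ratios, st, config$fdr_cutoff)
    if (nrow(sig$values) == 0) return(intercept_only())
    ex <- cluster_exemplars(sig, config)
    sel_genes <- sort(unique(c(ex$pairs$gene_num, ex$pairs$gene_den)))
    feats <- gene_feature_set(Xf, sel_genes, config$pseudocount)
  } else {
    fs <- gene_feature_set(Xf, genes, config$pseudocount)
    st <- permutation_significance(fs, y, config)
    sig <- select_significant(fs, st, config$fdr_cutoff)
    if (nrow(sig$values) == 0) return(intercept_only())
    ex <- cluster_exemplars(sig, config)
    feats <- ex
  }
  fit <- ridge_logistic(t(feats$values), as.numeric(y),
                        lambda = config$ridge_lambda)
  c_ <- config$pseudocount
  # gene features selected through select_significant() may have been
  # sign-flipped (stored as -log(x+c), with the gene moved to gene_den);
  # reproduce the same transform at prediction time
  num_is_gene <- feats$pairs$gene_num != ""
  sel <- ifelse(num_is_gene, feats$pairs$gene_num, feats$pairs$gene_den)
  sgn <- ifelse(num_is_gene, 1, -1)
  list(predict_prob = function(Xn) {
    missing <- setdiff(sel, rownames(Xn))
    if (length(missing) > 0) stop("gene(s) absent: ", paste(missing, collapse = ", "))
    V <- sgn * log(Xn[sel, , drop = FALSE] + c_)
    plogis(fit$intercept + drop(crossprod(V, fit$coef)))
  }, model = list(genes = sel, fit = fit))
}

#' Cross-validated comparison of GREP against its ablations
#'
#' Runs the same stratified folds over five classifiers: GREP (hypothesis
#' genes, ratio features), a standard single-gene classifier over all
#' genes, the same over the hypothesis genes, a hybrid that selects
#' features as ratios but classifies on the component genes, and the
#' two-gene median rule. Each variant swaps exactly one pipeline stage.
#'
#' @param X Expression matrix.
#' @param labels Sample labels.
#' @param hypothesis_genes Candidate gene set.
#' @param config A [grep_config()].
#' @param k Folds (default 5).
#' @return Data frame: `model`, `auc`, `ppv`, `auc_lo`, `auc_hi` (95% CI
#'   from fold dispersion), with attribute `"oof"` holding the out-of-fold
#'   probabilities per variant.
#' @export
ablation_suite <- function(X, labels, hypothesis_genes,
                           config = grep_config(), k = 5) {
  y <- as_binary_labels(labels)
  folds <- withr::with_seed(config$seed, stratified_folds(y, k))
  variants <- c("grep", "gene_all", "gene_hyp", "ratio_select_gene",
                "two_gene")
  oof <- matrix(NA_real_, length(y), length(variants),
                dimnames = list(colnames(X), variants))
  for (f in sort(unique(folds))) {
    test <- folds == f
    cfg_f <- config
    cfg_f$seed <- config$seed + 7919L * f
    for (v in variants) {
      m <- fit_variant(X[, !test, drop = FALSE], y[!test],
                       hypothesis_genes, cfg_f, v)
      oof[test, v] <- m$predict_prob(X[, test, drop = FALSE])
    }
  }
  rows <- lapply(variants, function(v) {
    me <- compute_metrics(oof[, v], y, threshold = config$threshold)
    fold_auc <- vapply(sort(unique(folds)), function(f) {
      idx <- folds == f
      if (length(unique(y[idx])) < 2) return(NA_real_)
      auc_roc(oof[idx, v], y[idx])
    }, 0)
    se <- sd(fold_auc, na.rm = TRUE) / sqrt(sum(!is.na(fold_auc)))
    data.frame(model = v, auc = me$auc, ppv = me$ppv,
               auc_lo = me$auc - 1.96 * se, auc_hi = me$auc + 1.96 * se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "oof") <- oof
  attr(out, "folds") <- folds
  out
}

#' GREP performance over random gene sets
#'
#' Refits the full pipeline under cross-validation for `n_sets` random
#' gene sets of the given size drawn from the filtered genes, returning
#' the AUC distribution and the fraction of models whose out-of-fold
#' confusion table associates significantly with the labels (one-sided
#' Fisher's exact test at 0.05).
#'
#' @param X Expression matrix.
#' @param labels Sample labels.
#' @param set_size Genes per random set.
#' @param n_sets Number of random sets (default 100).
#' @param config A [grep_config()].
#' @param k Folds.
#' @param exclude Genes never to sample (e.g. known signal genes).
#' @return Data frame with one row per set: `set`, `auc`, `ppv`,
#'   `fisher_p`, `significant`.
#' @export
random_geneset_control <- function(X, labels, set_size, n_sets = 100,
                                   config = grep_config(), k = 5,
                                   exclude = character(0)) {
  if (n_sets == 0) {
    return(data.frame(set = integer(0), auc = numeric(0), ppv = numeric(0),
                      fisher_p = numeric(0), significant = logical(0)))
  }
  y <- as_binary_labels(labels)
  pool <- setdiff(rownames(X), exclude)
  stopifnot(set_size <= length(pool))
  sets <- withr::with_seed(config$seed + 104729L, {
    lapply(seq_len(n_sets), function(i) sample(pool, set_size))
  })
  rows <- lapply(seq_len(n_sets), function(i) {
    cfg_i <- config
    cfg_i$seed <- config$seed + 31L * i
    cv <- cross_validate(X, y, sets[[i]], cfg_i, k = k)
    pred <- cv$samples$probability > config$threshold
    a <- sum(pred & y); b <- sum(pred & !y)
    c_ <- sum(!pred & y); d <- sum(!pred & !y)
    p <- fisher_exact_p(a, b, c_, d, "greater")
    data.frame(set = i, auc = cv$auc, ppv = cv$ppv, fisher_p = p,
               significant = p < 0.05, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Downsampling rank simulation for a single gene
#'
#' Repeatedly subsamples the cohort without replacement (preserving class
#' prevalence), reruns all-gene differential expression, and records where
#' the focal gene ranks and whether its p-value clears 0.05 — quantifying
#' how detectable a marker is at reduced screen sizes.
#'
#' @param X Expression matrix.
#' @param labels Sample labels.
#' @param gene Focal gene.
#' @param subset_sizes Cohort sizes to test (default `c(100, 200)`).
#' @param n_reps Replicates per size (default 50).
#' @param seed Integer seed.
#' @return Data frame per size: `subset_size`, `mean_rank`, `median_rank`,
#'   `frac_significant`; attribute `"reps"` has per-replicate ranks.
#' @export
downsampling_rank_simulation <- function(X, labels, gene,
                                         subset_sizes = c(100, 200),
                                         n_reps = 50, seed = 1) {
  validate_expression_matrix(X)
  if (!gene %in% rownames(X)) stop("gene absent: ", gene)
  y <- as_binary_labels(labels)
  n <- length(y)
  stopifnot(all(subset_sizes <= n))
  L <- log(X + 1)
  reps <- withr::with_seed(seed, {
    do.call(rbind, lapply(subset_sizes, function(m) {
      prop <- mean(y)
      n1 <- max(2, round(m * prop))
      n0 <- m - n1
      do.call(rbind, lapply(seq_len(n_reps), function(r) {
        idx <- c(sample(which(y), n1), sample(which(!y), n0))
        p <- welch_p_matrix(L[, idx, drop = FALSE], y[idx])
        rk <- rank(p, ties.method = "min")[gene]
        data.frame(subset_size = m, rep = r, rank = unname(rk),
                   p = unname(p[gene]), stringsAsFactors = FALSE)
      }))
    }))
  })
  out <- do.call(rbind, lapply(split(reps, reps$subset_size), function(d) {
    data.frame(subset_size = d$subset_size[1], mean_rank = mean(d$rank),
               median_rank = median(d$rank),
               frac_significant = mean(d$p < 0.05), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "reps") <- reps
  out
}
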