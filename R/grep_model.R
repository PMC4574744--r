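#' Fit a GREP gene-ratio classifier
#'
#' End-to-end training: gene filtering (expression level and dynamic
#' range), all pairwise log-ratios over the hypothesis genes, t-statistic
#' association with permutation p/q-values, selection at the FDR cutoff,
#' affinity propagation clustering of the significant ratios, and a
#' ridge-penalized logistic regression on the cluster exemplars. Training
#' is deterministic given `config$seed`.
#'
#' If no ratio passes the FDR cutoff the returned model is intercept-only
#' and flagged `no_signal`.
#'
#' @param X Expression matrix (genes x samples, non-negative linear scale).
#' @param labels Per-sample labels, `"sensitive"`/`"insensitive"`
#'   (intermediates must be excluded upstream).
#' @param hypothesis_genes Character vector of candidate genes.
#' @param config A [grep_config()].
#' @return Object of class `grep_model`: `pairs` (exemplar ratios,
#'   oriented), `coef`, `intercept`, `pseudocount`, `log_base`,
#'   `threshold`, `seed`, `filter` settings, `no_signal`, `ap_converged`,
#'   `significant` (full selected-ratio table with cluster report),
#'   `train_prob` (training-sample probabilities).
#' @export
fit_grep <- function(X, labels, hypothesis_genes, config = grep_config()) {
  validate_expression_matrix(X)
  y <- as_binary_labels(labels)
  stopifnot(ncol(X) == length(y))
  if (length(hypothesis_genes) == 0) stop("hypothesis gene set is empty")

  model <- structure(list(
    pairs = data.frame(gene_num = character(0), gene_den = character(0)),
    coef = numeric(0),
    intercept = stats::qlogis(max(min(mean(y), 1 - 1e-6), 1e-6)),
    pseudocount = config$pseudocount, log_base = "natural",
    threshold = config$threshold, seed = config$seed,
    filter = list(pct75_min = config$pct75_min, iqr_min = config$iqr_min),
    ridge_lambda = config$ridge_lambda,
    no_signal = TRUE, ap_converged = NA,
    significant = NULL, train_prob = NULL), class = "grep_model")

  Xf <- tryCatch(filter_genes(X, config$pct75_min, config$iqr_min),
                 error = function(e) NULL)
  if (is.null(Xf)) return(finish_intercept_only(model, X, y))
  genes <- intersect(hypothesis_genes, rownames(Xf))
  if (length(genes) < 2) return(finish_intercept_only(model, X, y))

  ratios <- compute_log_ratios(Xf, genes, config$pseudocount)
  stats <- permutation_significance(ratios, y, config)
  sig <- select_significant(ratios, stats, config$fdr_cutoff)
  if (nrow(sig$values) == 0) return(finish_intercept_only(model, X, y))

  ex <- cluster_exemplars(sig, config)
  ap <- attr(ex, "ap")
  fit <- ridge_logistic(t(ex$values), as.numeric(y),
                        lambda = config$ridge_lambda)
  if (config$ridge_lambda == 0 && any(abs(fit$coef) > 1e3)) {
    warning("possible complete separation: coefficients are very large; ",
            "consider ridge_lambda > 0")
  }

  model$pairs <- ex$pairs
  model$coef <- unname(fit$coef)
  model$intercept <- unname(fit$intercept)
  model$no_signal <- FALSE
  model$ap_converged <- if (is.null(ap)) TRUE else ap$converged
  model$significant <- attr(ex, "clustered_pairs")
  model$train_prob <- predict(model, X)$probability
  model
}

# Internal: intercept-only "no signal" model completion.
finish_intercept_only <- function(model, X, y) {
  model$train_prob <- rep(plogis(model$intercept), ncol(X))
  names(model$train_prob) <- colnames(X)
  model
}

#' @export
print.grep_model <- function(x, ...) {
  if (x$no_signal) {
    cat("GREP model: intercept-only (no significant ratios)\n")
  } else {
    cat(sprintf("GREP model: %d exemplar ratio(s), pseudocount %g, threshold %g\n",
                nrow(x$pairs), x$pseudocount, x$threshold))
    print(utils::head(data.frame(ratio = paste(x$pairs$gene_num,
                                               x$pairs$gene_den, sep = "/"),
                                 coef = x$coef), 10))
  }
  invisible(x)
}

#' Predict sensitivity from expression with a fitted GREP model
#'
#' Applies the model to new expression values directly: the stored log-
#' ratios are computed with the training pseudocount and combined through
#' the logistic coefficients. No rescaling or re-normalization of the new
#' matrix is performed (by design: ratio features make the model portable
#' across platforms with different per-sample scales).
#'
#' @param object A `grep_model`.
#' @param newdata Expression matrix containing every model gene (missing
#'   genes raise an error naming them).
#' @param ... Unused.
#' @return Data frame: `sample_id`, `probability`, `call`.
#' @export
predict.grep_model <- function(object, newdata, ...) {
  validate_expression_matrix(newdata)
  if (nrow(object$pairs) > 0) {
    need <- unique(c(object$pairs$gene_num, object$pairs$gene_den))
    missing <- setdiff(need, rownames(newdata))
    if (length(missing) > 0) {
      stop("model gene(s) absent from new data: ",
           paste(missing, collapse = ", "))
    }
    c_ <- object$pseudocount
    # quotient-then-log keeps c = 0 predictions exactly invariant when a
    # sample is rescaled by a power of two (the quotient is unchanged)
    V <- log((newdata[object$pairs$gene_num, , drop = FALSE] + c_) /
             (newdata[object$pairs$gene_den, , drop = FALSE] + c_))
    eta <- object$intercept + drop(crossprod(V, object$coef))
  } else {
    eta <- rep(object$intercept, ncol(newdata))
  }
  prob <- plogis(eta)
  data.frame(sample_id = colnames(newdata), probability = unname(prob),
             call = ifelse(prob > object$threshold, "sensitive", "insensitive"),
             stringsAsFactors = FALSE)
}

#' Stratified k-fold cross-validation of the full GREP pipeline
#'
#' Every training step — gene filtering, ratio computation, permutation
#' selection, clustering and regression — is refit inside each training
#' fold; metrics are computed only on the pooled out-of-fold predictions.
#' Folds are stratified by class.
#'
#' @param X Expression matrix.
#' @param labels Sample labels.
#' @param hypothesis_genes Candidate gene set.
#' @param config A [grep_config()].
#' @param k Number of folds (default 5).
#' @param folds Optional pre-computed integer fold assignment (length =
#'   samples); when supplied it is used as-is (enables paired comparisons).
#' @return Object of class `cv_report`: `samples` (data frame `sample_id`,
#'   `label`, `fold`, `probability`, `call`), `auc`, `ppv`, `recall`,
#'   `roc` (pooled ROC points), `fold_metrics` (per-fold AUC and ROC),
#'   `folds`, `config`.
#' @export
cross_validate <- function(X, labels, hypothesis_genes,
                           config = grep_config(), k = 5, folds = NULL) {
  validate_expression_matrix(X)
  y <- as_binary_labels(labels)
  n <- ncol(X)
  stopifnot(length(y) == n)
  if (min(sum(y), sum(!y)) < k) {
    stop("each class needs at least k = ", k, " samples for stratification")
  }
  if (is.null(folds)) {
    folds <- withr::with_seed(config$seed, stratified_folds(y, k))
  }
  stopifnot(length(folds) == n)
  prob <- rep(NA_real_, n)
  for (f in sort(unique(folds))) {
    test <- folds == f
    cfg_f <- config
    cfg_f$seed <- config$seed + 7919L * f  # per-fold deterministic stream
    m <- fit_grep(X[, !test, drop = FALSE], y[!test], hypothesis_genes, cfg_f)
    prob[test] <- predict(m, X[, test, drop = FALSE])$probability
  }
  calls <- ifelse(prob > config$threshold, "sensitive", "insensitive")
  metrics <- compute_metrics(prob, y, threshold = config$threshold)
  fold_metrics <- lapply(sort(unique(folds)), function(f) {
    idx <- folds == f
    a <- if (length(unique(y[idx])) == 2) auc_roc(prob[idx], y[idx]) else NA_real_
    list(fold = f, auc = a)
  })
  structure(list(
    samples = data.frame(sample_id = colnames(X),
                         label = ifelse(y, "sensitive", "insensitive"),
                         fold = folds, probability = prob, call = calls,
                         stringsAsFactors = FALSE),
    auc = metrics$auc, ppv = metrics$ppv, recall = metrics$recall,
    roc = metrics$roc,
    fold_metrics = do.call(rbind, lapply(fold_metrics, as.data.frame)),
    folds = folds, config = config), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("GREP cross-validation: %d samples, %d folds\n",
              nrow(x$samples), length(unique(x$folds))))
  cat(sprintf("  pooled out-of-fold AUC = %.3f, PPV = %s, recall = %.3f\n",
              x$auc, ifelse(is.na(x$ppv), "undefined", sprintf("%.3f", x$ppv)),
              x$recall))
  invisible(x)
}

#' Classification metrics from probabilities and labels
#'
#' PPV is the fraction of predicted sensitives that are truly sensitive
#' (undefined, `NA`, when nothing is predicted sensitive); recall the
#' fraction of sensitives predicted; AUC the midrank Mann-Whitney
#' concordance (equal to the trapezoidal ROC area). ROC points are listed
#' over descending probability thresholds.
#'
#' @param probabilities Numeric prediction scores in \[0, 1\].
#' @param labels Sample labels.
#' @param threshold Call cutoff (default 0.5).
#' @return List: `ppv`, `auc`, `recall`, `n_predicted_sensitive`, `roc`
#'   (data frame `threshold`, `fpr`, `tpr`).
#' @export
compute_metrics <- function(probabilities, labels, threshold = 0.5) {
  y <- as_binary_labels(labels)
  stopifnot(length(probabilities) == length(y))
  pred <- probabilities > threshold
  npred <- sum(pred)
  ppv <- if (npred == 0) NA_real_ else sum(pred & y) / npred
  recall <- if (sum(y) == 0) NA_real_ else sum(pred & y) / sum(y)
  auc <- if (length(unique(y)) == 2) auc_roc(probabilities, y) else NA_real_
  thr <- c(Inf, sort(unique(probabilities), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(probabilities[!y] >= t), 0),
    tpr = vapply(thr, function(t) mean(probabilities[y] >= t), 0))
  list(ppv = ppv, auc = auc, recall = recall,
       n_predicted_sensitive = npred, roc = roc)
}

#' Train/test evaluation across independent screens
#'
#' Fits on one screen's samples and evaluates on another's, removing test
#' samples shared with the training screen first (so the test set is truly
#' independent).
#'
#' @param X_train,labels_train Training expression matrix and labels.
#' @param X_test,labels_test Test expression matrix and labels.
#' @param hypothesis_genes Candidate gene set.
#' @param config A [grep_config()].
#' @return List: `model`, `predictions`, `metrics`, `n_removed` (shared
#'   samples dropped from the test set).
#' @export
screen_split_evaluate <- function(X_train, labels_train, X_test, labels_test,
                                  hypothesis_genes, config = grep_config()) {
  shared <- intersect(colnames(X_train), colnames(X_test))
  keep <- !(colnames(X_test) %in% shared)
  if (!any(keep)) stop("no independent test samples remain")
  X_test <- X_test[, keep, drop = FALSE]
  labels_test <- labels_test[keep]
  m <- fit_grep(X_train, labels_train, hypothesis_genes, config)
  pr <- predict(m, X_test)
  list(model = m, predictions = pr,
       metrics = compute_metrics(pr$probability, labels_test,
                                 threshold = config$threshold),
       n_removed = length(shared))
}

#' Serialize a GREP model to structured text
#'
#' Writes a self-contained JSON document recording the exemplar ratios
#' (gene orientation), coefficients, intercept, pseudocount, log base,
#' threshold and seed at full floating-point precision, so a reloaded
#' model reproduces predictions bit-for-bit.
#'
#' @param model A `grep_model`.
#' @param path Output path.
#' @export
write_grep_model <- function(model, path) {
  doc <- list(
    format = "grep_model", version = 1L,
    pairs = model$pairs[, c("gene_num", "gene_den"), drop = FALSE],
    coef = model$coef, intercept = model$intercept,
    pseudocount = model$pseudocount, log_base = model$log_base,
    threshold = model$threshold, seed = model$seed,
    filter = model$filter, ridge_lambda = model$ridge_lambda,
    no_signal = model$no_signal, ap_converged = model$ap_converged)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null", na = "null")
}

#' Load a serialized GREP model
#'
#' @param path Path written by [write_grep_model()].
#' @return A `grep_model`.
#' @export
read_grep_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "grep_model")) stop("not a grep_model file")
  pairs <- as.data.frame(doc$pairs, stringsAsFactors = FALSE)
  if (is.null(pairs$gene_num)) {
    pairs <- data.frame(gene_num = character(0), gene_den = character(0))
  }
  structure(list(
    pairs = pairs, coef = as.numeric(doc$coef),
    intercept = as.numeric(doc$intercept),
    pseudocount = as.numeric(doc$pseudocount),
    log_base = doc$log_base, threshold = as.numeric(doc$threshold),
    seed = doc$seed,
    filter = doc$filter, ridge_lambda = doc$ridge_lambda,
    no_signal = doc$no_signal, ap_converged = doc$ap_converged,
    significant = NULL, train_prob = NULL), class = "grep_model")
}
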