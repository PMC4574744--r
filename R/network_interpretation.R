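#' Build the ratio network from significant ratios
#'
#' Genes become nodes, positively oriented significant ratios become
#' oriented edges (numerator -> denominator). Each node records its degree
#' (number of significant ratios containing the gene) and its positivity —
#' the fraction of those ratios in which it is the numerator, so 1 marks a
#' positive regulator of response and 0 a negative one. Edges belonging to
#' the fitted classifier are flagged `in_model`.
#'
#' @param significant_ratios Data frame with columns `gene_num`,
#'   `gene_den`, `t` (all t > 0: positively oriented) — e.g. the `pairs`
#'   of a selected `ratio_set`.
#' @param model_ratios Optional data frame of the classifier's exemplar
#'   pairs (`gene_num`, `gene_den`).
#' @return Object of class `ratio_network`: `nodes` (data frame `gene`,
#'   `degree`, `n_numerator`, `n_denominator`, `positivity`), `edges`
#'   (data frame `gene_num`, `gene_den`, `t`, `in_model`).
#' @export
build_ratio_network <- function(significant_ratios, model_ratios = NULL) {
  ed <- significant_ratios
  stopifnot(all(c("gene_num", "gene_den") %in% names(ed)))
  if (!is.null(ed$t) && any(ed$t < 0)) {
    stop("ratios must be positively oriented (t > 0) before network construction")
  }
  genes <- sort(unique(c(ed$gene_num, ed$gene_den)))
  n_num <- table(factor(ed$gene_num, genes))
  n_den <- table(factor(ed$gene_den, genes))
  nodes <- data.frame(
    gene = genes,
    degree = as.integer(n_num + n_den),
    n_numerator = as.integer(n_num),
    n_denominator = as.integer(n_den),
    stringsAsFactors = FALSE)
  nodes$positivity <- nodes$n_numerator / nodes$degree
  key <- function(d) paste(d$gene_num, d$gene_den, sep = "/")
  edges <- data.frame(gene_num = ed$gene_num, gene_den = ed$gene_den,
                      t = if (is.null(ed$t)) NA_real_ else ed$t,
                      stringsAsFactors = FALSE)
  edges$in_model <- if (is.null(model_ratios)) FALSE else
    key(edges) %in% key(model_ratios)
  structure(list(nodes = nodes, edges = edges), class = "ratio_network")
}

#' @export
print.ratio_network <- function(x, ...) {
  cat(sprintf("ratio network: %d genes, %d oriented ratios (%d in model)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$in_model)))
  invisible(x)
}

#' Export a ratio network
#'
#' Writes the oriented edge list as tab-delimited text and, optionally, a
#' GraphML document with the node attributes (degree, positivity).
#'
#' @param network A `ratio_network`.
#' @param edges_path Path for the edge-list text file.
#' @param graphml_path Optional path for a GraphML export.
#' @export
write_ratio_network <- function(network, edges_path, graphml_path = NULL) {
  utils::write.table(network$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      network$edges, directed = TRUE,
      vertices = network$nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(network)
}

#' Rebuild a ratio network from a written edge list
#'
#' @param edges_path Path written by [write_ratio_network()].
#' @return A `ratio_network` equal to the original.
#' @export
read_ratio_network <- function(edges_path) {
  ed <- utils::read.delim(edges_path, stringsAsFactors = FALSE)
  net <- build_ratio_network(ed)
  net$edges$in_model <- ed$in_model
  net
}

#' Leave-one-gene-out importance by cross-validated AUC
#'
#' Compares the full pipeline's cross-validation AUC to that of reduced
#' models, each fit with one gene removed from the hypothesis set. Within
#' a repeat, folds are held fixed across all runs so fold-level deltas are
#' paired and reflect gene removal, not fold noise; `n_repeats` > 1 re-runs
#' the comparison over fresh fold partitions (deterministically seeded) to
#' stabilize the estimate. The per-gene z score is the mean fold-level AUC
#' delta divided by its standard error across the pooled fold deltas;
#' genes with z > 1 are flagged important.
#'
#' @param X Expression matrix.
#' @param labels Sample labels.
#' @param hypothesis_genes Candidate gene set (>= 3 genes).
#' @param config A [grep_config()].
#' @param k Folds.
#' @param genes Genes to eliminate (default: all of `hypothesis_genes`;
#'   supply a subset to bound runtime).
#' @param n_repeats Independent CV repetitions pooled per gene (default 1).
#' @return Data frame: `gene`, `auc_full`, `auc_without`, `delta`
#'   (`auc_full - auc_without`, averaged over repeats), `z`, `flagged`;
#'   one row per eliminated gene (sorted by gene).
#' @export
gene_elimination_importance <- function(X, labels, hypothesis_genes,
                                        config = grep_config(), k = 5,
                                        genes = NULL, n_repeats = 1) {
  stopifnot(length(hypothesis_genes) >= 3, n_repeats >= 1)
  y <- as_binary_labels(labels)
  if (is.null(genes)) genes <- hypothesis_genes
  genes <- sort(genes)
  d_folds <- matrix(0, length(genes), 0)
  auc_full <- auc_without <- matrix(NA_real_, length(genes), n_repeats)
  full_first <- NULL
  for (r in seq_len(n_repeats)) {
    cfg_r <- config
    cfg_r$seed <- config$seed + 6151L * (r - 1L)
    folds <- withr::with_seed(cfg_r$seed, stratified_folds(y, k))
    full <- cross_validate(X, y, hypothesis_genes, cfg_r, k = k,
                           folds = folds)
    if (r == 1L) full_first <- full
    fold_auc <- function(cv) {
      vapply(sort(unique(folds)), function(f) {
        idx <- folds == f
        auc_roc(cv$samples$probability[idx], y[idx])
      }, 0)
    }
    fa_full <- fold_auc(full)
    d_r <- t(vapply(seq_along(genes), function(i) {
      cv_g <- cross_validate(X, y, setdiff(hypothesis_genes, genes[i]),
                             cfg_r, k = k, folds = folds)
      auc_full[i, r] <<- full$auc
      auc_without[i, r] <<- cv_g$auc
      fa_full - fold_auc(cv_g)
    }, numeric(k)))
    d_folds <- cbind(d_folds, d_r)
  }
  rows <- lapply(seq_along(genes), function(i) {
    di <- d_folds[i, ]
    delta <- mean(auc_full[i, ] - auc_without[i, ])
    se <- sd(di) / sqrt(length(di))
    z <- mean(di) / max(se, 1e-12)
    data.frame(gene = genes[i], auc_full = mean(auc_full[i, ]),
               auc_without = mean(auc_without[i, ]),
               delta = delta, z = z, flagged = z > 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_cv") <- full_first
  attr(out, "fold_deltas") <- d_folds
  out
}
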