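#' Read an expression matrix from delimited text
#'
#' Reads a genes-x-samples matrix from TSV/CSV (first column = gene or probe
#' id, header row of sample ids) or from a GCT 1.2 file (leading `#1.2` and
#' dimension lines tolerated; the `Description` column is dropped).
#'
#' @param path Path to the file.
#' @param sep Field separator; guessed from the extension when `NULL`
#'   (`.csv` = comma, otherwise tab).
#' @return Numeric matrix, genes as rows (rownames), samples as columns.
#' @export
read_expression_matrix <- function(path, sep = NULL) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#1.2")) {
    df <- utils::read.delim(path, skip = 2, check.names = FALSE,
                            stringsAsFactors = FALSE)
    ids <- df[[1]]
    drop <- c(1L, which(tolower(names(df)) == "description"))
    df <- df[, -drop, drop = FALSE]
  } else {
    if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- df[[1]]
    df <- df[, -1, drop = FALSE]
  }
  X <- as.matrix(df)
  mode(X) <- "numeric"
  rownames(X) <- ids
  validate_expression_matrix(X)
  X
}

#' Write an expression matrix as tab-delimited text
#'
#' @param X Numeric genes-x-samples matrix with dimnames.
#' @param path Output path.
#' @param id_column Name for the identifier column (default `"gene_id"`).
#' @export
write_expression_matrix <- function(X, path, id_column = "gene_id") {
  df <- data.frame(id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Validate an expression matrix
#'
#' Checks the container contract: numeric, non-negative, unique gene and
#' sample identifiers.
#'
#' @param X Matrix to validate.
#' @return Invisibly, `X`.
#' @export
validate_expression_matrix <- function(X) {
  stopifnot(is.matrix(X), is.numeric(X))
  if (anyNA(X)) stop("expression matrix contains missing values")
  if (any(X < 0)) stop("expression matrix contains negative values")
  if (is.null(rownames(X)) || anyDuplicated(rownames(X))) {
    stop("gene identifiers must be present and unique")
  }
  if (is.null(colnames(X)) || anyDuplicated(colnames(X))) {
    stop("sample identifiers must be present and unique")
  }
  invisible(X)
}

#' Collapse a probe-level matrix to gene level
#'
#' Selects one best probe per gene: the probe maximizing mean expression
#' across samples (default) or maximizing interquartile range. Ties are
#' broken by the lexicographically smaller probe id, so selection is
#' deterministic. Values are copied, never averaged, so each output row is
#' an input row.
#'
#' @param X Probe-level expression matrix (probes as rows).
#' @param probe_map Data frame with columns `probe_id`, `gene_id`
#'   (many-to-one).
#' @param method `"max_mean"` (default) or `"max_iqr"`.
#' @return Gene-level expression matrix; unmapped probes are dropped with a
#'   message stating the count.
#' @export
collapse_probes <- function(X, probe_map, method = c("max_mean", "max_iqr")) {
  method <- match.arg(method)
  validate_expression_matrix(X)
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_map)))
  if (anyDuplicated(probe_map$probe_id)) stop("probe_map has duplicate probes")
  gene <- probe_map$gene_id[match(rownames(X), probe_map$probe_id)]
  unmapped <- is.na(gene)
  if (any(unmapped)) {
    message("dropping ", sum(unmapped), " unmapped probe(s)")
    X <- X[!unmapped, , drop = FALSE]
    gene <- gene[!unmapped]
  }
  if (nrow(X) == 0) stop("no mapped probes remain")
  crit <- switch(method,
    max_mean = rowMeans(X),
    max_iqr = apply(X, 1, function(v) {
      q <- quantile(v, c(0.25, 0.75), names = FALSE)
      q[2] - q[1]
    }))
  ord <- order(gene, -crit, rownames(X))
  first <- ord[!duplicated(gene[ord])]
  first <- first[order(match(gene[first], unique(gene)))]  # keep input order
  out <- X[first, , drop = FALSE]
  rownames(out) <- gene[first]
  out
}

#' Filter genes by expression level and dynamic range
#'
#' Retains genes whose 75th percentile across samples is at least
#' `pct75_min` (default 250, a low-expression floor on the MAS5-like linear
#' scale) and whose interquartile range is at least `iqr_min` (default 500,
#' a dynamic-range requirement). Quantiles use linear interpolation between
#' order statistics (R type 7). Gene order is preserved.
#'
#' @param X Expression matrix (genes x samples).
#' @param pct75_min Minimum 75th percentile (expression units).
#' @param iqr_min Minimum interquartile range (expression units).
#' @return The filtered matrix. Errors if no gene survives.
#' @export
filter_genes <- function(X, pct75_min = 250, iqr_min = 500) {
  validate_expression_matrix(X)
  if (ncol(X) < 4) stop("at least 4 samples are required for quantile filtering")
  qs <- apply(X, 1, quantile, probs = c(0.25, 0.75), names = FALSE, type = 7)
  keep <- qs[2, ] >= pct75_min & (qs[2, ] - qs[1, ]) >= iqr_min
  if (!any(keep)) stop("no genes survive the expression filters")
  X[keep, , drop = FALSE]
}
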