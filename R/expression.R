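#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix (genes in rows, samples in
#' columns) carrying a `scale` attribute (`"linear"` or `"log2"`). Linear-scale
#' values must be non-negative; gene and sample identifiers must be unique.
#'
#' @param values Numeric matrix with gene symbols as rownames and sample
#'   identifiers as colnames.
#' @param scale Either `"linear"` or `"log2"`.
#' @return The validated matrix with class `"expr_matrix"` and a `scale`
#'   attribute.
#' @export
expression_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix requires gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (scale == "linear" && any(values < 0)) {
    stop("negative values are not allowed on the linear scale")
  }
  attr(values, "scale") <- scale
  class(values) <- c("expr_matrix", class(values))
  values
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples (%s scale)\n",
              nrow(x), ncol(x), attr(x, "scale")))
  invisible(x)
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' Expects a header row of sample identifiers and gene symbols in the first
#' column. Rows with duplicate gene symbols are collapsed by the per-sample
#' maximum, which preserves the signal of marker genes mapped to several
#' probes or transcripts.
#'
#' @param path Path to a tab-separated file.
#' @inheritParams expression_matrix
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("no data rows in ", path)
  df <- utils::read.delim(text = lines, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a gene column plus at least one sample column")
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample identifier in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  genes <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1L)))
    cell <- which(is.na(suppressWarnings(as.numeric(df[[bad[1L] + 1L]]))))[1L]
    stop(sprintf("non-numeric value at row %d, column '%s'",
                 cell, colnames(df)[bad[1L] + 1L]))
  }
  if (anyDuplicated(genes)) {
    vals <- do.call(rbind, lapply(split.data.frame(vals, genes), function(m) {
      apply(m, 2L, max)
    }))
    genes <- rownames(vals)
  }
  rownames(vals) <- genes
  colnames(vals) <- samples
  expression_matrix(vals, scale = scale)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: genes in rows, a `gene` header for
#' the first column, sample identifiers for the rest.
#'
#' @param x An [expression_matrix()] or numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene = rownames(x), as.data.frame(unclass(x)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
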