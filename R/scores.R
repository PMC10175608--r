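#' Mean z-score of a gene panel per sample
#'
#' Each panel gene present in the matrix is z-scored across samples on the
#' log2 scale; a sample's score is the mean z over the available panel
#' genes. Genes with zero variance across samples contribute z = 0 (with a
#' warning), and panel genes absent from the matrix are reported, not
#' imputed.
#'
#' @param expr Log2-scale [expression_matrix()] with `>= 2` samples.
#' @param panel Character vector of panel gene symbols.
#' @return List with `scores` (named per-sample numeric vector),
#'   `genes_used`, `genes_missing`.
#' @export
panel_score <- function(expr, panel) {
  if (ncol(expr) < 2L) stop("z-scores need at least two samples")
  panel <- unique(toupper(panel))
  used <- intersect(panel, rownames(expr))
  if (length(used) == 0L) stop("no panel gene present in the expression matrix")
  sub <- unclass(expr)[used, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("panel gene(s) with zero variance scored as z = 0: ",
            paste(used[sds == 0], collapse = ", "))
  }
  z <- (sub - rowMeans(sub)) / ifelse(sds == 0, 1, sds)
  z[sds == 0, ] <- 0
  list(scores = colMeans(z), genes_used = used,
       genes_missing = setdiff(panel, used))
}

#' Weighted T-cell-inflamed GEP score per sample
#'
#' Weighted mean of per-gene z-scores over the 18-gene T-cell-inflamed
#' panel (or any panel). Uniform weights reduce to [panel_score()]; the
#' published per-gene weights are not reproduced here, so uniform is the
#' default.
#'
#' @inheritParams panel_score
#' @param panel Panel genes (default [gep18_panel()]).
#' @param weights Optional per-gene weights, same length and order as
#'   `panel`.
#' @return As [panel_score()].
#' @export
gep_score <- function(expr, panel = gep18_panel(), weights = NULL) {
  panel <- unique(toupper(panel))
  if (is.null(weights)) return(panel_score(expr, panel))
  if (length(weights) != length(panel)) {
    stop("weights must match the panel length (", length(panel), ")")
  }
  ps <- panel_score(expr, panel)
  used <- ps$genes_used
  w <- weights[match(used, panel)]
  sub <- unclass(expr)[used, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  z <- (sub - rowMeans(sub)) / ifelse(sds == 0, 1, sds)
  z[sds == 0, ] <- 0
  list(scores = colSums(z * w) / sum(w), genes_used = used,
       genes_missing = ps$genes_missing)
}

#' Cluster samples on a gene panel for heatmap grouping
#'
#' Average-linkage hierarchical clustering on the Euclidean distance between
#' samples over z-scored panel genes, with a 2-group cut. Samples are
#' ordered by identifier before clustering so the result is invariant to
#' input column order; ties in the dendrogram resolve deterministically.
#'
#' @param expr Log2-scale [expression_matrix()] (`>= 2` samples).
#' @param panel Panel gene symbols.
#' @return List with `order` (sample ids in leaf order), `groups` (named
#'   1/2 assignment), and `hclust` (the tree).
#' @export
cluster_samples <- function(expr, panel) {
  if (ncol(expr) < 2L) stop("clustering needs at least two samples")
  used <- intersect(unique(toupper(panel)), rownames(expr))
  if (length(used) == 0L) stop("no panel gene present in the expression matrix")
  sub <- unclass(expr)[used, order(colnames(expr)), drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  z <- (sub - rowMeans(sub)) / ifelse(sds == 0, 1, sds)
  z[sds == 0, ] <- 0
  hc <- stats::hclust(stats::dist(t(z)), method = "average")
  groups <- stats::cutree(hc, k = min(2L, ncol(sub)))
  list(order = hc$labels[hc$order], groups = groups, hclust = hc)
}
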