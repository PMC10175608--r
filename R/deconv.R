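#' Estimate relative cell-type fractions by non-negative least squares
#'
#' Solves `min ||reference %*% b - sample||^2` subject to `b >= 0` over the
#' genes shared between sample and reference, then normalises `b` to sum 1.
#' The fit correlation is the Pearson r between the reconstruction and the
#' sample over the shared signature genes; a low value flags a sample the
#' reference cannot explain.
#'
#' @param sample Named numeric vector of linear-scale expression.
#' @param reference Linear-scale signature matrix, one column per cell type.
#' @return List with `b` (named fractions summing to 1), `fit_correlation`,
#'   `n_genes` (shared signature genes used).
#' @export
estimate_fractions <- function(sample, reference) {
  genes <- intersect(names(sample), rownames(reference))
  if (length(genes) == 0L) stop("sample and reference share no genes")
  y <- sample[genes]
  if (all(y == 0)) stop("all-zero sample over the signature genes")
  X <- unclass(reference)[genes, , drop = FALSE]
  fit <- pracma::lsqnonneg(X, y)
  b <- fit$x
  recon <- drop(X %*% b)
  if (sum(b) == 0) {
    b <- rep(0, length(b))
    r <- 0
  } else {
    r <- if (stats::sd(recon) == 0 || stats::sd(y) == 0) 0 else stats::cor(recon, y)
    b <- b / sum(b)
  }
  list(b = stats::setNames(b, colnames(reference)), fit_correlation = r,
       n_genes = length(genes))
}

#' Permutation p-value for a deconvolution fit
#'
#' Builds a null distribution of the fit correlation by permuting the
#' sample's expression values over the genes `n_perm` times and refitting;
#' `p = (1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @inheritParams estimate_fractions
#' @param n_perm Number of permutations (`>= 1`; 1000 for reported results).
#' @param seed Integer seed.
#' @return List with `p_perm`, `observed` fit correlation, and `n_perm`.
#' @export
permutation_pvalue <- function(sample, reference, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  obs <- estimate_fractions(sample, reference)$fit_correlation
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    perm <- stats::setNames(sample[sample.int(length(sample))], names(sample))
    estimate_fractions(perm, reference)$fit_correlation
  }, numeric(1L))
  list(p_perm = (1 + sum(null >= obs)) / (n_perm + 1), observed = obs,
       n_perm = n_perm)
}

#' Overall immune fraction of a sample
#'
#' Fits the sample against a joint reference containing immune and
#' non-immune (e.g. malignant epithelial) signatures and sums the fractions
#' of the immune-tagged columns. This is the quantity `a` by which relative
#' immune-subset fractions are rescaled to absolute ones.
#'
#' @inheritParams estimate_fractions
#' @param immune_tags Logical vector, one per reference column, `TRUE` for
#'   immune cell types.
#' @return List with `a` (in `[0, 1]`), plus the underlying fit (`b`,
#'   `fit_correlation`).
#' @export
overall_immune_fraction <- function(sample, reference, immune_tags) {
  if (length(immune_tags) != ncol(reference)) {
    stop("immune_tags must have one entry per reference column")
  }
  if (!any(immune_tags)) stop("reference has no immune-tagged column")
  fit <- estimate_fractions(sample, reference)
  list(a = sum(fit$b[immune_tags]), b = fit$b,
       fit_correlation = fit$fit_correlation)
}

#' Compose absolute cell-type fractions
#'
#' The absolute fraction of each immune subset is the overall immune
#' fraction `a` times its relative fraction `b`; the result sums to `a`.
#'
#' @param a Overall immune fraction in `[0, 1]`.
#' @param b Relative fractions, non-negative, summing to 1 (tolerance 1e-8).
#' @return Numeric vector `a * b`.
#' @export
absolute_fractions <- function(a, b) {
  if (!is.finite(a) || a < 0 || a > 1) stop("a must lie in [0, 1]")
  if (any(b < 0) || abs(sum(b) - 1) > 1e-8) {
    stop("b must be non-negative and sum to 1 (tolerance 1e-8)")
  }
  a * b
}

#' Full deconvolution of one sample
#'
#' One joint fit of the sample against the immune + non-immune reference
#' yields everything: the overall immune fraction `a` (sum of immune-tagged
#' fractions), the relative immune proportions `b` (the immune part of the
#' fit renormalised to sum 1), the absolute composition `a * b`, the fit
#' correlation, and a permutation p-value for that same fit. When the fit
#' assigns no immune content (`a = 0`), relative proportions are undefined
#' and `b` is reported uniform over the immune types so its sum-to-one
#' contract still holds; `absolute` is then all zero.
#'
#' @inheritParams overall_immune_fraction
#' @inheritParams permutation_pvalue
#' @return List with `b`, `a`, `absolute`, `fit_correlation`, `p_perm`,
#'   `n_perm`.
#' @export
deconvolve <- function(sample, reference, immune_tags, n_perm = 1000L,
                       seed = 1L) {
  ov <- overall_immune_fraction(sample, reference, immune_tags)
  b_imm <- ov$b[immune_tags]
  b <- if (ov$a > 0) b_imm / ov$a else rep(1 / length(b_imm), length(b_imm))
  names(b) <- names(b_imm)
  pp <- permutation_pvalue(sample, reference, n_perm = n_perm, seed = seed)
  list(b = b, a = ov$a, absolute = absolute_fractions(ov$a, b),
       fit_correlation = ov$fit_correlation, p_perm = pp$p_perm,
       n_perm = n_perm)
}

#' Synthetic toy deconvolution reference
#'
#' A 120-gene, 7-type signature matrix (six immune types: CD8 T, CD4 T, B,
#' plasma, mononuclear phagocyte, mast; one malignant epithelial type),
#' generated in code as block marker structure plus a shared baseline. It is
#' a synthetic stand-in used for testing and simulation; it is not a curated
#' reference and real analyses should supply one.
#'
#' @param n_genes Total signature genes (divisible design: 15 markers per
#'   type plus shared genes).
#' @param marker_high,baseline Linear-scale expression of a type's markers
#'   and of non-markers.
#' @return List with `reference` ([expression_matrix()], linear scale) and
#'   `immune_tags` (logical, `FALSE` for the malignant column).
#' @export
make_toy_reference <- function(n_genes = 120L, marker_high = 100,
                               baseline = 1) {
  types <- c("T_CD8", "T_CD4", "B_cell", "Plasma", "MonoMac", "Mast",
             "Malignant")
  n_marker <- 15L
  if (n_genes < n_marker * length(types)) {
    stop("n_genes too small for 15 markers per type")
  }
  genes <- sprintf("SIG%03d", seq_len(n_genes))
  ref <- matrix(baseline, nrow = n_genes, ncol = length(types),
                dimnames = list(genes, types))
  for (j in seq_along(types)) {
    idx <- ((j - 1L) * n_marker + 1L):(j * n_marker)
    ref[idx, j] <- marker_high
  }
  list(reference = expression_matrix(ref, scale = "linear"),
       immune_tags = types != "Malignant")
}
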