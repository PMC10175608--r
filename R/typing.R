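#' Call differentially expressed genes between tumor and matched normal
#'
#' With a single tumor/normal pair (the usual case for per-patient typing) a
#' pure fold-change rule is applied: up-regulated means
#' `log2FC >= lfc_min`, down-regulated `log2FC <= -lfc_min`. With replicates
#' in both groups a per-gene Welch t-test is combined with the fold-change
#' rule and Benjamini-Hochberg correction (`q < q_max`).
#'
#' @param tumor,normal Log2-scale expression matrices (or vectors) over the
#'   same gene universe; columns are replicates.
#' @param lfc_min Minimum absolute log2 fold change (default 1).
#' @param q_max BH-adjusted p-value cut-off, used only when both groups have
#'   `>= 2` replicates.
#' @return List with `up`, `down` (character vectors), and `stats`, a
#'   `data.frame` of per-gene `log2fc` and `q` (`NA` without replicates).
#' @export
call_degs <- function(tumor, normal, lfc_min = 1, q_max = 0.05) {
  tumor <- as.matrix(tumor); normal <- as.matrix(normal)
  if (is.null(rownames(tumor)) || is.null(rownames(normal)) ||
      !identical(rownames(tumor), rownames(normal))) {
    stop("tumor and normal must share an identical gene universe")
  }
  lfc <- rowMeans(tumor) - rowMeans(normal)
  q <- rep(NA_real_, length(lfc))
  if (ncol(tumor) >= 2L && ncol(normal) >= 2L) {
    p <- vapply(seq_len(nrow(tumor)), function(i) {
      stats::t.test(tumor[i, ], normal[i, ])$p.value
    }, numeric(1L))
    q <- bh_adjust(p)
    sig <- q < q_max
  } else {
    sig <- rep(TRUE, length(lfc))
  }
  genes <- rownames(tumor)
  list(up = genes[sig & lfc >= lfc_min],
       down = genes[sig & lfc <= -lfc_min],
       stats = data.frame(gene = genes, log2fc = lfc, q = q,
                          stringsAsFactors = FALSE))
}

#' One-sided Fisher's exact (hypergeometric) over-representation test
#'
#' Tests whether `query` over-represents `set` within `universe`:
#' `p = P(X >= k)` for `X ~ Hypergeom(N, K, n)` with `N = |universe|`,
#' `K = |set|`, `n = |query|`, `k = |query intersect set|` (memberships taken
#' after intersecting with the universe).
#'
#' @param query,set,universe Character vectors of gene symbols;
#'   `query, set` are restricted to `universe`.
#' @return List with `k`, `K`, `n`, `N` and `p`.
#' @export
fisher_enrichment <- function(query, set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query <- intersect(unique(query), universe)
  set <- intersect(unique(set), universe)
  k <- length(intersect(query, set))
  K <- length(set); n <- length(query); N <- length(universe)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR control: with sorted p-values `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} min(1, p_(j) * m / j)`, returned in input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0L))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Run over-representation of a DEG list against a gene-set collection
#'
#' @param query Character vector of genes (e.g. up-regulated DEGs).
#' @param sets Named list of gene sets.
#' @param universe Gene universe (all genes of the expression matrix).
#' @param q_max Significance cut-off on the BH-adjusted p.
#' @return `data.frame` with one row per set: `set_name`, `k`, `K`, `n`, `N`,
#'   `p`, `q`, `enriched`.
#' @export
enrich_sets <- function(query, sets, universe, q_max = 0.05) {
  res <- lapply(names(sets), function(nm) {
    e <- fisher_enrichment(query, sets[[nm]], universe)
    data.frame(set_name = nm, k = e$k, K = e$K, n = e$n, N = e$N, p = e$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- bh_adjust(res$p)
  res$enriched <- res$q < q_max
  res
}

#' Score the three immune-signature categories from enrichment results
#'
#' Each category's score is the sum of `-log10(q)` over its feature sets
#' that reached significance; sets with `q` above the cut-off contribute
#' nothing. Uniform weights across a category's sets.
#'
#' @param enrichment Output of [enrich_sets()].
#' @param cmap Category map, as [default_category_map()].
#' @return Named numeric vector `c(inflamed=, excluded=, desert=)`.
#' @export
score_signature_categories <- function(enrichment, cmap = default_category_map()) {
  unknown <- setdiff(unlist(cmap), enrichment$set_name)
  if (length(unknown)) {
    stop("category map references unknown set(s): ", paste(unknown, collapse = ", "))
  }
  vapply(cmap, function(set_names) {
    rows <- enrichment[enrichment$set_name %in% set_names & enrichment$enriched, ]
    if (nrow(rows) == 0L) return(0)
    sum(-log10(pmax(rows$q, .Machine$double.xmin)))
  }, numeric(1L))
}

#' Classify the immune signature from category scores
#'
#' Argmax over category scores when the maximum reaches `min_score`
#' (default 1.3, i.e. one feature set enriched at q = 0.05). A tumor whose
#' transcriptome enriches no immune program behaves as an immune desert and
#' is called desert with low confidence. Ties resolve by the fixed precedence
#' inflamed > excluded > desert, with low confidence.
#'
#' @param scores Named vector over `inflamed`, `excluded`, `desert`.
#' @param min_score Minimum winning score for a confident call.
#' @return A `subtype_call`.
#' @export
classify_transcriptomic <- function(scores, min_score = 1.3) {
  stopifnot(all(c("inflamed", "excluded", "desert") %in% names(scores)),
            all(is.finite(scores)))
  precedence <- c("inflamed", "excluded", "desert")
  scores <- scores[precedence]
  mx <- max(scores)
  ev <- sprintf("category scores: %s",
                paste(sprintf("%s=%.3g", names(scores), scores), collapse = ", "))
  if (mx < min_score) {
    return(subtype_call("desert", scores,
                        c(ev, sprintf("no category reached min_score=%g; defaulting to desert", min_score)),
                        "low"))
  }
  winners <- names(scores)[scores == mx]
  label <- winners[1L]  # precedence order
  conf <- if (length(winners) > 1L) "low" else "high"
  ev <- c(ev, sprintf("argmax -> %s%s", label,
                      if (length(winners) > 1L) " (tie broken by precedence)" else ""))
  subtype_call(label, scores, ev, conf)
}

#' Transcriptome-based immune-signature typing of one tumor/normal pair
#'
#' Convenience wrapper: DEG calling, over-representation of the up-regulated
#' genes against the signature-feature sets, category scoring, and
#' classification.
#'
#' @param tumor,normal Log2 expression vectors/matrices over the same genes.
#' @param sets Gene-set collection (default [signature_gene_sets()]).
#' @param cmap Category map (default [default_category_map()]).
#' @param lfc_min,q_max,min_score Tuning parameters, see [call_degs()],
#'   [enrich_sets()], [classify_transcriptomic()].
#' @return A `subtype_call`; the enrichment table is attached as attribute
#'   `enrichment`, the DEG result as `degs`.
#' @export
type_transcriptome <- function(tumor, normal, sets = signature_gene_sets(),
                               cmap = default_category_map(), lfc_min = 1,
                               q_max = 0.05, min_score = 1.3) {
  degs <- call_degs(tumor, normal, lfc_min = lfc_min, q_max = q_max)
  universe <- degs$stats$gene
  enr <- enrich_sets(degs$up, sets, universe, q_max = q_max)
  scores <- score_signature_categories(enr, cmap)
  call <- classify_transcriptomic(scores, min_score = min_score)
  attr(call, "enrichment") <- enr
  attr(call, "degs") <- degs
  call
}

#' Integrate spatial and transcriptomic subtype calls
#'
#' Concordant calls yield that label with high confidence. Discordant calls
#' keep the spatial label (T-cell distribution is the primary basis of the
#' categorisation) with low confidence and both labels in the evidence. A
#' single available call passes through unchanged.
#'
#' @param spatial,transcriptomic `subtype_call`s or `NULL`.
#' @return A `subtype_call`.
#' @export
integrate_calls <- function(spatial = NULL, transcriptomic = NULL) {
  if (is.null(spatial) && is.null(transcriptomic)) {
    stop("at least one subtype call is required")
  }
  if (is.null(spatial)) return(transcriptomic)
  if (is.null(transcriptomic)) return(spatial)
  if (identical(spatial$label, transcriptomic$label)) {
    subtype_call(spatial$label, spatial$scores,
                 c(sprintf("spatial and transcriptomic typing concordant: %s",
                           spatial$label)), "high")
  } else {
    subtype_call(spatial$label, spatial$scores,
                 c(sprintf("discordant calls: spatial=%s, transcriptomic=%s; keeping spatial",
                           spatial$label, transcriptomic$label)), "low")
  }
}
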