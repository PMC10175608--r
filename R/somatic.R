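#' Thresholds of the five-rule somatic filter
#'
#' The five criteria a candidate somatic variant must satisfy, all
#' inclusive: sequencing depth of BOTH tumor and normal `>= min_depth`;
#' tumor reads supporting the variant `>= min_alt_reads`; tumor allele
#' fraction `>= min_af_tumor`; normal allele fraction `<= max_af_normal`;
#' caller filter equal to `PASS` (unless `require_pass = FALSE`).
#'
#' @param min_depth Minimum depth in each of tumor and normal (default 10).
#' @param min_alt_reads Minimum tumor alt reads (default 3).
#' @param min_af_tumor Minimum tumor allele fraction (default 0.05).
#' @param max_af_normal Maximum normal allele fraction (default 0.01).
#' @param require_pass Require `filter_status == "PASS"` (default `TRUE`).
#' @return A list with class `"filter_thresholds"`.
#' @export
filter_thresholds <- function(min_depth = 10L, min_alt_reads = 3L,
                              min_af_tumor = 0.05, max_af_normal = 0.01,
                              require_pass = TRUE) {
  if (min_depth < 0 || min_alt_reads < 0 || min_af_tumor < 0 || max_af_normal < 0) {
    stop("thresholds must be non-negative")
  }
  if (min_af_tumor <= max_af_normal) {
    stop("min_af_tumor must exceed max_af_normal")
  }
  structure(list(min_depth = as.integer(min_depth),
                 min_alt_reads = as.integer(min_alt_reads),
                 min_af_tumor = min_af_tumor, max_af_normal = max_af_normal,
                 require_pass = isTRUE(require_pass)),
            class = "filter_thresholds")
}

#' Apply the five-rule somatic filter
#'
#' A record is kept iff it satisfies every rule of [filter_thresholds()].
#' Each rejected record is attributed to EVERY rule it fails, so the
#' rejection counts can exceed the number of rejected records.
#'
#' @param records A [variant_table()].
#' @param t A [filter_thresholds()].
#' @return List with `kept` (the passing subset), `rejected`, and
#'   `rejections` (named counts per rule).
#' @export
apply_somatic_filters <- function(records, t = filter_thresholds()) {
  stopifnot(inherits(t, "filter_thresholds"))
  fails <- cbind(
    depth     = records$depth_tumor < t$min_depth |
                records$depth_normal < t$min_depth,
    alt_reads = records$alt_reads_tumor < t$min_alt_reads,
    af_tumor  = records$af_tumor < t$min_af_tumor,
    af_normal = records$af_normal > t$max_af_normal,
    filter    = t$require_pass & records$filter_status != "PASS"
  )
  keep <- rowSums(fails) == 0L
  list(kept = records[keep, , drop = FALSE],
       rejected = records[!keep, , drop = FALSE],
       rejections = colSums(fails[!keep, , drop = FALSE]))
}

#' Summarise a filtered mutation set
#'
#' Counts, SNV/indel spectrum, mutated genes, and tumor mutational burden
#' `TMB = n / target_mb` in mutations per megabase. The targeted size is a
#' required input: no exome size is silently assumed.
#'
#' @param kept A [variant_table()] of filtered somatic calls.
#' @param target_mb Targeted sequence size in Mb, `> 0`.
#' @return List with `n_total`, `n_snv`, `n_indel`, `snv_fraction`,
#'   `indel_fraction`, `tmb`, `mutated_genes`, and `spectrum_defined`
#'   (`FALSE` when there are no mutations, in which case the fractions are
#'   reported as 0).
#' @export
mutation_summary <- function(kept, target_mb) {
  if (!is.finite(target_mb) || target_mb <= 0) stop("target_mb must be > 0")
  n <- nrow(kept)
  n_snv <- sum(kept$variant_class == "SNV")
  n_indel <- n - n_snv
  list(n_total = n, n_snv = n_snv, n_indel = n_indel,
       snv_fraction = if (n > 0) n_snv / n else 0,
       indel_fraction = if (n > 0) n_indel / n else 0,
       tmb = n / target_mb,
       mutated_genes = sort(unique(kept$gene[nzchar(kept$gene)])),
       spectrum_defined = n > 0)
}

#' Concordance between mutated-gene and down-regulated pathway panels
#'
#' Measures how similar the pathways enriched among somatically mutated
#' genes are to the pathways enriched among down-regulated genes of the same
#' tumor (mutational impairment of a pathway mirrors its transcriptional
#' loss). Similarity is the Jaccard index of the two enriched-term sets; its
#' significance comes from drawing equally-sized random term sets from the
#' tested universe `n_perm` times with the add-one rule
#' `p = (1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param mutated_terms,down_terms Character vectors of enriched term names.
#' @param universe_terms All tested term names (must contain both sets).
#' @param n_perm Number of permutation draws.
#' @param seed Integer seed.
#' @return List with `jaccard`, `p_perm`, `n_perm`, and `both_empty` flag.
#' @export
pathway_concordance <- function(mutated_terms, down_terms, universe_terms,
                                n_perm = 1000L, seed = 1L) {
  universe_terms <- unique(universe_terms)
  mutated_terms <- unique(mutated_terms)
  down_terms <- unique(down_terms)
  if (length(setdiff(mutated_terms, universe_terms)) ||
      length(setdiff(down_terms, universe_terms))) {
    stop("term sets must be subsets of the universe")
  }
  jac <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0L) 0 else length(intersect(a, b)) / u
  }
  obs <- jac(mutated_terms, down_terms)
  both_empty <- length(mutated_terms) == 0L && length(down_terms) == 0L
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    jac(sample(universe_terms, length(mutated_terms)),
        sample(universe_terms, length(down_terms)))
  }, numeric(1L))
  list(jaccard = obs, p_perm = (1 + sum(null >= obs)) / (n_perm + 1),
       n_perm = n_perm, both_empty = both_empty)
}
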