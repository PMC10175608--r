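#' Build a 2x2 subtype-by-feature contingency table
#'
#' Columns are fixed as immune desert versus excluded + inflamed (the
#' predicted non-responsive versus potentially responsive split); rows are
#' the two requested level groups of the feature. Patients with a missing
#' feature value are excluded and counted.
#'
#' @param clinical A [clinical_table()].
#' @param feature Column name of the covariate.
#' @param level_split List of two character vectors giving the levels that
#'   form row 1 and row 2; defaults to the two defined levels of the
#'   feature.
#' @return List with `counts` (2x2 integer matrix with dimnames),
#'   `n_missing`, `feature`.
#' @export
build_contingency <- function(clinical, feature, level_split = NULL) {
  if (!feature %in% colnames(clinical)) stop("unknown feature: ", feature)
  vals <- clinical[[feature]]
  keep <- !is.na(vals)
  vals <- vals[keep]
  desert <- clinical$subtype[keep] == "desert"
  if (is.null(level_split)) {
    lv <- clinical_levels[[feature]]
    if (is.null(lv) || length(lv) != 2L) stop("level_split required for ", feature)
    level_split <- list(lv[1L], lv[2L])
  }
  unknown <- setdiff(unique(vals), unlist(level_split))
  if (length(unknown)) stop("level(s) not covered by split: ",
                            paste(unknown, collapse = ", "))
  r1 <- vals %in% level_split[[1L]]
  counts <- matrix(c(sum(r1 & desert), sum(r1 & !desert),
                     sum(!r1 & desert), sum(!r1 & !desert)),
                   nrow = 2L, byrow = TRUE,
                   dimnames = list(c(paste(level_split[[1L]], collapse = "+"),
                                     paste(level_split[[2L]], collapse = "+")),
                                   c("desert", "excluded+inflamed")))
  list(counts = counts, n_missing = sum(!keep), feature = feature)
}

#' Pearson chi-square test of a 2x2 table (no continuity correction)
#'
#' Uncorrected Pearson chi-square with 1 degree of freedom, identical to the
#' closed form `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` referred to the
#' chi-square(1) distribution.
#'
#' @param counts 2x2 non-negative integer matrix.
#' @return List with `statistic` and `p` (two-sided).
#' @export
chi_square_p <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2L), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("chi-square undefined with a zero marginal")
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' Two-sided Fisher's exact test of a 2x2 table
#'
#' Two-sided p-value summing, over all tables with the observed margins,
#' the hypergeometric probabilities no larger than that of the observed
#' table (standard two-sided convention).
#'
#' @param counts 2x2 non-negative integer matrix.
#' @return Two-sided p-value.
#' @export
fisher_exact_p <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2L), all(counts >= 0))
  if (sum(counts) == 0) stop("empty table")
  stats::fisher.test(counts)$p.value
}

#' Expected counts of a 2x2 table under independence
#'
#' @param counts 2x2 matrix.
#' @return 2x2 matrix of expected counts.
#' @export
expected_counts <- function(counts) {
  counts <- as.matrix(counts)
  outer(rowSums(counts), colSums(counts)) / sum(counts)
}

#' Choose between chi-square and Fisher's exact test
#'
#' The chi-square approximation is used unless the data are limited,
#' operationalised by the conventional rule: any expected cell count below 5
#' (including tables with a zero margin) selects Fisher's exact test.
#'
#' @param counts 2x2 matrix.
#' @return `"chi_square"` or `"fisher"`.
#' @export
select_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) return("fisher")
  if (any(expected_counts(counts) < 5)) "fisher" else "chi_square"
}

#' Clinical association report (desert vs excluded + inflamed)
#'
#' Cross-tabulates the immune-signature subtype against every
#' clinicopathologic covariate, reporting per-level counts, percentages of
#' the full cohort, the automatically selected test and its p-value. One
#' output row per feature level; the test and p are attached to both rows of
#' a feature.
#'
#' @param clinical A [clinical_table()].
#' @return `data.frame` with columns `feature`, `level`, `n_cases`,
#'   `n_desert`, `pct_desert`, `n_other`, `pct_other`, `n_missing`,
#'   `test_used`, `p_value`. The first row (`feature = "total"`) gives the
#'   cohort margins.
#' @export
table1_report <- function(clinical) {
  stopifnot(inherits(clinical, "clinical_table"))
  N <- nrow(clinical)
  pct <- function(k) round(100 * k / N, 1)
  n_desert <- sum(clinical$subtype == "desert")
  rows <- list(data.frame(
    feature = "total", level = "", n_cases = N, n_desert = n_desert,
    pct_desert = pct(n_desert), n_other = N - n_desert,
    pct_other = pct(N - n_desert), n_missing = 0L, test_used = "",
    p_value = NA_real_, stringsAsFactors = FALSE))
  features <- setdiff(names(clinical_levels), "subtype")
  for (f in features) {
    ct <- build_contingency(clinical, f)
    test <- select_test(ct$counts)
    p <- if (test == "chi_square") chi_square_p(ct$counts)$p
         else fisher_exact_p(ct$counts)
    for (i in 1:2) {
      k_d <- ct$counts[i, "desert"]; k_o <- ct$counts[i, "excluded+inflamed"]
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, level = rownames(ct$counts)[i], n_cases = k_d + k_o,
        n_desert = k_d, pct_desert = pct(k_d), n_other = k_o,
        pct_other = pct(k_o), n_missing = ct$n_missing, test_used = test,
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
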