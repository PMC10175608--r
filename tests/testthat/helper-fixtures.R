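# shared helpers: tiny on-disk fixtures and cohort typing

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# transcriptomic typing of every tumor in a simulated cohort
type_cohort <- function(cohort, ...) {
  vapply(colnames(cohort$tumor), function(id) {
    type_transcriptome(unclass(cohort$tumor)[, id, drop = FALSE],
                       unclass(cohort$normal)[, id, drop = FALSE], ...)$label
  }, character(1L))
}

# independent hypergeometric upper-tail oracle by direct pmf summation
hyper_tail_oracle <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# independent two-sided Fisher oracle: enumerate all tables with the margins
fisher_two_sided_oracle <- function(counts) {
  a <- counts[1, 1]
  r1 <- sum(counts[1, ]); c1 <- sum(counts[, 1]); N <- sum(counts)
  support <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- dhyper(support, c1, N - c1, r1)
  obs <- dhyper(a, c1, N - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
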