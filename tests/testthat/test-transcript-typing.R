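test_that("single-pair DEG calling applies the fold-change rule", {
  genes <- c("A", "B", "C")
  t <- matrix(c(8, 5, 2), dimnames = list(genes, "T"))
  n <- matrix(c(5, 5, 5), dimnames = list(genes, "N"))
  d <- call_degs(t, n, lfc_min = 1)
  expect_identical(d$up, "A")
  expect_identical(d$down, "C")
  same <- call_degs(t, t)
  expect_length(same$up, 0L)
  expect_length(same$down, 0L)
  expect_error(call_degs(t, matrix(1, 3, 1, dimnames = list(c("A", "B", "X"), "N"))),
               "gene universe")
})

test_that("replicated DEG calling combines Welch test with the fold rule", {
  set.seed(1)
  genes <- sprintf("G%02d", 1:40)
  t <- matrix(rnorm(40 * 4, 5, 0.1), 40, 4, dimnames = list(genes, paste0("T", 1:4)))
  n <- matrix(rnorm(40 * 4, 5, 0.1), 40, 4, dimnames = list(genes, paste0("N", 1:4)))
  t["G01", ] <- t["G01", ] + 3
  d <- call_degs(t, n, lfc_min = 1, q_max = 0.05)
  expect_identical(d$up, "G01")
  expect_false(anyNA(d$stats$q))
})

test_that("fisher_enrichment matches the hypergeometric tail", {
  u <- paste0("g", 1:20)
  # forced full overlap
  expect_equal(fisher_enrichment(u, u, u)$p, 1)
  # zero hits always gives p = 1
  expect_equal(fisher_enrichment(u[1:5], u[6:10], u)$p, 1)
  # N=20, K=5, n=5, k=5 -> 1/choose(20,5)
  e <- fisher_enrichment(u[1:5], u[1:5], u)
  expect_equal(e$p, 1 / 15504, tolerance = 1e-12)
  expect_error(fisher_enrichment("a", "a", character(0)), "empty universe")
})

test_that("fisher_enrichment agrees with exhaustive enumeration for N <= 30", {
  set.seed(7)
  for (rep in 1:60) {
    N <- sample(2:30, 1)
    u <- paste0("g", seq_len(N))
    K <- sample.int(N, 1); n <- sample.int(N, 1)
    set <- sample(u, K); query <- sample(u, n)
    e <- fisher_enrichment(query, set, u)
    expect_equal(e$p, hyper_tail_oracle(e$k, K, n, N), tolerance = 1e-12)
  }
})

test_that("bh_adjust reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.9, 0.8)), c(0.9, 0.9))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # permutation invariance and sorted monotonicity
  set.seed(3)
  p <- runif(25)
  perm <- sample.int(25)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_true(all(diff(bh_adjust(p)[order(p)]) >= 0))
})

test_that("category scores sum -log10(q) over enriched feature sets", {
  enr <- data.frame(
    set_name = c("IFNG_RESPONSE", "ANTIGEN_PRESENTATION", "TLS_B_CELL",
                 "TIL_CYTOTOXIC", "TGFB_SIGNALING", "ANGIOGENESIS",
                 "FATTY_ACID_METABOLISM", "NEUROENDOCRINE"),
    q = c(0.001, 1, 1, 1, 0.01, 0.01, 1, 1),
    enriched = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  s <- score_signature_categories(enr)
  expect_equal(unname(s["inflamed"]), 3)
  expect_equal(unname(s["excluded"]), 4)
  expect_equal(unname(s["desert"]), 0)
  none <- transform(enr, enriched = FALSE)
  expect_equal(unname(score_signature_categories(none)), c(0, 0, 0))
  bad_map <- list(inflamed = "NOT_A_SET", excluded = "TGFB_SIGNALING",
                  desert = "NEUROENDOCRINE")
  expect_error(score_signature_categories(enr, bad_map), "unknown set")
})

test_that("classification is argmax with precedence ties and a desert default", {
  hi <- classify_transcriptomic(c(inflamed = 5, excluded = 1, desert = 0))
  expect_identical(hi$label, "inflamed")
  expect_identical(hi$confidence, "high")
  zero <- classify_transcriptomic(c(inflamed = 0, excluded = 0, desert = 0))
  expect_identical(zero$label, "desert")
  expect_identical(zero$confidence, "low")
  tie <- classify_transcriptomic(c(inflamed = 3, excluded = 3, desert = 0))
  expect_identical(tie$label, "inflamed")
  expect_identical(tie$confidence, "low")
  # scale equivariance of the label
  s <- c(inflamed = 0.4, excluded = 2.2, desert = 1.1)
  expect_identical(classify_transcriptomic(s * 10)$label,
                   classify_transcriptomic(s, min_score = 0.13)$label)
})

test_that("integration favors concordance and falls back to the spatial call", {
  a <- classify_transcriptomic(c(inflamed = 5, excluded = 0, desert = 0))
  b <- classify_spatial(list(rho_tumor = 400, rho_peri = 400))
  both <- integrate_calls(b, a)
  expect_identical(both$label, "inflamed")
  expect_identical(both$confidence, "high")
  d <- classify_spatial(list(rho_tumor = 2, rho_peri = 3))
  disc <- integrate_calls(d, a)
  expect_identical(disc$label, "desert")
  expect_identical(disc$confidence, "low")
  expect_match(paste(disc$evidence, collapse = " "), "inflamed")
  expect_identical(integrate_calls(NULL, a)$label, "inflamed")
  expect_error(integrate_calls(NULL, NULL), "at least one")
})

test_that("typing recovers noisy cohorts well above chance", {
  co <- simulate_expression_cohort(
    cohort_spec(c(inflamed = 5L, excluded = 5L, desert = 5L), noise_sd = 0.5,
                seed = 21L))
  expect_gte(mean(type_cohort(co) == co$truth), 0.9)
})
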