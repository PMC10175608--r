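test_that("noise-free cohorts have exact fold changes and are reproducible", {
  spec <- cohort_spec(c(inflamed = 1L, excluded = 1L, desert = 1L),
                      noise_sd = 0, effect_size = 2, seed = 11L)
  co <- simulate_expression_cohort(spec)
  lfc <- unclass(co$tumor) - unclass(co$normal)
  for (id in colnames(co$tumor)) {
    cat_genes <- co$category_genes[[co$truth[id]]]
    expect_true(all(lfc[cat_genes, id] == 2))
    expect_true(all(lfc[setdiff(rownames(lfc), cat_genes), id] == 0))
  }
  co2 <- simulate_expression_cohort(spec)
  expect_identical(unclass(co$tumor)[, ], unclass(co2$tumor)[, ])
  expect_identical(unclass(co$normal)[, ], unclass(co2$normal)[, ])
})

test_that("transcriptomic typing recovers generator labels exactly without noise", {
  co <- simulate_expression_cohort(
    cohort_spec(c(inflamed = 2L, excluded = 2L, desert = 2L), noise_sd = 0,
                seed = 5L))
  expect_identical(unname(type_cohort(co)), unname(co$truth))
})

test_that("mixtures are exact convex combinations and validate fractions", {
  toy <- make_toy_reference()
  one <- c(1, rep(0, 6))
  expect_equal(unname(simulate_mixture(toy$reference, one)),
               unname(unclass(toy$reference)[, 1]))
  two <- c(0.6, 0.4, rep(0, 5))
  expect_equal(unname(simulate_mixture(toy$reference, two)),
               unname(drop(unclass(toy$reference) %*% two)))
  expect_error(simulate_mixture(toy$reference, c(0.6, 0.5, rep(0, 5))),
               "sum to 1")
  expect_error(simulate_mixture(toy$reference, c(0.6, 0.4)), "one entry per")
})

test_that("noise-free mixtures are recovered by the least-squares oracle and NNLS", {
  toy <- make_toy_reference()
  fr <- c(0.25, 0.2, 0.15, 0.15, 0.1, 0.1, 0.05)
  mix <- simulate_mixture(toy$reference, fr, noise_sd = 0)
  # unconstrained least-squares oracle on the full-rank reference
  oracle <- qr.solve(unclass(toy$reference), mix)
  expect_equal(unname(oracle), fr, tolerance = 1e-8)
  fit <- estimate_fractions(mix, toy$reference)
  expect_equal(unname(fit$b), fr, tolerance = 1e-6)
})

test_that("simulated variants realise the truth classes by construction", {
  spec_s <- variant_sim_spec(n_true_somatic = 20L, n_germline = 0L,
                             n_artifact = 0L, seed = 2L)
  only_somatic <- simulate_variants(spec_s)
  res <- apply_somatic_filters(only_somatic)
  expect_equal(nrow(res$kept), 20L)
  expect_equal(nrow(res$rejected), 0L)

  spec_a <- variant_sim_spec(n_true_somatic = 0L, n_germline = 0L,
                             n_artifact = 18L, seed = 2L)
  only_bad <- simulate_variants(spec_a)
  res <- apply_somatic_filters(only_bad)
  expect_equal(nrow(res$kept), 0L)

  expect_identical(simulate_variants(spec_s)$af_tumor,
                   simulate_variants(spec_s)$af_tumor)
})

test_that("simulated cell maps classify to their generating subtype", {
  for (s in c("desert", "excluded", "inflamed")) {
    m <- simulate_cell_map(s, seed = 42L)
    expect_identical(classify_spatial(cell_densities(m))$label, s)
  }
  m1 <- simulate_cell_map("inflamed", seed = 9L)
  m2 <- simulate_cell_map("inflamed", seed = 9L)
  expect_identical(m1$points, m2$points)
})

test_that("the 82-patient fixture reproduces every published margin exactly", {
  clin <- make_table1_fixture()
  expect_equal(nrow(clin), 82L)
  tab <- function(feature) {
    t(table(clin[[feature]], clin$subtype)[, c("desert", "excluded", "inflamed")])
  }
  expect_equal(unname(table(clin$subtype)[c("desert", "excluded", "inflamed")]),
               c(27L, 28L, 27L), ignore_attr = TRUE)
  # (desert, excluded, inflamed) counts per covariate level
  expect_equal(unname(tab("age_group")["desert", c("<50", ">=50")]), c(12L, 15L))
  expect_equal(unname(tab("age_group")["excluded", c("<50", ">=50")]), c(9L, 19L))
  expect_equal(unname(tab("age_group")["inflamed", c("<50", ">=50")]), c(14L, 13L))
  expect_equal(unname(tab("gender")[, "female"]), c(9L, 10L, 7L))
  expect_equal(unname(tab("metastasis")[, "yes"]), c(16L, 3L, 3L))
  expect_equal(unname(tab("metastasis")[, "no"]), c(11L, 25L, 24L))
  expect_equal(unname(tab("tumor_size")[, ">=3cm"]), c(8L, 1L, 0L))
  expect_equal(unname(tab("location1")[, "colon"]), c(18L, 20L, 21L))
  expect_equal(unname(tab("location2")[, "cecum"]), c(6L, 2L, 2L))
  expect_equal(unname(tab("histologic_type")[, "MDA+MHDA"]), c(7L, 19L, 11L))
  expect_equal(unname(tab("infiltration")[, "WLIW"]), c(17L, 18L, 14L))
  stage <- table(clin$stage, clin$subtype, useNA = "always")
  expect_equal(unname(stage["T1+T2", c("desert", "excluded", "inflamed")]),
               c(0L, 2L, 1L))
  expect_equal(unname(stage["T3+T4", c("desert", "excluded", "inflamed")]),
               c(6L, 6L, 7L))
  expect_equal(sum(is.na(clin$stage)), 60L)
  # construction is deterministic
  expect_identical(clin, make_table1_fixture())
})
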