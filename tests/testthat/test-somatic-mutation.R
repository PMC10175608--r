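boundary_record <- function(depth_tumor = 10L, depth_normal = 10L,
                            alt = 3L, af_t = 0.05, af_n = 0.01,
                            filter = "PASS") {
  variant_table("chr1", 100L, "A", "G", depth_tumor, depth_normal, alt,
                af_t, af_n, filter)
}

test_that("all five filter boundaries are inclusive", {
  res <- apply_somatic_filters(boundary_record())
  expect_equal(nrow(res$kept), 1L)
  expect_equal(sum(res$rejections), 0L)
})

test_that("single-rule violators are rejected with correct attribution", {
  cases <- list(
    list(rec = boundary_record(depth_tumor = 9L), rule = "depth"),
    list(rec = boundary_record(depth_normal = 9L), rule = "depth"),
    list(rec = boundary_record(alt = 2L), rule = "alt_reads"),
    list(rec = boundary_record(af_t = 0.049), rule = "af_tumor"),
    list(rec = boundary_record(af_n = 0.011), rule = "af_normal"),
    list(rec = boundary_record(filter = "germline_risk"), rule = "filter")
  )
  for (case in cases) {
    res <- apply_somatic_filters(case$rec)
    expect_equal(nrow(res$kept), 0L)
    expect_equal(unname(res$rejections[case$rule]), 1L)
    expect_equal(sum(res$rejections), 1L)
  }
  # a multi-rule failure is attributed to every failed rule
  multi <- boundary_record(depth_tumor = 9L, af_n = 0.011)
  res <- apply_somatic_filters(multi)
  expect_equal(unname(res$rejections[c("depth", "af_normal")]), c(1L, 1L))
})

test_that("require_pass = FALSE waives only the filter-status rule", {
  rec <- boundary_record(filter = "clustered_events")
  th <- filter_thresholds(require_pass = FALSE)
  expect_equal(nrow(apply_somatic_filters(rec, th)$kept), 1L)
  expect_error(filter_thresholds(min_af_tumor = 0.01, max_af_normal = 0.05),
               "exceed")
})

test_that("tightening any threshold never enlarges the kept set", {
  v <- simulate_variants(variant_sim_spec(n_true_somatic = 30L,
                                          n_germline = 15L, n_artifact = 18L,
                                          seed = 5L))
  base <- filter_thresholds()
  kept_ids <- function(t) rownames(apply_somatic_filters(v, t)$kept)
  base_ids <- kept_ids(base)
  tighter <- list(
    filter_thresholds(min_depth = 20L),
    filter_thresholds(min_alt_reads = 5L),
    filter_thresholds(min_af_tumor = 0.1),
    filter_thresholds(max_af_normal = 0.005),
    filter_thresholds(min_depth = 50L, min_alt_reads = 10L, min_af_tumor = 0.2)
  )
  for (t in tighter) expect_true(all(kept_ids(t) %in% base_ids))
})

test_that("filtering simulated truth classes is perfectly sensitive and specific", {
  v <- simulate_variants(variant_sim_spec(n_true_somatic = 40L,
                                          n_germline = 20L, n_artifact = 24L,
                                          seed = 9L))
  res <- apply_somatic_filters(v)
  expect_true(all(res$kept$truth == "somatic"))
  expect_true(all(res$rejected$truth != "somatic"))
  expect_equal(nrow(res$kept), sum(v$truth == "somatic"))
})

test_that("mutation summaries compute spectrum and TMB", {
  v <- simulate_variants(variant_sim_spec(n_true_somatic = 67L, n_germline = 0L,
                                          n_artifact = 0L, seed = 3L))
  s <- mutation_summary(v, target_mb = 1)
  expect_equal(s$tmb, 67)
  expect_equal(s$n_snv + s$n_indel, s$n_total)
  expect_equal(s$snv_fraction + s$indel_fraction, 1)
  # 2,010 mutations over a 30 Mb target give the same burden per Mb
  big <- simulate_variants(variant_sim_spec(n_true_somatic = 2010L,
                                            n_germline = 0L, n_artifact = 0L,
                                            seed = 3L))
  expect_equal(mutation_summary(big, target_mb = 30)$tmb, 67)
  empty <- v[0, ]
  s0 <- mutation_summary(empty, target_mb = 30)
  expect_equal(s0$tmb, 0)
  expect_false(s0$spectrum_defined)
  expect_equal(s0$snv_fraction, 0)
  expect_error(mutation_summary(v, target_mb = 0), "> 0")
})

test_that("pathway concordance computes Jaccard with a permutation null", {
  u <- paste0("term", 1:100)
  expect_equal(pathway_concordance(c("term1", "term2", "term3"),
                                   c("term2", "term3", "term4"), u,
                                   n_perm = 10L)$jaccard, 0.5)
  expect_equal(pathway_concordance(u[1:5], u[1:5], u, n_perm = 10L)$jaccard, 1)
  disj <- pathway_concordance(u[1:5], u[6:10], u, n_perm = 1000L, seed = 2L)
  expect_equal(disj$jaccard, 0)
  expect_gt(disj$p_perm, 0.5)
  # overlapping sets in a large universe are unlikely by chance
  over <- pathway_concordance(u[1:6], u[1:6], u, n_perm = 1000L, seed = 2L)
  expect_lte(over$p_perm, 0.01)
  # symmetry and range
  ab <- pathway_concordance(u[1:4], u[3:8], u, n_perm = 50L, seed = 1L)
  ba <- pathway_concordance(u[3:8], u[1:4], u, n_perm = 50L, seed = 1L)
  expect_equal(ab$jaccard, ba$jaccard)
  expect_true(ab$p_perm > 0 && ab$p_perm <= 1)
  empty <- pathway_concordance(character(0), character(0), u, n_perm = 10L)
  expect_equal(empty$jaccard, 0)
  expect_true(empty$both_empty)
  expect_error(pathway_concordance("x", "term1", u, n_perm = 10L), "subsets")
})
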