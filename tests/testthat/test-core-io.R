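test_that("expression TSV round-trips and enforces identifier invariants", {
  m <- expression_matrix(matrix(c(1.5, 0, 2, 3.25), 2,
                                dimnames = list(c("TP53", "CD8A"), c("S1", "S2"))),
                         scale = "linear")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, path)
  back <- read_expression_matrix(path, scale = "linear")
  expect_equal(unclass(back)[, ], unclass(m)[, ])
  expect_identical(attr(back, "scale"), "linear")

  dup <- write_tsv_fixture(c("gene\tS1\tS1", "TP53\t1\t2"))
  expect_error(read_expression_matrix(dup), "duplicate sample")
  empty <- write_tsv_fixture("gene\tS1")
  expect_error(read_expression_matrix(empty), "no data rows")
  bad <- write_tsv_fixture(c("gene\tS1", "TP53\toops"))
  expect_error(read_expression_matrix(bad), "non-numeric")
  expect_error(expression_matrix(matrix(-1, 1, 1, dimnames = list("A", "S")),
                                 "linear"), "negative")
})

test_that("duplicate gene rows collapse by per-sample max", {
  path <- write_tsv_fixture(c("gene\tS1\tS2", "CD8A\t1\t9", "CD8A\t5\t2"))
  m <- read_expression_matrix(path, scale = "linear")
  expect_equal(unname(unclass(m)["CD8A", ]), c(5, 9))
})

test_that("GMT parsing normalises case and rejects empty sets", {
  path <- write_tsv_fixture(c("S1\tdesc\tA\tB", "S2\tdesc\ta\tb\tA"))
  sets <- read_gene_sets(path)
  expect_identical(sets$S1, c("A", "B"))
  expect_identical(sets$S2, c("A", "B"))
  bad <- write_tsv_fixture("ONLYNAME")
  expect_error(read_gene_sets(bad), "no members")
  bad2 <- write_tsv_fixture("NAME\tdesc")
  expect_error(read_gene_sets(bad2), "no members")
})

test_that("variant class follows the ref/alt length rule", {
  v <- variant_table(chrom = "chr1", pos = c(1, 2, 3),
                     ref = c("A", "AT", "A"), alt = c("AT", "A", "G"),
                     depth_tumor = 50, depth_normal = 50,
                     alt_reads_tumor = 10, af_tumor = 0.2, af_normal = 0)
  expect_identical(v$variant_class, c("insertion", "deletion", "SNV"))
  expect_error(variant_table("chr1", 1, "A", "G", 10, 10, 11, 0.5, 0),
               "exceeds depth")
  expect_error(variant_table("chr1", 0, "A", "G", 10, 10, 3, 0.5, 0), ">= 1")
})

test_that("variant tables round-trip through TSV", {
  v <- simulate_variants(variant_sim_spec(n_true_somatic = 5L, n_germline = 2L,
                                          n_artifact = 3L, seed = 7L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(v, path)
  back <- read_variant_table(path)
  expect_equal(back$af_tumor, v$af_tumor)
  expect_identical(back$variant_class, v$variant_class)
  expect_identical(attr(back, "n_skipped"), 0L)
})

test_that("VCF input honours AF precedence and counts skipped records", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR\tNORMAL",
    # AF field present: takes precedence over AD/DP (12/100 = 0.12 != 0.2)
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP:AD:AF\t0/1:100:88,12:0.2\t0/0:80:80,0:0.0",
    # no AF: falls back to AD/DP = 5/50 = 0.1
    "chr1\t200\t.\tAT\tA\t.\tPASS\t.\tGT:DP:AD\t0/1:50:45,5\t0/0:60:60,0",
    # missing AD in normal: skipped
    "chr1\t300\t.\tC\tT\t.\tPASS\t.\tGT:DP:AD\t0/1:50:40,10\t./.:.:."
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  expect_warning(v <- read_variant_table(path), "skipped 1")
  expect_equal(nrow(v), 2L)
  expect_equal(v$af_tumor, c(0.2, 0.1))
  expect_identical(v$variant_class, c("SNV", "deletion"))
  expect_identical(attr(v, "n_skipped"), 1L)
})

test_that("cell map and clinical readers validate their inputs", {
  pts <- data.frame(x = c(1, 2), y = c(3, 4), marker = "CD8",
                    compartment = c("tumor", "peritumoral"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cell_map(cell_map(pts, 1, 2), path)
  back <- read_cell_map(path, 1, 2)
  expect_equal(back$points$x, pts$x)
  expect_error(cell_map(pts, 0, 1), "positive")
  expect_error(cell_map(transform(pts, compartment = "margin"), 1, 1),
               "unknown compartment")

  clin <- make_table1_fixture()
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_clinical_table(clin, cpath)
  back <- read_clinical_table(cpath)
  expect_equal(nrow(back), 82L)
  expect_identical(back$subtype, clin$subtype)
  bad <- as.data.frame(clin)
  bad$gender[1] <- "unknown"
  expect_error(clinical_table(bad), "invalid level")
  bad2 <- as.data.frame(clin)
  bad2$metastasis[1] <- NA
  expect_error(clinical_table(bad2), "only for stage")
})
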