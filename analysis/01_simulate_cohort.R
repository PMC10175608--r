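#!/usr/bin/env Rscript
# Generate the synthetic study inputs: an 11-tumor cohort (6 inflamed /
# 2 excluded / 3 desert, mirroring the composition of a small hereditary
# MMR-deficient series) with paired normals, a CD8 cell map per tumor, and
# one paired tumor/normal variant table. Bulky inputs go to scratch/; the
# truth table to results/.

suppressPackageStartupMessages(library(immsig))

dir.create("scratch/synthetic", showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)

co <- simulate_expression_cohort(
  cohort_spec(c(inflamed = 6L, excluded = 2L, desert = 3L),
              noise_sd = 0.5, effect_size = 2, seed = 2023L))
write_expression_matrix(co$tumor, "scratch/synthetic/tumor_log2.tsv")
write_expression_matrix(co$normal, "scratch/synthetic/normal_log2.tsv")

for (id in names(co$truth)) {
  m <- simulate_cell_map(co$truth[[id]], seed = 2023L + match(id, names(co$truth)))
  write_cell_map(m, sprintf("scratch/synthetic/cells_%s.csv", id))
}

v <- simulate_variants(variant_sim_spec(n_true_somatic = 48L, n_germline = 24L,
                                        n_artifact = 30L, seed = 2023L))
write_variant_table(v, "scratch/synthetic/variants.tsv")

truth <- data.frame(sample = names(co$truth), subtype = unname(co$truth))
write.table(truth, "results/01_truth_labels.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("simulated", length(co$truth), "tumor/normal pairs,",
    nrow(v), "variant records; truth labels in results/01_truth_labels.tsv\n")
print(table(truth$subtype))
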