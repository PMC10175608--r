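#!/usr/bin/env Rscript
# Type every simulated tumor twice — from the CD8 cell map (spatial route)
# and from the tumor/normal transcriptome (enrichment route) — then
# integrate the calls and compare with the generating labels.

suppressPackageStartupMessages(library(immsig))

truth <- read.delim("results/01_truth_labels.tsv", stringsAsFactors = FALSE)
tumor <- read_expression_matrix("scratch/synthetic/tumor_log2.tsv", scale = "log2")
normal <- read_expression_matrix("scratch/synthetic/normal_log2.tsv", scale = "log2")

calls <- do.call(rbind, lapply(truth$sample, function(id) {
  map <- read_cell_map(sprintf("scratch/synthetic/cells_%s.csv", id),
                       area_tumor = 1, area_peritumoral = 1)
  spatial <- classify_spatial(cell_densities(map, "CD8"))
  transcr <- type_transcriptome(unclass(tumor)[, id, drop = FALSE],
                                unclass(normal)[, id, drop = FALSE])
  final <- integrate_calls(spatial, transcr)
  data.frame(sample = id, truth = truth$subtype[truth$sample == id],
             spatial = spatial$label, transcriptomic = transcr$label,
             integrated = final$label, confidence = final$confidence)
}))

write.table(calls, "results/02_subtype_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("spatial agreement with truth: %d/%d\n",
            sum(calls$spatial == calls$truth), nrow(calls)))
cat(sprintf("transcriptomic agreement with truth: %d/%d\n",
            sum(calls$transcriptomic == calls$truth), nrow(calls)))
cat(sprintf("spatial vs transcriptomic concordance: %d/%d\n",
            sum(calls$spatial == calls$transcriptomic), nrow(calls)))
print(calls)
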