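#!/usr/bin/env Rscript
# Somatic filtering and mutation/expression concordance: apply the five-rule
# filter to the simulated paired records, report per-rule rejections, the
# SNV/indel spectrum and TMB, and show that pathways enriched among mutated
# genes coincide with pathways enriched among down-regulated genes when they
# share a generating program.

suppressPackageStartupMessages(library(immsig))

v <- read_variant_table("scratch/synthetic/variants.tsv")
truth <- read.delim("scratch/synthetic/variants.tsv",
                    stringsAsFactors = FALSE)$truth
res <- apply_somatic_filters(v)
cat(sprintf("kept %d of %d records; rejections by rule:\n",
            nrow(res$kept), nrow(v)))
print(res$rejections)
cat(sprintf("sensitivity %.3f, specificity %.3f against simulation truth\n",
            sum(truth[as.integer(rownames(res$kept))] == "somatic") /
              sum(truth == "somatic"),
            sum(truth[as.integer(rownames(res$rejected))] != "somatic") /
              sum(truth != "somatic")))

s <- mutation_summary(res$kept, target_mb = 30)
cat(sprintf("spectrum: %d SNV (%.1f%%), %d indel (%.1f%%); TMB %.2f mut/Mb over 30 Mb\n",
            s$n_snv, 100 * s$snv_fraction, s$n_indel, 100 * s$indel_fraction,
            s$tmb))
write.table(data.frame(metric = c("n_kept", "n_snv", "n_indel", "tmb_mut_per_mb"),
                       value = c(s$n_total, s$n_snv, s$n_indel, s$tmb)),
            "results/05_mutation_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# concordance: mutated genes and down-regulated genes drawn from the same
# immune-excluded programs enrich the same terms; an unrelated draw does not
sets <- signature_gene_sets()
universe <- unique(c(unlist(sets), sprintf("BG%04d", 1:1000)))
set.seed(55)
shared <- unique(unlist(sets[c("TGFB_SIGNALING", "ANGIOGENESIS")]))
mut_terms <- enrich_sets(sample(c(shared, sample(universe, 40)), 50),
                         sets, universe)
down_terms <- enrich_sets(sample(c(shared, sample(universe, 40)), 50),
                          sets, universe)
rand_terms <- enrich_sets(sample(universe, 50), sets, universe)
term_names <- names(sets)
conc <- pathway_concordance(mut_terms$set_name[mut_terms$enriched],
                            down_terms$set_name[down_terms$enriched],
                            term_names, n_perm = 1000L, seed = 5L)
ctrl <- pathway_concordance(mut_terms$set_name[mut_terms$enriched],
                            rand_terms$set_name[rand_terms$enriched],
                            term_names, n_perm = 1000L, seed = 5L)
cat(sprintf("pathway concordance (shared program): jaccard %.2f, p_perm %.4g\n",
            conc$jaccard, conc$p_perm))
cat(sprintf("pathway concordance (unrelated control): jaccard %.2f, p_perm %.4g\n",
            ctrl$jaccard, ctrl$p_perm))
write.table(data.frame(comparison = c("shared_program", "unrelated_control"),
                       jaccard = c(conc$jaccard, ctrl$jaccard),
                       p_perm = c(conc$p_perm, ctrl$p_perm)),
            "results/05_pathway_concordance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
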