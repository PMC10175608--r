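#!/usr/bin/env Rscript
# Immune deconvolution on the synthetic toy reference: recover known
# mixtures with and without noise, and report one full composition
# (relative fractions b, overall immune fraction a, absolute a*b with a
# permutation p-value).

suppressPackageStartupMessages(library(immsig))
dir.create("results", showWarnings = FALSE)

toy <- make_toy_reference()

set.seed(33)
recovery <- do.call(rbind, lapply(c(0, 0.1), function(ns) {
  errs <- vapply(1:50, function(i) {
    b <- runif(7); b <- b / sum(b)
    mix <- simulate_mixture(toy$reference, b, noise_sd = ns, seed = 33L + i)
    mean(abs(estimate_fractions(mix, toy$reference)$b - b))
  }, numeric(1L))
  data.frame(noise_sd = ns, n_mixtures = 50L, mean_abs_error = mean(errs),
             max_abs_error = max(errs))
}))
write.table(recovery, "results/03_mixture_recovery.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("mixture recovery (mean absolute error per component):\n")
print(recovery)

# a worked composition: 60% malignant, 40% immune split over 3 types
fr <- c(T_CD8 = 0.2, T_CD4 = 0.1, B_cell = 0.1, Plasma = 0, MonoMac = 0,
        Mast = 0, Malignant = 0.6)
mix <- simulate_mixture(toy$reference, fr, noise_sd = 0.1, seed = 99L)
res <- deconvolve(mix, toy$reference, toy$immune_tags, n_perm = 1000L,
                  seed = 7L)
comp <- data.frame(cell_type = names(res$b), relative_b = res$b,
                   absolute_ab = res$absolute)
write.table(comp, "results/03_composition.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\noverall immune fraction a = %.3f (truth 0.40), fit r = %.3f, p_perm = %.4g\n",
            res$a, res$fit_correlation, res$p_perm))
print(comp, row.names = FALSE)
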