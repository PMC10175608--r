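# immsig — tumor immune-signature typing for MMR-deficient tumors

`immsig` classifies mismatch-repair (MMR)-deficient tumors into the three
tumor immune signatures — **inflamed**, **immune excluded**, **immune
desert** — from two independent data modalities, and provides the companion
analyses an immune-signature study needs. It is written for computational
oncologists working with paired tumor/normal bulk RNA-seq, scored
immunostains, and paired variant calls from MMR-deficient (e.g. Lynch
syndrome) cohorts, where the desert subtype predicts poor response to
immune checkpoint inhibition.

## What it computes

**Spatial typing.** From a marker-positive cell map (CD8 by default) with
tumor-core and peritumoral compartments, densities ρ_tumor and ρ_peri
(cells/mm²) feed a deterministic rule table: inflamed if
ρ_tumor ≥ τ_low; desert if both densities < τ_low; excluded if the core is
sparse but the stroma dense (confident when ρ_peri / max(ρ_tumor, ε) ≥
ratio_min). Defaults τ_low = 50 cells/mm², ratio_min = 5, ε = 0.1; all
configurable, all recorded in the call's evidence.

**Transcriptomic typing.** Per tumor/normal pair: DEGs (|log2FC| ≥ 1 for
single pairs; Welch + BH with replicates) → one-sided hypergeometric
over-representation P(X ≥ k), X ~ Hypergeom(N, K, n), of up-regulated genes
in signature-feature sets, BH-corrected → category score
Σ −log10(q) over a category's significant sets → argmax (min score 1.3;
ties inflamed > excluded > desert; nothing enriched ⇒ desert, low
confidence). Discordant spatial/transcriptomic calls keep the spatial
label with low confidence.

**Deconvolution.** Non-negative least squares against a cell-type signature
matrix, relative immune fractions *b*, overall immune fraction *a* from a
joint immune + malignant fit, absolute composition **a·b** (always summing
to *a*), and a gene-permutation p-value (1000 permutations, add-one rule).

**Response signatures.** 12-chemokine TLS score and 18-gene T-cell-inflamed
GEP as mean per-gene z-scores (optional weights), plus average-linkage
2-group clustering for heatmap layout.

**Somatic filtering and TMB.** The five-rule paired filter (tumor and
normal depth ≥ 10, tumor alt reads ≥ 3, tumor AF ≥ 0.05, normal AF ≤ 0.01,
caller PASS; all inclusive), per-rule rejection attribution, SNV/indel
spectrum, TMB = n / target_Mb, and mutated-versus-downregulated pathway
concordance (Jaccard with a term-level permutation null).

**Clinical associations.** 2×2 tables of desert vs excluded + inflamed
against clinicopathologic covariates, uncorrected Pearson chi-square or
two-sided Fisher (selected by the expected-count < 5 rule), and a
deterministic 82-patient fixture reproducing every published margin of the
reference cohort.

Synthetic-data generators (`simulate_expression_cohort`,
`simulate_cell_map`, `simulate_variants`, `simulate_mixture`,
`make_table1_fixture`) produce every input with known ground truth.

## Worked example

```r
library(immsig)

co <- simulate_expression_cohort(
  cohort_spec(c(inflamed = 6L, excluded = 2L, desert = 3L),
              noise_sd = 0.5, effect_size = 2, seed = 2023L))
map <- simulate_cell_map("excluded", seed = 2030L)

spatial <- classify_spatial(cell_densities(map, "CD8"))
transcr <- type_transcriptome(unclass(co$tumor)[, "EXC_07", drop = FALSE],
                              unclass(co$normal)[, "EXC_07", drop = FALSE])
integrate_calls(spatial, transcr)
#> immune signature: excluded (high confidence)
#>   - spatial and transcriptomic typing concordant: excluded
```

The numbered drivers under `analysis/` run the whole study on synthetic
data (`Rscript analysis/01_simulate_cohort.R`, then `02` … `06`), writing
tables to `results/`. On the 11-tumor cohort above, both routes recover all
11 generating labels and agree with each other (`02_subtype_calls.tsv`);
deconvolution recovers a 40%-immune mixture at a = 0.398 with fit r =
0.997 and p_perm ≈ 0.001 (`03_composition.tsv`); the GEP separates inflamed
from the rest at AUC 1.000 but excluded from desert only at 0.684
(`04_gep_auc.tsv`); the five-rule filter keeps 48/102 simulated records at
sensitivity and specificity 1.000 (`05_mutation_summary.tsv`); and the
clinical battery reports desert 32.9% / predicted-responsive 67.1% with
metastasis p = 3.4e-06, histologic type p = 0.014, age p = 0.821
(`06_table1_report.tsv`).

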