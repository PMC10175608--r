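---
title: "Typing tumor immune signatures in MMR-deficient tumors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing tumor immune signatures in MMR-deficient tumors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immsig)
```

## The three tumor immune signatures

Mismatch-repair (MMR)-deficient tumors, including those of Lynch syndrome,
are hypermutated and often — but far from always — responsive to immune
checkpoint inhibition. A useful way to stratify them is by *tumor immune
signature*, defined jointly by where T lymphocytes sit in the tissue and by
which transcriptional programs the tumor runs:

* **inflamed** — T cells disperse through the tumor core; IFN-γ response,
  intact antigen presentation, B-cell/TLS programs, PD-L1 expression;
* **immune excluded** — T cells accumulate in the peritumoral stroma but are
  kept out of the core; TGF-β signaling and angiogenesis;
* **immune desert** — T cells are absent everywhere; fatty-acid metabolism
  and neuroendocrine programs dominate.

Deserts respond worst to checkpoint blockade, so calling the signature
before therapy is clinically consequential. `immsig` implements both typing
routes (spatial and transcriptomic), their integration, and the companion
analyses a typing study needs: immune deconvolution with the absolute
`a * b` composition, the 12-chemokine TLS and 18-gene GEP response scores,
five-rule somatic variant filtering with mutational-burden summaries,
mutation-versus-expression pathway concordance, and the clinical 2×2
association battery.

## Spatial route

`cell_densities()` reduces a marker-positive cell map (CD8 by default; CD3
is an accepted alternative) to two numbers: cells/mm² in the tumor core
(`rho_tumor`) and in the peritumoral stroma (`rho_peri`), each a count
divided by an explicitly supplied compartment area. Areas come from the
annotated regions of interest, not from point hulls, because sparse maps
(the interesting ones) have degenerate hulls.

`classify_spatial()` applies a deterministic rule table:

| condition | call |
|---|---|
| `rho_tumor >= tau_low` | inflamed |
| both densities `< tau_low` | desert |
| core sparse, stroma dense, ratio ≥ `ratio_min` | excluded (high confidence) |
| core sparse, stroma dense, ratio < `ratio_min` | excluded (low confidence) |

The published definitions of "devoid" and "rich" are verbal; histologists
classify by eye. Making the thresholds explicit is the point of this
formalisation. Defaults are `tau_low = 50` cells/mm² (an order of magnitude
below densities typical of brisk infiltrates, an order above truly deserted
tissue), `ratio_min = 5` (the stroma must clearly dominate the core before a
confident exclusion call), and `eps = 0.1` cells/mm² as the denominator
floor so an empty core cannot produce an infinite ratio. All three are
arguments, and every call records the fired rule and the thresholds in its
evidence strings. The rules partition the density plane — exactly one label
per input — and raising `rho_tumor` can only move a call toward inflamed.

## Transcriptomic route

Per tumor the route is: differential expression against the matched normal →
one-sided over-representation of the up-regulated genes in signature-feature
gene sets → category scores → argmax.

**DEGs.** With a single tumor/normal pair — the design this package
anticipates, since each patient contributes one tumor and one adjacent
normal — no variance estimate exists, and `call_degs()` uses a pure
fold-change rule, `|log2FC| >= lfc_min` (default 1). With replicates in both
groups it switches to a per-gene Welch t-test with Benjamini–Hochberg
correction combined with the same fold cut-off. Both paths share one
interface; the single-pair rule is the default path exercised throughout.

**Enrichment.** `fisher_enrichment()` is the one-sided hypergeometric tail
`P(X >= k)` — the standard reading of "Fisher's exact test" for gene-set
over-representation. The universe is all genes of the expression matrix:
anything measured could have been a DEG. `bh_adjust()` is the step-up
procedure, applied across the tested sets.

**Category scores.** Each category (inflamed, excluded, desert) owns a few
feature sets (`default_category_map()`); its score is the sum of
`-log10(q)` over its sets that reached `q < 0.05`. Summing only over
significant sets keeps one strongly enriched program from being diluted by
its category's other sets, and weights all of a category's programs
uniformly — whether some "dominant" programs should count more is genuinely
open, and uniform weighting is the choice made here.

**Classification.** `classify_transcriptomic()` takes the argmax if it
reaches `min_score = 1.3` (= `-log10(0.05)`, i.e. at least one feature set
significantly enriched). Below that, the tumor shows no immune-program
enrichment at all and is called **desert with low confidence** — the
transcriptional definition of a desert is precisely the absence of immune
programs. Ties resolve by the fixed precedence inflamed > excluded > desert
(low confidence); the label is invariant to rescaling all scores by a
positive constant.

**Integration.** When spatial and transcriptomic calls agree, the label is
kept with high confidence. When they disagree, the spatial call wins with
low confidence and both labels are recorded: T-cell localisation is the
primary basis of the categorisation, and the transcriptome is treated as
confirmatory.

The seven bundled feature sets (IFN-γ response, antigen presentation,
B-cell/TLS, cytotoxic TIL, TGF-β, angiogenesis, fatty-acid metabolism,
neuroendocrine) are curated, editable GMT defaults shipped in
`inst/extdata/`; real analyses can substitute full GO/KEGG/Reactome
collections through `read_gene_sets()`.

## Deconvolution and the absolute composition

`estimate_fractions()` solves non-negative least squares
(`min ||R b − y||²`, `b ≥ 0`) over the genes shared between sample and
reference, then renormalises `b` to sum 1. NNLS is a transparent,
deterministic solver whose answer on full-rank references coincides with
the unconstrained least-squares solution whenever that solution is
feasible; the composition step this package exists for is
solver-independent, so nothing downstream depends on this choice. The fit
correlation (Pearson r between reconstruction and sample over the shared
genes) flags samples the reference cannot explain.

`permutation_pvalue()` permutes the sample's values over genes and refits;
`p = (1 + #{null >= observed}) / (n_perm + 1)` with 1000 permutations by
default. `overall_immune_fraction()` fits a joint immune + non-immune
reference and sums the immune-tagged fractions into `a`; whether a
reference-based tool should report `a` in absolute or relative mode is
ambiguous in general, and here `a` is *defined* as the immune-tagged
fraction sum of the joint fit. `absolute_fractions()` composes the final
quantity `a * b`, which always sums to `a`. `deconvolve()` derives all of
these from one joint fit so that `b`, `a`, the fit correlation and the
permutation p describe the same model; if the fit assigns no immune content
(`a = 0`), `b` is reported uniform so its sum-to-one contract holds while
`absolute` is zero.

The bundled `make_toy_reference()` (120 genes, six immune types plus one
malignant, block marker design) is **synthetic**, generated in code for
simulation and testing; it stands for no published signature matrix, and
real analyses must supply one.

## Response-prediction scores

`panel_score()` z-scores each panel gene across samples on the log2 scale
and averages; z-scoring makes the score invariant to gene-wise affine
rescaling, which matters because the bundled panels are applied to matrices
normalised elsewhere. Whether published heatmaps used raw or standardised
expression is usually unstated; standardisation is chosen here for that
invariance. Zero-variance genes score 0 with a warning; absent panel genes
are listed, not imputed. The 12-chemokine TLS panel and the 18-gene
T-cell-inflamed GEP ship as externally sourced, editable GMT defaults.
`gep_score()` accepts optional per-gene weights (the published GEP is a
weighted sum whose weights are not reproduced here) and defaults to
uniform, where it reduces exactly to `panel_score()`. `cluster_samples()`
(average-linkage on Euclidean distance of z-scored panel genes, samples
pre-sorted by id for order invariance) provides the 2-group heatmap cut.

A property worth stating: on synthetic cohorts the GEP separates inflamed
from non-inflamed tumors nearly perfectly but excluded from desert only
weakly. This is by construction — most GEP genes belong to inflamed
programs, and neither the excluded nor the desert programs touch them — and
it mirrors the empirical finding that GEPs cannot distinguish those two
subtypes, which is exactly why spatial typing adds value.

## Somatic filtering, TMB, concordance

`apply_somatic_filters()` keeps a paired record iff **all five** criteria
hold, every comparison inclusive: tumor AND normal depth ≥ 10 (the "and"
reading of depth in both tissues), tumor alt reads ≥ 3, tumor allele
fraction ≥ 0.05, normal allele fraction ≤ 0.01, caller filter `PASS`.
Rejected records are attributed to *every* rule they fail, so rejection
counts are diagnostic, not a partition. Tightening any threshold can only
shrink the kept set.

`mutation_summary()` reports the SNV/indel spectrum and
`TMB = n / target_mb`. The targeted size is a **required** argument: exome
target sizes differ by kit, published TMBs rarely state whether pre- or
post-filter counts were used, and silently assuming a denominator would
manufacture an unverifiable number.

`pathway_concordance()` quantifies the observation that pathways enriched
among somatically mutated genes mirror the pathways transcriptionally lost
in the same tumor: the Jaccard index of the two enriched-term name sets,
with significance from drawing equally-sized random term sets out of the
tested universe (add-one permutation p). Permutation is at the term level,
not the gene level, because the comparison is between enriched-pathway
panels.

## Clinical associations

`build_contingency()` fixes the columns as desert versus excluded +
inflamed — the predicted non-responders versus potential responders — and
rows as the requested covariate split; patients missing the covariate
(stage, in practice) are excluded and counted. `chi_square_p()` is the
**uncorrected** Pearson chi-square: on the bundled 82-patient fixture it
reproduces the published association p-values (age 0.821, gender 0.825,
colon location 0.455, infiltration 0.678, histologic type 0.014) to three
decimals, which the Yates-corrected statistic does not; `fisher_exact_p()`
is the two-sided exact test (tables as or less probable than observed).
`select_test()` uses the conventional rule — any expected count below 5
selects Fisher — and with it the cecum-location row reproduces its
published 0.073. Two caveats the package reports but does not force: the
stage row's published 0.833 is not reproduced by uncorrected chi-square
(0.254), Yates (0.657) or two-sided Fisher (0.533) on the printed counts,
and the tumor-size row computes to 1.8e-4 (chi-square) / 4.3e-4 (Fisher)
rather than the published "< 0.0001"; both rows are reported as computed.

`make_table1_fixture()` deterministically reconstructs an 82-patient table
(27 desert / 28 excluded / 27 inflamed) whose every subtype-by-covariate
margin matches the published counts exactly. Only those margins are
published; within a subtype, covariate levels are assigned greedily (the
first *k* patients take the first level), which realises all margins
jointly because each covariate is constrained independently given the
subtype. Any joint structure *between* covariates in the fixture is
therefore arbitrary, and no analysis here depends on it.

## What the generators emulate — and what they do not

`simulate_expression_cohort()` draws matched tumor/normal log2 matrices in
which subtype-k tumors up-regulate category-k genes by `effect_size`
(default 2, a 4-fold change — strong but ordinary for marker programs) over
a flat baseline (default 5) with i.i.d. Gaussian noise (default
`noise_sd = 0.5` per sample, so log2FC noise sd ≈ 0.71 — comparable to
replicate scatter in bulk data). `simulate_cell_map()` is a homogeneous
Poisson process per compartment with subtype intensities desert (2, 3),
excluded (2, 400), inflamed (400, 400) cells/mm² — an order of magnitude on
either side of `tau_low`, as the verbal definitions ("devoid" versus
"rich") imply. `simulate_variants()` places true somatics inside all five
filter boundaries (a quarter exactly *on* them), germline records at
matched tumor/normal allele fraction, and artifacts violating exactly one
rule each with one-off boundary probes (depth 9, alt reads 2, AF 0.049,
normal AF 0.011, non-PASS). All generators are pure functions of their
spec and seed.

These simulations validate the machinery, not the biology: real
transcriptomes have correlated genes, compositional structure, batch and
purity effects; real infiltrates cluster (TLSs are the extreme case) rather
than scattering as Poisson points; real variant callers produce error modes
far richer than single-rule boundary violations. Passing on synthetic data
shows the rules and estimators do what they claim under their stated model
— it does not show the thresholds are optimal for any particular cohort.

## Numerical choices and scales

Degenerate inputs are defined, not crashed on: z of a constant gene is 0
(warned), spectrum fractions of an empty mutation set are 0 (flagged),
Jaccard of two empty sets is 0 (flagged), permutation p-values use the
add-one rule so they can never be 0. Duplicate gene rows collapse by
per-sample max, preserving marker signal. VCF allele fractions prefer the
`FORMAT/AF` field and fall back to `AD/DP`. Reported analyses use 60-tumor
cohorts (20 per subtype) for recovery rates, 50 replicate mixtures for
deconvolution error, 50 simulated cohorts for the GEP AUC comparison, and
200 maps for spatial recovery — sizes at which the binomial noise on a
reported rate is a few percent, chosen to keep the whole suite fast to
re-run.

## Limitations

The spatial thresholds are explicit stand-ins for expert judgment, not
fitted quantities. The transcriptomic route inherits everything that is
hard about single-pair designs: no variance estimate, so the fold cut-off
is doing all the work. The bundled gene sets and panels are compact
defaults, not the full collections a production analysis would use. The
deconvolution reference is a synthetic toy; absolute compositions are only
as good as the reference supplied. And the clinical fixture reproduces
published margins, not patients — associations beyond those margins are
not recoverable from it.
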