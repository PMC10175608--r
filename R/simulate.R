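#' Specification of a synthetic tumor/normal expression cohort
#'
#' Defines the generating conditions for [simulate_expression_cohort()]:
#' tumors of each immune-signature subtype up-regulate the genes of that
#' subtype's feature programs by `effect_size` log2-fold relative to the
#' matched normal, on a shared log2 baseline with Gaussian noise.
#'
#' @param n_per_subtype Named integer vector `c(inflamed=, excluded=, desert=)`.
#' @param n_genes Total number of genes including background (at least the
#'   size of the combined feature programs plus 100).
#' @param effect_size Log2 fold change of category genes in tumors, `> 0`.
#' @param noise_sd Gaussian noise sd on the log2 scale, applied independently
#'   to tumor and normal, `>= 0`.
#' @param baseline_mean Log2 baseline expression of every gene.
#' @param seed Integer seed making the cohort reproducible.
#' @return A list with class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_per_subtype = c(inflamed = 4L, excluded = 4L, desert = 3L),
                        n_genes = 1500L, effect_size = 2, noise_sd = 0.5,
                        baseline_mean = 5, seed = 1L) {
  stopifnot(all(c("inflamed", "excluded", "desert") %in% names(n_per_subtype)))
  if (any(n_per_subtype < 1L)) stop("need at least one tumor per subtype")
  if (effect_size <= 0) stop("effect_size must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_per_subtype = n_per_subtype, n_genes = as.integer(n_genes),
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a tumor/normal expression cohort with known subtypes
#'
#' Builds paired tumor and matched-normal log2 expression matrices over the
#' bundled signature-feature programs, the bundled response panels, and
#' background genes. A tumor of subtype k carries its category genes at
#' `baseline_mean + effect_size`; all other genes, and all normal samples,
#' sit at `baseline_mean`. Independent Gaussian noise (`noise_sd`) is added
#' to every value.
#'
#' @param spec A [cohort_spec()].
#' @return List with elements `tumor` and `normal` ([expression_matrix()]s,
#'   log2 scale, one column per tumor), `truth` (named subtype labels) and
#'   `category_genes` (list of per-category gene vectors).
#' @export
simulate_expression_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  sets <- signature_gene_sets()
  cmap <- default_category_map()
  category_genes <- lapply(cmap, function(nm) sort(unique(unlist(sets[nm]))))
  panel_genes <- union(chemokine12_panel(), gep18_panel())
  feature_genes <- sort(unique(c(unlist(category_genes), panel_genes)))
  n_bg <- spec$n_genes - length(feature_genes)
  if (n_bg < 100L) stop("n_genes leaves fewer than 100 background genes")
  genes <- c(feature_genes, sprintf("BG%04d", seq_len(n_bg)))

  labels <- rep(names(spec$n_per_subtype), spec$n_per_subtype)
  ids <- sprintf("%s_%02d", toupper(substr(labels, 1, 3)), seq_along(labels))
  names(labels) <- ids

  set.seed(spec$seed)
  mu <- matrix(spec$baseline_mean, nrow = length(genes), ncol = length(ids),
               dimnames = list(genes, ids))
  for (j in seq_along(ids)) {
    mu[category_genes[[labels[j]]], j] <- spec$baseline_mean + spec$effect_size
  }
  noise <- function() matrix(stats::rnorm(length(mu), sd = spec$noise_sd),
                             nrow = nrow(mu))
  tumor <- mu + noise()
  normal <- matrix(spec$baseline_mean, nrow = nrow(mu), ncol = ncol(mu),
                   dimnames = dimnames(mu)) + noise()
  list(tumor = expression_matrix(tumor, scale = "log2"),
       normal = expression_matrix(normal, scale = "log2"),
       truth = labels, category_genes = category_genes)
}

#' Simulate a bulk sample as a known mixture of reference signatures
#'
#' The noise-free sample is the convex combination `reference %*% fractions`;
#' multiplicative log-normal noise (`2^N(0, noise_sd)` per gene) emulates
#' measurement error on normalized linear-scale expression.
#'
#' @param reference Linear-scale [expression_matrix()], one column per cell
#'   type.
#' @param fractions Non-negative vector, one per reference column, summing to
#'   1 (tolerance 1e-8).
#' @param noise_sd Log2-scale noise sd, `>= 0`.
#' @param seed Integer seed.
#' @return Named numeric vector over the reference genes.
#' @export
simulate_mixture <- function(reference, fractions, noise_sd = 0, seed = 1L) {
  if (length(fractions) != ncol(reference)) {
    stop("fractions must have one entry per reference column")
  }
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be non-negative and sum to 1 (tolerance 1e-8)")
  }
  sample <- drop(unclass(reference) %*% fractions)
  if (noise_sd > 0) {
    set.seed(seed)
    sample <- sample * 2^stats::rnorm(length(sample), sd = noise_sd)
  }
  stats::setNames(sample, rownames(reference))
}

#' Specification for simulated paired variant records
#'
#' @param n_true_somatic Number of true somatic records. A quarter of them
#'   (rounded down, at least one when any are requested) are placed exactly
#'   on the five inclusive filter boundaries (depth 10, alt reads 3,
#'   tumor AF 0.05, normal AF 0.01, PASS).
#' @param n_germline Germline records: matched tumor/normal allele fraction
#'   near 0.5, so only the normal-AF rule rejects them.
#' @param n_artifact Artifact records, each violating exactly one filter rule
#'   with boundary probes (depth 9, alt reads 2, tumor AF 0.049, normal AF
#'   0.011, non-PASS), cycled over the rules.
#' @param depth_range Integer range for sequencing depth of clean records.
#' @param fraction_indel Fraction of records drawn as insertions/deletions.
#' @param seed Integer seed.
#' @return A list with class `"variant_sim_spec"`.
#' @export
variant_sim_spec <- function(n_true_somatic = 40L, n_germline = 20L,
                             n_artifact = 24L, depth_range = c(30L, 200L),
                             fraction_indel = 0.15, seed = 1L) {
  if (fraction_indel < 0 || fraction_indel > 1) stop("fraction_indel in [0,1]")
  if (any(depth_range < 10L)) stop("depth_range must allow depth >= 10")
  structure(list(n_true_somatic = as.integer(n_true_somatic),
                 n_germline = as.integer(n_germline),
                 n_artifact = as.integer(n_artifact),
                 depth_range = as.integer(depth_range),
                 fraction_indel = fraction_indel, seed = as.integer(seed)),
            class = "variant_sim_spec")
}

#' Simulate paired variant records with known somatic/germline/artifact truth
#'
#' @param spec A [variant_sim_spec()].
#' @return A [variant_table()] with an extra `truth` column
#'   (`"somatic"`/`"germline"`/`"artifact"`).
#' @export
simulate_variants <- function(spec = variant_sim_spec()) {
  stopifnot(inherits(spec, "variant_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_true_somatic + spec$n_germline + spec$n_artifact
  if (n == 0L) stop("spec requests no records")
  rdepth <- function(k) sample(seq(spec$depth_range[1L], spec$depth_range[2L]), k,
                               replace = TRUE)
  rows <- list()
  add <- function(truth, depth_t, depth_n, af_t, af_n, alt_t, filt) {
    rows[[length(rows) + 1L]] <<- data.frame(
      truth = truth, depth_tumor = depth_t, depth_normal = depth_n,
      af_tumor = af_t, af_normal = af_n, alt_reads_tumor = alt_t,
      filter_status = filt, stringsAsFactors = FALSE)
  }
  if (spec$n_true_somatic > 0L) {
    n_bound <- max(1L, spec$n_true_somatic %/% 4L)
    for (i in seq_len(n_bound)) add("somatic", 10L, 10L, 0.05, 0.01, 3L, "PASS")
    n_free <- spec$n_true_somatic - n_bound
    if (n_free > 0L) {
      d <- rdepth(n_free)
      af <- stats::runif(n_free, 0.10, 0.60)
      alt <- pmax(3L, as.integer(round(af * d)))
      for (i in seq_len(n_free)) {
        add("somatic", d[i], rdepth(1L), af[i], 0, alt[i], "PASS")
      }
    }
  }
  if (spec$n_germline > 0L) {
    d <- rdepth(spec$n_germline)
    af <- stats::runif(spec$n_germline, 0.35, 0.65)
    for (i in seq_len(spec$n_germline)) {
      add("germline", d[i], rdepth(1L), af[i], af[i],
          pmax(3L, as.integer(round(af[i] * d[i]))), "PASS")
    }
  }
  if (spec$n_artifact > 0L) {
    kinds <- rep(c("depth_tumor", "depth_normal", "alt_reads", "af_tumor",
                   "af_normal", "filter"), length.out = spec$n_artifact)
    for (k in kinds) {
      d <- rdepth(1L)
      switch(k,
        depth_tumor  = add("artifact", 9L, rdepth(1L), 0.4, 0, 3L, "PASS"),
        depth_normal = add("artifact", d, 9L, 0.4, 0, pmax(3L, round(0.4 * d)), "PASS"),
        alt_reads    = add("artifact", max(d, 40L), rdepth(1L), 0.05, 0, 2L, "PASS"),
        af_tumor     = add("artifact", d, rdepth(1L), 0.049, 0,
                           pmax(3L, as.integer(round(0.049 * d))), "PASS"),
        af_normal    = add("artifact", d, rdepth(1L), 0.4, 0.011,
                           pmax(3L, round(0.4 * d)), "PASS"),
        filter       = add("artifact", d, rdepth(1L), 0.4, 0,
                           pmax(3L, round(0.4 * d)), "germline_risk"))
    }
  }
  df <- do.call(rbind, rows)
  is_indel <- stats::runif(nrow(df)) < spec$fraction_indel
  ref <- ifelse(is_indel & stats::runif(nrow(df)) < 0.5, "AT", "A")
  alt <- ifelse(ref == "AT", "A", ifelse(is_indel, "AT", "G"))
  out <- variant_table(
    chrom = sample(paste0("chr", 1:22), nrow(df), replace = TRUE),
    pos = sample.int(1e8, nrow(df)), ref = ref, alt = alt,
    depth_tumor = df$depth_tumor, depth_normal = df$depth_normal,
    alt_reads_tumor = pmin(df$alt_reads_tumor, df$depth_tumor),
    af_tumor = df$af_tumor, af_normal = df$af_normal,
    filter_status = df$filter_status,
    gene = sprintf("GENE%03d", sample.int(500L, nrow(df), replace = TRUE)))
  out$truth <- df$truth
  out
}

#' Simulate a CD8+ cell map of a given immune-signature subtype
#'
#' Homogeneous Poisson point process per compartment: the inflamed subtype is
#' dense in both compartments, immune excluded dense only peritumorally, and
#' immune desert sparse everywhere. Compartments are adjacent unit squares
#' (tumor core at x in \[0, 1000\] um, peritumoral stroma at x in
#' \[1000, 2000\] um) of 1 mm^2 each by default.
#'
#' @param subtype `"inflamed"`, `"excluded"` or `"desert"`.
#' @param intensities Named list of per-subtype `c(tumor, peri)` intensities
#'   in cells/mm^2.
#' @param area_tumor,area_peritumoral Compartment areas in mm^2.
#' @param marker Marker label for the points.
#' @param seed Integer seed.
#' @return A [cell_map()].
#' @export
simulate_cell_map <- function(subtype = c("desert", "excluded", "inflamed"),
                              intensities = list(desert = c(2, 3),
                                                 excluded = c(2, 400),
                                                 inflamed = c(400, 400)),
                              area_tumor = 1, area_peritumoral = 1,
                              marker = "CD8", seed = 1L) {
  subtype <- match.arg(subtype)
  lam <- intensities[[subtype]]
  set.seed(seed)
  side_t <- 1000 * sqrt(area_tumor)
  side_p <- 1000 * sqrt(area_peritumoral)
  n_t <- stats::rpois(1L, lam[1L] * area_tumor)
  n_p <- stats::rpois(1L, lam[2L] * area_peritumoral)
  pts <- data.frame(
    x = c(stats::runif(n_t, 0, side_t), stats::runif(n_p, side_t, side_t + side_p)),
    y = c(stats::runif(n_t, 0, side_t), stats::runif(n_p, 0, side_p)),
    marker = rep(marker, n_t + n_p),
    compartment = rep(c("tumor", "peritumoral"), c(n_t, n_p)),
    stringsAsFactors = FALSE)
  cell_map(pts, area_tumor, area_peritumoral)
}

#' Deterministic 82-patient clinical fixture
#'
#' Reconstructs a per-patient clinical table whose cross-tabulations of
#' immune-signature subtype against every clinicopathologic covariate
#' reproduce the published per-row counts of the 82-patient
#' MMR-deficient cohort exactly (27 desert, 28 excluded, 27 inflamed).
#' Only the subtype-by-covariate margins are published; within each subtype
#' the covariate levels are assigned to patients greedily (the first k
#' patients of a subtype take the first level), which realises all margins
#' jointly because each covariate is constrained independently.
#'
#' @return A [clinical_table()] with 82 rows.
#' @export
make_table1_fixture <- function() {
  # per-subtype counts taking the FIRST level of each covariate
  # (desert n=27, excluded n=28, inflamed n=27)
  n_sub <- c(desert = 27L, excluded = 28L, inflamed = 27L)
  first_level <- list(
    age_group       = c(desert = 12L, excluded =  9L, inflamed = 14L), # <50
    gender          = c(desert =  9L, excluded = 10L, inflamed =  7L), # female
    metastasis      = c(desert = 16L, excluded =  3L, inflamed =  3L), # yes
    tumor_size      = c(desert = 19L, excluded = 27L, inflamed = 27L), # <3cm
    location1       = c(desert = 18L, excluded = 20L, inflamed = 21L), # colon
    location2       = c(desert =  6L, excluded =  2L, inflamed =  2L), # cecum
    histologic_type = c(desert =  7L, excluded = 19L, inflamed = 11L), # MDA+MHDA
    infiltration    = c(desert = 17L, excluded = 18L, inflamed = 14L)  # WLIW
  )
  # stage has three states: T1+T2, T3+T4, missing
  stage_counts <- list(desert = c(0L, 6L, 21L), excluded = c(2L, 6L, 20L),
                       inflamed = c(1L, 7L, 19L))
  rows <- lapply(names(n_sub), function(s) {
    n <- n_sub[[s]]
    df <- data.frame(id = sprintf("%s_%02d", s, seq_len(n)), subtype = s,
                     stringsAsFactors = FALSE)
    for (col in names(first_level)) {
      k <- first_level[[col]][[s]]
      lv <- clinical_levels[[col]]
      df[[col]] <- rep(lv, c(k, n - k))
    }
    sc <- stage_counts[[s]]
    df$stage <- rep(c("T1+T2", "T3+T4", NA), sc)
    df
  })
  df <- do.call(rbind, rows)
  clinical_table(df[, c("id", names(clinical_levels))])
}
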