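#' Run the typing pipeline over configured inputs
#'
#' Orchestrates the per-tumor stages — spatial typing from a cell map,
#' transcriptomic typing from a tumor/normal expression pair, integration,
#' deconvolution, response-signature scoring, somatic filtering — plus the
#' cohort-level clinical association report. Stages whose inputs are absent
#' from the configuration are skipped and noted in the report, not errors.
#'
#' @param config A named list, or path to a YAML file with the same
#'   structure. Recognised entries (all optional except at least one input):
#'   \describe{
#'     \item{expression}{`tumor`, `normal`: paths to log2 TSV matrices with
#'       matching sample columns.}
#'     \item{cell_maps}{named list per sample: `path` (CSV), `area_tumor`,
#'       `area_peritumoral`, optional `marker`.}
#'     \item{variants}{named list per sample: path to a VCF/TSV of paired
#'       records; plus top-level `target_mb` for the TMB.}
#'     \item{deconvolution}{`reference` path (linear TSV) and `immune_types`
#'       (character vector of immune column names); omit to use the bundled
#'       synthetic toy reference.}
#'     \item{clinical}{path to a clinical covariate CSV.}
#'     \item{thresholds}{`tau_low`, `ratio_min`, `lfc_min`, `q_max`,
#'       `min_score`, and the [filter_thresholds()] fields.}
#'     \item{n_perm, seed}{permutation settings.}
#'   }
#' @return List with `samples` (per-sample reports), `associations` (the
#'   [table1_report()] or `NULL`), and `provenance` (thresholds and seeds
#'   used).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  if (is.null(config$expression) && is.null(config$cell_maps) &&
      is.null(config$variants) && is.null(config$clinical)) {
    stop("config provides no inputs")
  }
  th <- config$thresholds
  get <- function(name, default) if (is.null(th[[name]])) default else th[[name]]
  tau_low <- get("tau_low", 50); ratio_min <- get("ratio_min", 5)
  lfc_min <- get("lfc_min", 1); q_max <- get("q_max", 0.05)
  min_score <- get("min_score", 1.3)
  ft <- filter_thresholds(get("min_depth", 10L), get("min_alt_reads", 3L),
                          get("min_af_tumor", 0.05), get("max_af_normal", 0.01),
                          get("require_pass", TRUE))
  n_perm <- if (is.null(config$n_perm)) 1000L else as.integer(config$n_perm)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  tumor <- normal <- NULL
  if (!is.null(config$expression)) {
    tumor <- read_expression_matrix(config$expression$tumor, scale = "log2")
    normal <- read_expression_matrix(config$expression$normal, scale = "log2")
  }
  if (!is.null(config$deconvolution)) {
    reference <- read_expression_matrix(config$deconvolution$reference,
                                        scale = "linear")
    immune_tags <- colnames(reference) %in% config$deconvolution$immune_types
  } else {
    toy <- make_toy_reference()
    reference <- toy$reference; immune_tags <- toy$immune_tags
  }

  ids <- unique(c(colnames(tumor), names(config$cell_maps),
                  names(config$variants)))
  samples <- lapply(ids, function(id) {
    rep <- list(sample = id, skipped = character(0))
    spatial <- transcriptomic <- NULL
    cm_cfg <- config$cell_maps[[id]]
    if (!is.null(cm_cfg)) {
      map <- read_cell_map(cm_cfg$path, cm_cfg$area_tumor, cm_cfg$area_peritumoral)
      marker <- if (is.null(cm_cfg$marker)) "CD8" else cm_cfg$marker
      spatial <- classify_spatial(cell_densities(map, marker),
                                  tau_low = tau_low, ratio_min = ratio_min)
    } else rep$skipped <- c(rep$skipped, "spatial")
    if (!is.null(tumor) && id %in% colnames(tumor) && id %in% colnames(normal)) {
      transcriptomic <- type_transcriptome(
        unclass(tumor)[, id, drop = FALSE], unclass(normal)[, id, drop = FALSE],
        lfc_min = lfc_min, q_max = q_max, min_score = min_score)
      lin <- 2^unclass(tumor)[, id]
      if (length(intersect(names(lin), rownames(reference)))) {
        rep$deconvolution <- deconvolve(lin, reference, immune_tags,
                                        n_perm = n_perm, seed = seed)
      } else {
        rep$skipped <- c(rep$skipped, "deconvolution")
      }
    } else rep$skipped <- c(rep$skipped, "transcriptomic", "deconvolution")
    v_cfg <- config$variants[[id]]
    if (!is.null(v_cfg)) {
      recs <- read_variant_table(v_cfg)
      filt <- apply_somatic_filters(recs, ft)
      tmb_mb <- config$target_mb
      rep$mutation <- if (is.null(tmb_mb)) {
        list(filtered = filt, summary = NULL)
      } else {
        list(filtered = filt, summary = mutation_summary(filt$kept, tmb_mb))
      }
    } else rep$skipped <- c(rep$skipped, "somatic")
    rep$spatial <- spatial
    rep$transcriptomic <- transcriptomic
    rep$integrated <- if (is.null(spatial) && is.null(transcriptomic)) NULL
                      else integrate_calls(spatial, transcriptomic)
    rep
  })
  names(samples) <- ids

  if (!is.null(tumor) && ncol(tumor) >= 2L) {
    chemo <- panel_score(tumor, chemokine12_panel())
    gep <- gep_score(tumor)
    for (id in colnames(tumor)) {
      samples[[id]]$chemokine12 <- unname(chemo$scores[id])
      samples[[id]]$gep18 <- unname(gep$scores[id])
    }
  }

  associations <- NULL
  if (!is.null(config$clinical)) {
    associations <- table1_report(read_clinical_table(config$clinical))
  }
  list(samples = samples, associations = associations,
       provenance = list(tau_low = tau_low, ratio_min = ratio_min,
                         lfc_min = lfc_min, q_max = q_max,
                         min_score = min_score, filter = unclass(ft),
                         n_perm = n_perm, seed = seed))
}
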