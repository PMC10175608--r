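#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Member symbols are
#' uppercase-normalised so that matching against expression matrices is
#' case-insensitive.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (unique, uppercase gene symbols).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    members <- unique(toupper(fields[-(1:2)]))
    members <- members[nzchar(members)]
    if (length(fields) < 3L || length(members) == 0L) {
      stop(sprintf("gene set '%s' (line %d) has no members", fields[1L], i))
    }
    stats::setNames(list(members), fields[1L])
  })
  sets <- unlist(sets, recursive = FALSE)
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene-set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(name, desc, members) {
    paste(c(name, desc, members), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Bundled immune-signature feature gene sets
#'
#' Seven curated feature sets covering the transcriptional programs that
#' characterise the three tumor immune signatures: IFN-gamma response,
#' antigen presentation, B-cell/TLS and cytotoxic-TIL programs (inflamed);
#' TGF-beta signaling and angiogenesis (immune excluded); fatty-acid
#' metabolism and neuroendocrine markers (immune desert). These are editable
#' defaults assembled from the source literature on the three phenotypes;
#' substitute full GO/KEGG/Reactome collections for real analyses.
#'
#' @return A named list of character vectors.
#' @export
signature_gene_sets <- function() {
  read_gene_sets(system.file("extdata", "immune_signature_sets.gmt",
                             package = "immsig", mustWork = TRUE))
}

#' Map signature-feature gene sets to immune-signature categories
#'
#' @return A named list with elements `inflamed`, `excluded` and `desert`,
#'   each a character vector of gene-set names present in
#'   [signature_gene_sets()].
#' @export
default_category_map <- function() {
  list(
    inflamed = c("IFNG_RESPONSE", "ANTIGEN_PRESENTATION", "TLS_B_CELL",
                 "TIL_CYTOTOXIC"),
    excluded = c("TGFB_SIGNALING", "ANGIOGENESIS"),
    desert   = c("FATTY_ACID_METABOLISM", "NEUROENDOCRINE")
  )
}

#' The 12-chemokine tertiary-lymphoid-structure signature panel
#'
#' Chemokine panel used to detect tertiary lymphoid structures from bulk
#' transcriptomes in colorectal cancer.
#'
#' @return Character vector of 12 gene symbols.
#' @export
chemokine12_panel <- function() {
  read_gene_sets(system.file("extdata", "response_panels.gmt",
                             package = "immsig", mustWork = TRUE))[["CHEMOKINE12"]]
}

#' The 18-gene T-cell-inflamed gene expression profile (GEP) panel
#'
#' IFN-gamma-related panel developed to predict clinical response to PD-1
#' blockade.
#'
#' @return Character vector of 18 gene symbols.
#' @export
gep18_panel <- function() {
  read_gene_sets(system.file("extdata", "response_panels.gmt",
                             package = "immsig", mustWork = TRUE))[["GEP18"]]
}
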