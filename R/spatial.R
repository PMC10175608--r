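#' Per-compartment immune-cell densities
#'
#' Counts marker-positive cells in the tumor core and peritumoral stroma and
#' divides by the respective compartment area.
#'
#' @param map A [cell_map()].
#' @param marker Marker label to count (default `"CD8"`).
#' @return List with `rho_tumor`, `rho_peri` (cells/mm^2), `n_tumor`,
#'   `n_peri`.
#' @export
cell_densities <- function(map, marker = "CD8") {
  stopifnot(inherits(map, "cell_map"))
  pts <- map$points[map$points$marker == marker, , drop = FALSE]
  n_t <- sum(pts$compartment == "tumor")
  n_p <- sum(pts$compartment == "peritumoral")
  list(rho_tumor = n_t / map$area_tumor, rho_peri = n_p / map$area_peritumoral,
       n_tumor = n_t, n_peri = n_p)
}

subtype_call <- function(label, scores, evidence, confidence) {
  structure(list(label = label, scores = scores, evidence = evidence,
                 confidence = confidence),
            class = "subtype_call")
}

#' @export
print.subtype_call <- function(x, ...) {
  cat(sprintf("immune signature: %s (%s confidence)\n", x$label, x$confidence))
  if (length(x$evidence)) cat(paste0("  - ", x$evidence, collapse = "\n"), "\n")
  invisible(x)
}

#' Classify the immune signature from compartment densities
#'
#' Deterministic rule table over the T-cell density in the tumor core
#' (`rho_tumor`) and the peritumoral stroma (`rho_peri`):
#' * inflamed: `rho_tumor >= tau_low` (T cells disperse through the tumor);
#' * desert: both densities below `tau_low` (tumor devoid of T cells);
#' * excluded: sparse core but dense stroma (`rho_peri >= tau_low`); the call
#'   has high confidence when the stroma-to-core ratio
#'   `rho_peri / max(rho_tumor, eps)` reaches `ratio_min`, and low confidence
#'   in the ambiguous band below it.
#' The rules partition the density plane, so every input gets exactly one
#' label. The published definitions are verbal; the numeric cut-offs are this
#' package's explicit defaults and are recorded in the evidence strings.
#'
#' @param d Output of [cell_densities()].
#' @param tau_low Density separating "devoid" from "infiltrated", cells/mm^2.
#' @param ratio_min Minimum stroma/core density ratio for a confident
#'   excluded call.
#' @param eps Floor for the core density in the ratio (cells/mm^2).
#' @return A `subtype_call`.
#' @export
classify_spatial <- function(d, tau_low = 50, ratio_min = 5, eps = 0.1) {
  if (tau_low <= 0 || ratio_min <= 0) stop("thresholds must be > 0")
  rt <- d$rho_tumor; rp <- d$rho_peri
  ratio <- rp / max(rt, eps)
  ev <- sprintf("rho_tumor=%.3g, rho_peri=%.3g cells/mm^2 (tau_low=%g, ratio_min=%g)",
                rt, rp, tau_low, ratio_min)
  if (rt >= tau_low) {
    call <- subtype_call("inflamed", c(rho_tumor = rt, rho_peri = rp),
                         c(ev, "rule: rho_tumor >= tau_low -> inflamed"), "high")
  } else if (rp < tau_low) {
    call <- subtype_call("desert", c(rho_tumor = rt, rho_peri = rp),
                         c(ev, "rule: both densities < tau_low -> desert"), "high")
  } else if (ratio >= ratio_min) {
    call <- subtype_call("excluded", c(rho_tumor = rt, rho_peri = rp),
                         c(ev, sprintf("rule: sparse core, dense stroma (ratio %.3g >= %g) -> excluded",
                                       ratio, ratio_min)), "high")
  } else {
    call <- subtype_call("excluded", c(rho_tumor = rt, rho_peri = rp),
                         c(ev, sprintf("rule: sparse core, dense stroma but ratio %.3g < %g -> excluded (ambiguous)",
                                       ratio, ratio_min)), "low")
  }
  call
}
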