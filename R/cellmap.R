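#' Construct a cell map
#'
#' A cell map is the point set produced by scoring an immunostained section:
#' marker-positive cell centroids (micrometre coordinates, arbitrary origin),
#' each assigned to the tumor core or the peritumoral stroma, plus the two
#' compartment areas in mm^2. Areas are supplied explicitly (from the
#' annotated regions of interest) rather than inferred from point hulls.
#'
#' @param points `data.frame` with columns `x`, `y` (micrometres), `marker`
#'   (e.g. `"CD8"`), `compartment` (`"tumor"` or `"peritumoral"`).
#' @param area_tumor,area_peritumoral Compartment areas in mm^2, `> 0`.
#' @return A list with class `"cell_map"`.
#' @export
cell_map <- function(points, area_tumor, area_peritumoral) {
  if (!all(c("x", "y", "marker", "compartment") %in% colnames(points))) {
    stop("`points` needs columns x, y, marker, compartment")
  }
  bad <- setdiff(unique(points$compartment), c("tumor", "peritumoral"))
  if (length(bad)) stop("unknown compartment label(s): ", paste(bad, collapse = ", "))
  if (!is.finite(area_tumor) || !is.finite(area_peritumoral) ||
      area_tumor <= 0 || area_peritumoral <= 0) {
    stop("compartment areas must be positive")
  }
  structure(list(points = as.data.frame(points),
                 area_tumor = area_tumor,
                 area_peritumoral = area_peritumoral),
            class = "cell_map")
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("cell map: %d points (%d tumor / %d peritumoral), areas %.3g / %.3g mm^2\n",
              nrow(x$points), sum(x$points$compartment == "tumor"),
              sum(x$points$compartment == "peritumoral"),
              x$area_tumor, x$area_peritumoral))
  invisible(x)
}

#' Read a cell map from CSV
#'
#' Expects columns `x`, `y`, `marker`, `compartment`.
#'
#' @param path CSV path.
#' @inheritParams cell_map
#' @return A [cell_map()].
#' @export
read_cell_map <- function(path, area_tumor, area_peritumoral) {
  pts <- utils::read.csv(path, stringsAsFactors = FALSE)
  cell_map(pts, area_tumor, area_peritumoral)
}

#' Write a cell map's points to CSV
#'
#' @param map A [cell_map()].
#' @param path Output path.
#' @export
write_cell_map <- function(map, path) {
  utils::write.csv(map$points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
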