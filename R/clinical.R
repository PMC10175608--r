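clinical_levels <- list(
  age_group       = c("<50", ">=50"),
  gender          = c("female", "male"),
  metastasis      = c("yes", "no"),
  tumor_size      = c("<3cm", ">=3cm"),
  location1       = c("colon", "others"),
  location2       = c("cecum", "others"),
  histologic_type = c("MDA+MHDA", "others"),
  stage           = c("T1+T2", "T3+T4"),
  infiltration    = c("WLIW", "others"),
  subtype         = c("desert", "excluded", "inflamed")
)

#' Validate a per-patient clinical covariate table
#'
#' One row per patient with the categorical covariates of the
#' clinicopathologic association analysis plus the immune-signature subtype.
#' All covariates are restricted to their defined levels; only `stage` may be
#' missing (`NA`).
#'
#' @param df A `data.frame` with columns `id`, `age_group` (`"<50"`/`">=50"`),
#'   `gender`, `metastasis`, `tumor_size` (`"<3cm"`/`">=3cm"`), `location1`
#'   (`"colon"`/`"others"`), `location2` (`"cecum"`/`"others"`),
#'   `histologic_type` (`"MDA+MHDA"`/`"others"`), `stage`
#'   (`"T1+T2"`/`"T3+T4"`/`NA`), `infiltration` (`"WLIW"`/`"others"`),
#'   `subtype` (`"desert"`/`"excluded"`/`"inflamed"`).
#' @return The validated `data.frame` with class `"clinical_table"`.
#' @export
clinical_table <- function(df) {
  needed <- c("id", names(clinical_levels))
  missing <- setdiff(needed, colnames(df))
  if (length(missing)) stop("clinical table lacks columns: ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(df$id)) stop("duplicate patient identifiers")
  for (col in names(clinical_levels)) {
    vals <- df[[col]]
    if (col != "stage" && anyNA(vals)) {
      stop("missing values allowed only for stage, found in ", col)
    }
    bad <- setdiff(unique(vals[!is.na(vals)]), clinical_levels[[col]])
    if (length(bad)) {
      stop(sprintf("invalid level(s) in %s: %s", col, paste(bad, collapse = ", ")))
    }
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a clinical covariate table from CSV
#'
#' @param path CSV path with the columns of [clinical_table()]; empty cells
#'   are treated as missing.
#' @return A [clinical_table()].
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  clinical_table(df)
}

#' Write a clinical table to CSV
#'
#' @param x A [clinical_table()].
#' @param path Output path.
#' @export
write_clinical_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}
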