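#' Construct a table of paired tumor/normal variant records
#'
#' One row per candidate variant with read support in both the tumor and the
#' matched normal. `variant_class` is derived from allele lengths: equal
#' single-base alleles are SNVs, a longer alt is an insertion, a longer ref a
#' deletion.
#'
#' @param chrom,pos,ref,alt Variant coordinates and alleles (`pos` 1-based).
#' @param depth_tumor,depth_normal Integer read depths.
#' @param alt_reads_tumor Integer count of tumor reads supporting the alt.
#' @param af_tumor,af_normal Allele fractions in `[0, 1]`.
#' @param filter_status Caller filter string (`"PASS"` for confident calls).
#' @param gene Gene symbol or `""`.
#' @return A `data.frame` with class `"variant_table"`.
#' @export
variant_table <- function(chrom, pos, ref, alt, depth_tumor, depth_normal,
                          alt_reads_tumor, af_tumor, af_normal,
                          filter_status = "PASS", gene = "") {
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    depth_tumor = as.integer(depth_tumor),
    depth_normal = as.integer(depth_normal),
    alt_reads_tumor = as.integer(alt_reads_tumor),
    af_tumor = as.numeric(af_tumor), af_normal = as.numeric(af_normal),
    filter_status = as.character(filter_status), gene = as.character(gene),
    stringsAsFactors = FALSE
  )
  if (any(df$pos < 1L)) stop("variant positions must be >= 1")
  if (any(df$alt_reads_tumor > df$depth_tumor)) {
    stop("alt_reads_tumor exceeds depth_tumor")
  }
  if (any(df$af_tumor < 0 | df$af_tumor > 1 | df$af_normal < 0 | df$af_normal > 1)) {
    stop("allele fractions must lie in [0, 1]")
  }
  if (any(df$depth_tumor < 0 | df$depth_normal < 0 | df$alt_reads_tumor < 0)) {
    stop("depths and read counts must be non-negative")
  }
  df$variant_class <- classify_variant(df$ref, df$alt)
  class(df) <- c("variant_table", "data.frame")
  df
}

classify_variant <- function(ref, alt) {
  ifelse(nchar(alt) > nchar(ref), "insertion",
         ifelse(nchar(ref) > nchar(alt), "deletion", "SNV"))
}

#' Read paired tumor/normal variant records
#'
#' Accepts either a VCF (v4.x, detected by the `##fileformat` header or a
#' `.vcf` extension) with tumor and normal sample columns, or a tab-separated
#' table with the columns of [variant_table()]. For VCF input the per-sample
#' `DP` and `AD` FORMAT fields are required; the allele fraction is taken
#' from the `AF` FORMAT field when present and otherwise computed as
#' alt reads / depth. Records lacking depth or allele-depth in either sample
#' are skipped with a warning; the number skipped is attached as the
#' `n_skipped` attribute.
#'
#' @param path Path to the VCF or TSV file.
#' @param tumor,normal Sample column names for VCF input; defaults to the
#'   first and second sample columns.
#' @return A [variant_table()] with attribute `n_skipped`.
#' @export
read_variant_table <- function(path, tumor = NULL, normal = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("^##fileformat=VCF", first) || grepl("\\.vcf$", path)) {
    read_variant_vcf(path, tumor = tumor, normal = normal)
  } else {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    needed <- c("chrom", "pos", "ref", "alt", "depth_tumor", "depth_normal",
                "alt_reads_tumor", "af_tumor", "af_normal", "filter_status")
    missing <- setdiff(needed, colnames(df))
    if (length(missing)) stop("variant TSV lacks columns: ",
                              paste(missing, collapse = ", "))
    if (is.null(df$gene)) df$gene <- ""
    out <- variant_table(df$chrom, df$pos, df$ref, df$alt, df$depth_tumor,
                         df$depth_normal, df$alt_reads_tumor, df$af_tumor,
                         df$af_normal, df$filter_status, df$gene)
    attr(out, "n_skipped") <- 0L
    out
  }
}

read_variant_vcf <- function(path, tumor = NULL, normal = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1L]
  if (length(samples) < 2L) stop("VCF must contain tumor and normal sample columns")
  if (is.null(tumor)) tumor <- samples[1L]
  if (is.null(normal)) normal <- samples[2L]
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  dp <- vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(vcf, "AD")
  af <- tryCatch(vcfR::extract.gt(vcf, "AF", as.numeric = TRUE),
                 error = function(e) NULL)
  alt_of <- function(ad_field) {
    vapply(strsplit(ad_field, ",", fixed = TRUE), function(x) {
      suppressWarnings(as.numeric(x[2L]))
    }, numeric(1L))
  }
  alt_t <- alt_of(ad[, tumor])
  alt_n <- alt_of(ad[, normal])
  ok <- !is.na(dp[, tumor]) & !is.na(dp[, normal]) & !is.na(alt_t) & !is.na(alt_n)
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) {
    warning(sprintf("skipped %d record(s) lacking DP/AD in tumor or normal",
                    n_skipped))
  }
  af_t <- if (!is.null(af)) af[, tumor] else rep(NA_real_, nrow(fix))
  af_n <- if (!is.null(af)) af[, normal] else rep(NA_real_, nrow(fix))
  af_t <- ifelse(is.na(af_t), alt_t / pmax(dp[, tumor], 1), af_t)
  af_n <- ifelse(is.na(af_n), alt_n / pmax(dp[, normal], 1), af_n)
  gene <- rep("", nrow(fix))
  info <- fix[, "INFO"]
  m <- regexpr("GENE=[^;]+", ifelse(is.na(info), "", info))
  gene[m > 0] <- sub("^GENE=", "", regmatches(info, m))
  out <- variant_table(
    chrom = fix[ok, "CHROM"], pos = as.integer(fix[ok, "POS"]),
    ref = fix[ok, "REF"], alt = fix[ok, "ALT"],
    depth_tumor = dp[ok, tumor], depth_normal = dp[ok, normal],
    alt_reads_tumor = alt_t[ok],
    af_tumor = pmin(pmax(af_t[ok], 0), 1), af_normal = pmin(pmax(af_n[ok], 0), 1),
    filter_status = fix[ok, "FILTER"], gene = gene[ok]
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a variant table to TSV
#'
#' @param x A [variant_table()].
#' @param path Output path.
#' @export
write_variant_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
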