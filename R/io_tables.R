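# Tabular inputs: expression matrix, PAS catalog, sample design and qPCR
# Ct / delta-Ct tables. All TSV with a header row.

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, ": missing required column '", missing[1L], "'")
  invisible(df)
}

read_tsv_df <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  colClasses = NULL, data.table = FALSE,
                                  na.strings = NULL))
}

#' Read a gene expression table (TPM)
#'
#' TSV with a `gene_id` column followed by one numeric column per sample.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix, genes x samples, with gene ids as row names.
#' @export
read_expression_table <- function(path) {
  df <- read_tsv_df(path)
  require_columns(df, "gene_id", "expression table")
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("expression table: non-numeric or missing values")
  if (any(m < 0)) stop("expression table: negative values")
  rownames(m) <- df$gene_id
  m
}

#' Write a gene expression table
#' @param expr Genes x samples matrix with row names.
#' @param path Output path.
#' @export
write_expression_table <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a polyadenylation-site catalog (BED6)
#'
#' One row per PAS: the cleavage site is the `chromStart` coordinate, the
#' BED name field carries the gene id. Strand is required (it orients the
#' downstream readthrough window).
#'
#' @param path Path to the BED file.
#' @return A `data.frame` with columns `gene_id`, `pas_id`, `chrom`,
#'   `site` (0-based) and `strand`.
#' @export
read_pas_bed <- function(path) {
  lines <- read_text_lines(path)
  if (length(lines) == 0L)
    return(data.frame(gene_id = character(), pas_id = character(),
                      chrom = character(), site = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop("malformed PAS BED line ", which(nf < 6L)[1L], " in ", path,
         ": expected 6 fields")
  mat <- do.call(rbind, lapply(fields, `[`, 1:6))
  site <- as.integer(mat[, 2L])
  if (anyNA(site) || any(site < 0L)) stop("invalid PAS coordinates in ", path)
  strand <- mat[, 6L]
  if (!all(strand %in% c("+", "-")))
    stop("PAS strand must be '+' or '-'")
  data.frame(gene_id = mat[, 4L],
             pas_id = sprintf("%s:%d:%s", mat[, 1L], site, strand),
             chrom = mat[, 1L], site = site, strand = strand,
             stringsAsFactors = FALSE)
}

#' Write a polyadenylation-site catalog (BED6)
#' @param pas PAS data frame as returned by [read_pas_bed()].
#' @param path Output path.
#' @export
write_pas_bed <- function(pas, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", pas$chrom, pas$site,
                     pas$site + 1L, pas$gene_id, pas$strand), path)
  invisible(path)
}

#' Read a sample design table
#'
#' TSV with columns `sample_id` and `genotype` (`WT` or `MUT`), plus any
#' optional path columns (e.g. `junctions`, `coverage`).
#'
#' @param path Path to the TSV file.
#' @return The design `data.frame`.
#' @export
read_design <- function(path) {
  df <- read_tsv_df(path)
  require_columns(df, c("sample_id", "genotype"), "design table")
  validate_design(df)
}

validate_design <- function(df) {
  if (anyDuplicated(df$sample_id))
    stop("design table: duplicate sample_id")
  if (!all(df$genotype %in% c("WT", "MUT")))
    stop("design table: genotype must be 'WT' or 'MUT'")
  df
}

#' Write a sample design table
#' @param design Design data frame.
#' @param path Output path.
#' @export
write_design <- function(design, path) {
  data.table::fwrite(design, path, sep = "\t")
  invisible(path)
}

#' Read a raw qPCR Ct table
#'
#' TSV with columns `target`, `organ`, `genotype`, `mouse_id`,
#' `ct_abnormal`, `ct_normal`. Ct cells are numbers in `(0, ceiling]` or
#' the token `ND` (not detected within the run's cycle ceiling).
#'
#' @param path Path to the TSV file.
#' @param ceiling Cycle ceiling of the assay (default 40 cycles).
#' @return A `data.frame` with numeric `ct_abnormal` / `ct_normal`
#'   (`NA` = not detected) and the ceiling as attribute `ceiling`.
#' @export
read_qpcr_table <- function(path, ceiling = 40) {
  df <- read_tsv_df(path)
  require_columns(df, c("target", "organ", "genotype", "mouse_id",
                        "ct_abnormal", "ct_normal"), "qPCR table")
  validate_design(data.frame(sample_id = paste(df$organ, df$mouse_id,
                                               df$target),
                             genotype = df$genotype))
  df$ct_abnormal <- parse_ct(df$ct_abnormal, ceiling)
  df$ct_normal <- parse_ct(df$ct_normal, ceiling)
  structure(df, ceiling = ceiling)
}

parse_ct <- function(x, ceiling) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  detected <- toupper(x) != "ND"
  out[detected] <- suppressWarnings(as.numeric(x[detected]))
  if (anyNA(out[detected])) stop("qPCR table: unparseable Ct value '",
                                 x[detected][is.na(out[detected])][1L], "'")
  if (any(out[detected] <= 0) || any(out[detected] > ceiling))
    stop("qPCR table: Ct values must lie in (0, ", ceiling, "]")
  out
}

#' Read a table of pre-computed delta-Ct values
#'
#' Long-format TSV with columns `organ`, `target`, `genotype`,
#' `replicate`, `delta_ct`, where `delta_ct` cells are numbers, `ND`
#' (normal isoform undetected, value missing) or `> x` (abnormal isoform
#' undetected: the true delta-Ct is at least `x`, a censored lower
#' limit). This is the layout in which published multi-organ delta-Ct
#' summaries are reported.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `organ`, `target`, `genotype`,
#'   `replicate`, `value`, `is_lower_limit`, `is_missing`.
#' @export
read_delta_ct_table <- function(path) {
  df <- read_tsv_df(path)
  require_columns(df, c("organ", "target", "genotype", "replicate",
                        "delta_ct"), "delta-Ct table")
  tok <- trimws(as.character(df$delta_ct))
  missing <- toupper(tok) == "ND"
  limit <- grepl("^>", tok)
  value <- rep(NA_real_, length(tok))
  plain <- !missing
  value[plain] <- suppressWarnings(as.numeric(sub("^>\\s*", "",
                                                  gsub("−", "-", tok[plain]))))
  if (anyNA(value[plain]))
    stop("delta-Ct table: unparseable cell '", tok[plain][is.na(value[plain])][1L], "'")
  out <- data.frame(organ = df$organ, target = df$target,
                    genotype = df$genotype, replicate = df$replicate,
                    value = value, is_lower_limit = limit,
                    is_missing = missing, stringsAsFactors = FALSE)
  validate_design(data.frame(sample_id = paste(out$organ, out$target,
                                               out$genotype, out$replicate),
                             genotype = out$genotype))
  out
}
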