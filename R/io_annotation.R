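# Exon annotation I/O.
#
# Internal convention everywhere in this package: 0-based half-open
# intervals [start, end). GTF (1-based inclusive) is converted at the I/O
# boundary and nowhere else.

#' Read an exon annotation
#'
#' Parses exon records from a GTF (only `exon` feature rows are used) or a
#' BED12 file (each row one gene, blocks are exons). Coordinates are
#' converted to the package-internal 0-based half-open convention.
#' Duplicate exons (same gene, chromosome, interval and strand) are
#' collapsed. Exons must be stranded: strand `"."` is rejected because the
#' downstream motif windows and readthrough windows are oriented by
#' transcription.
#'
#' @param path Path to the annotation file.
#' @param dialect `"gtf"` or `"bed12"`.
#' @return A `data.frame` with columns `gene_id`, `exon_id`, `chrom`,
#'   `start`, `end` (0-based half-open) and `strand`.
#' @export
read_exon_annotation <- function(path, dialect = c("gtf", "bed12")) {
  dialect <- match.arg(dialect)
  lines <- read_text_lines(path)
  if (length(lines) == 0L) {
    warning("empty annotation file: ", path)
    return(empty_exon_annotation())
  }
  ex <- switch(dialect,
    gtf = parse_gtf_exons(lines, path),
    bed12 = parse_bed12_exons(lines, path)
  )
  validate_exon_annotation(ex)
}

empty_exon_annotation <- function() {
  data.frame(gene_id = character(), exon_id = character(),
             chrom = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines[!grepl("^(#|track |browser )", lines) & nzchar(lines)]
}

parse_gtf_exons <- function(lines, path) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L))
    stop("malformed GTF line ", which(nf < 9L)[1L], " in ", path,
         ": expected 9 tab-separated fields")
  feat <- vapply(fields, `[`, "", 3L)
  keep <- which(feat == "exon")
  if (length(keep) == 0L) {
    warning("no exon features in ", path)
    return(empty_exon_annotation())
  }
  f <- fields[keep]
  start1 <- suppressWarnings(as.integer(vapply(f, `[`, "", 4L)))
  end1   <- suppressWarnings(as.integer(vapply(f, `[`, "", 5L)))
  bad <- which(is.na(start1) | is.na(end1))
  if (length(bad))
    stop("malformed GTF line ", keep[bad[1L]], " in ", path,
         ": non-numeric coordinates")
  attrs <- vapply(f, `[`, "", 9L)
  gene_id <- gtf_attr(attrs, "gene_id")
  if (anyNA(gene_id))
    stop("malformed GTF line ", keep[which(is.na(gene_id))[1L]], " in ",
         path, ": missing gene_id attribute")
  exon_id <- gtf_attr(attrs, "exon_id")
  ex <- data.frame(
    gene_id = gene_id,
    exon_id = exon_id,
    chrom   = vapply(f, `[`, "", 1L),
    start   = start1 - 1L,       # GTF is 1-based inclusive
    end     = end1,
    strand  = vapply(f, `[`, "", 7L),
    stringsAsFactors = FALSE
  )
  ex <- unique(ex[, c("gene_id", "exon_id", "chrom", "start", "end", "strand")])
  fill_exon_ids(ex)
}

gtf_attr <- function(attrs, key) {
  pat <- paste0(key, '[ =]+"?([^";]+)"?')
  m <- regmatches(attrs, regexec(pat, attrs))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
}

parse_bed12_exons <- function(lines, path) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    stop("malformed BED12 line ", which(nf < 12L)[1L], " in ", path,
         ": expected 12 fields")
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    chrom_start <- as.integer(f[2L])
    n_blocks <- as.integer(f[10L])
    sizes  <- as.integer(strsplit(f[11L], ",", fixed = TRUE)[[1L]])
    starts <- as.integer(strsplit(f[12L], ",", fixed = TRUE)[[1L]])
    if (is.na(chrom_start) || is.na(n_blocks) ||
        length(sizes) != n_blocks || length(starts) != n_blocks)
      stop("malformed BED12 line ", i, " in ", path)
    out[[i]] <- data.frame(
      gene_id = f[4L],
      exon_id = NA_character_,
      chrom   = f[1L],
      start   = chrom_start + starts,
      end     = chrom_start + starts + sizes,
      strand  = f[6L],
      stringsAsFactors = FALSE
    )
  }
  ex <- unique(do.call(rbind, out))
  fill_exon_ids(ex)
}

# deterministic exon ids in genomic order within each gene
fill_exon_ids <- function(ex) {
  ex <- ex[order(ex$gene_id, ex$chrom, ex$start, ex$end), , drop = FALSE]
  need <- is.na(ex$exon_id)
  if (any(need)) {
    idx <- stats::ave(seq_len(nrow(ex)), ex$gene_id, FUN = seq_along)
    ex$exon_id[need] <- sprintf("%s.e%02d", ex$gene_id[need], idx[need])
  }
  rownames(ex) <- NULL
  ex
}

validate_exon_annotation <- function(ex) {
  if (nrow(ex) == 0L) return(ex)
  if (any(ex$start < 0L) || any(ex$start >= ex$end))
    stop("invalid exon interval: require 0 <= start < end")
  if (!all(ex$strand %in% c("+", "-")))
    stop("exon strand must be '+' or '-' (found '",
         setdiff(ex$strand, c("+", "-"))[1L], "')")
  key <- paste(ex$gene_id, ex$exon_id)
  if (anyDuplicated(key))
    stop("duplicate (gene_id, exon_id) pair: ", key[duplicated(key)][1L])
  ex
}

#' Write an exon annotation
#'
#' Inverse of [read_exon_annotation()]. The GTF writer emits one `exon`
#' row per record (1-based inclusive coordinates, `gene_id` and `exon_id`
#' attributes); the BED12 writer emits one row per gene whose blocks are
#' the gene's exons, which requires all exons of a gene to share a
#' chromosome and strand.
#'
#' @param exons Annotation data frame as returned by [read_exon_annotation()].
#' @param path Output path.
#' @param dialect `"gtf"` or `"bed12"`.
#' @export
write_exon_annotation <- function(exons, path, dialect = c("gtf", "bed12")) {
  dialect <- match.arg(dialect)
  if (dialect == "gtf") {
    lines <- sprintf(
      "%s\tspliceshift\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; exon_id \"%s\";",
      exons$chrom, exons$start + 1L, exons$end, exons$strand,
      exons$gene_id, exons$exon_id)
    writeLines(lines, path)
    return(invisible(path))
  }
  rows <- lapply(split(exons, exons$gene_id), function(g) {
    if (length(unique(g$chrom)) > 1L || length(unique(g$strand)) > 1L)
      stop("BED12 writer: gene ", g$gene_id[1L],
           " spans multiple chromosomes or strands")
    g <- g[order(g$start), , drop = FALSE]
    first <- min(g$start)
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            g$chrom[1L], first, max(g$end), g$gene_id[1L], g$strand[1L],
            first, max(g$end), nrow(g),
            paste0(g$end - g$start, collapse = ","),
            paste0(g$start - first, collapse = ","))
  })
  writeLines(unlist(rows, use.names = FALSE), path)
  invisible(path)
}
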