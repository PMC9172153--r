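# Splice-junction I/O.
#
# A junction set is a data.frame (chrom, intron_start, intron_end, strand,
# count) in 0-based half-open intron coordinates, one row per unique
# intron, with the sample id carried as the "sample_id" attribute.
# Two dialects are supported: the TopHat-style BED12 junction format
# (two anchor blocks; the intron is the gap between them; the score is the
# supporting read count) and the STAR SJ.out.tab format (1-based inclusive
# intron; column 7 is the uniquely-mapping read count).

#' Read per-sample splice junctions
#'
#' @param path Path to the junction file.
#' @param dialect `"bed12_junctions"` (TopHat-style: the intron is the gap
#'   between the two anchor blocks, the BED score is the read count) or
#'   `"sj_tab"` (STAR `SJ.out.tab`: uniquely-mapping read count used).
#' @param sample_id Sample label attached to the returned set; defaults to
#'   the file base name.
#' @return A `data.frame` with columns `chrom`, `intron_start`,
#'   `intron_end` (0-based half-open), `strand` (`"+"`, `"-"` or `"."`
#'   when unknown) and `count`, with attribute `sample_id`.
#' @export
read_junctions <- function(path, dialect = c("bed12_junctions", "sj_tab"),
                           sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- read_text_lines(path)
  js <- if (length(lines) == 0L) {
    data.frame(chrom = character(), intron_start = integer(),
               intron_end = integer(), strand = character(),
               count = integer(), stringsAsFactors = FALSE)
  } else {
    switch(dialect,
      bed12_junctions = parse_junction_bed12(lines, path),
      sj_tab = parse_sj_tab(lines, path))
  }
  validate_junction_set(js)
  structure(js, sample_id = sample_id)
}

parse_junction_bed12 <- function(lines, path) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    stop("malformed junction BED12 line ", which(nf < 12L)[1L], " in ", path)
  keep <- logical(length(fields))
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    n_blocks <- as.integer(f[10L])
    if (is.na(n_blocks) || n_blocks != 2L) {
      warning("junction BED12 line ", i, " in ", path,
              ": blockCount != 2, record skipped")
      next
    }
    sizes <- as.integer(strsplit(f[11L], ",", fixed = TRUE)[[1L]])
    chrom_start <- as.integer(f[2L])
    chrom_end <- as.integer(f[3L])
    count <- as.integer(f[5L])
    if (anyNA(c(sizes, chrom_start, chrom_end, count)))
      stop("malformed junction BED12 line ", i, " in ", path)
    keep[i] <- TRUE
    out[[i]] <- data.frame(
      chrom = f[1L],
      intron_start = chrom_start + sizes[1L],
      intron_end = chrom_end - sizes[2L],
      strand = f[6L],
      count = count,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out[keep])
}

parse_sj_tab <- function(lines, path) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L))
    stop("malformed SJ.out.tab line ", which(nf < 9L)[1L], " in ", path)
  mat <- do.call(rbind, fields)
  start1 <- as.integer(mat[, 2L])
  end1 <- as.integer(mat[, 3L])
  count <- as.integer(mat[, 7L])
  if (anyNA(c(start1, end1, count)))
    stop("malformed SJ.out.tab in ", path, ": non-numeric fields")
  data.frame(
    chrom = mat[, 1L],
    intron_start = start1 - 1L,     # 1-based inclusive -> half-open
    intron_end = end1,
    strand = c(".", "+", "-")[as.integer(mat[, 4L]) + 1L],
    count = count,
    stringsAsFactors = FALSE)
}

validate_junction_set <- function(js) {
  if (nrow(js) == 0L) return(invisible(js))
  if (any(js$count < 0L)) stop("negative junction read count")
  if (any(js$intron_start >= js$intron_end))
    stop("invalid intron interval: require intron_start < intron_end")
  key <- paste(js$chrom, js$intron_start, js$intron_end, js$strand)
  if (anyDuplicated(key))
    stop("duplicate junction record: ", key[duplicated(key)][1L])
  invisible(js)
}

#' Write per-sample splice junctions
#'
#' Inverse of [read_junctions()]. The BED12 writer emits two 20-bp anchor
#' blocks around each intron; the SJ writer emits the nine STAR columns
#' with the count in the unique-reads column.
#'
#' @inheritParams read_junctions
#' @param junctions Junction set data frame.
#' @export
write_junctions <- function(junctions, path,
                            dialect = c("bed12_junctions", "sj_tab")) {
  dialect <- match.arg(dialect)
  anchor <- 20L
  if (dialect == "bed12_junctions") {
    cs <- pmax(junctions$intron_start - anchor, 0L)
    a1 <- junctions$intron_start - cs
    lines <- sprintf(
      "%s\t%d\t%d\tjunc_%d\t%d\t%s\t%d\t%d\t0\t2\t%d,%d\t0,%d",
      junctions$chrom, cs, junctions$intron_end + anchor,
      seq_len(nrow(junctions)), junctions$count, junctions$strand,
      cs, junctions$intron_end + anchor,
      a1, anchor, junctions$intron_end - cs)
  } else {
    strand_code <- match(junctions$strand, c(".", "+", "-")) - 1L
    lines <- sprintf("%s\t%d\t%d\t%d\t0\t0\t%d\t0\t%d",
                     junctions$chrom, junctions$intron_start + 1L,
                     junctions$intron_end, strand_code, junctions$count,
                     anchor)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Merge junction sets by summing read counts
#'
#' Counting is additive over junction files: the same intron observed in
#' several sets accumulates its read counts.
#'
#' @param ... Junction set data frames.
#' @return A merged junction set (sample_id attribute of the first set).
#' @export
merge_junction_sets <- function(...) {
  sets <- list(...)
  all <- data.table::rbindlist(lapply(sets, as.data.frame))
  merged <- all[, list(count = sum(count)),
                by = c("chrom", "intron_start", "intron_end", "strand")]
  out <- as.data.frame(merged)
  structure(out, sample_id = attr(sets[[1L]], "sample_id"))
}
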