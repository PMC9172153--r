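# Read-depth coverage tracks.
#
# A coverage track is a named list (one element per chromosome) of
# data.frames (start, end, depth) holding a piecewise-constant depth
# function over sorted, non-overlapping, 0-based half-open intervals.
# Positions outside every interval have depth 0.

#' Construct a coverage track from interval depths
#'
#' @param df A data.frame with columns `chrom`, `start`, `end`, `depth`.
#' @return A `coverage_track`: per-chromosome sorted non-overlapping
#'   interval lists.
#' @export
coverage_track <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(df)))
  if (any(df$depth < 0)) stop("coverage depth must be non-negative")
  if (any(df$start >= df$end)) stop("invalid coverage interval")
  df <- df[df$depth > 0, , drop = FALSE]
  track <- lapply(split(df[, c("start", "end", "depth")], df$chrom),
                  function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)]))
      stop("overlapping coverage intervals on one chromosome")
    rownames(d) <- NULL
    d
  })
  structure(track, class = "coverage_track")
}

#' Read a coverage track
#'
#' Two dialects: `"bedgraph"` (chrom, start, end, depth; 0-based
#' half-open; overlapping intervals are an error) and `"read_bed"` (plain
#' read intervals in BED; depth is computed by a sweep over read starts
#' and ends). Unsorted input is sorted internally.
#'
#' @param path Path to the file.
#' @param dialect `"bedgraph"` or `"read_bed"`.
#' @return A `coverage_track`. For `read_bed` input the attribute
#'   `mean_read_length` records the mean read length, used downstream to
#'   convert depth-area into approximate read counts.
#' @export
read_coverage <- function(path, dialect = c("bedgraph", "read_bed")) {
  dialect <- match.arg(dialect)
  lines <- read_text_lines(path)
  if (length(lines) == 0L)
    return(coverage_track(data.frame(chrom = character(), start = integer(),
                                     end = integer(), depth = numeric())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- if (dialect == "bedgraph") 4L else 3L
  if (any(nf < need))
    stop("malformed line ", which(nf < need)[1L], " in ", path)
  mat <- do.call(rbind, lapply(fields, `[`, seq_len(need)))
  chrom <- mat[, 1L]
  start <- as.integer(mat[, 2L])
  end <- as.integer(mat[, 3L])
  if (anyNA(start) || anyNA(end)) stop("non-numeric coordinates in ", path)
  if (dialect == "bedgraph") {
    depth <- as.numeric(mat[, 4L])
    if (anyNA(depth)) stop("non-numeric depth in ", path)
    return(coverage_track(data.frame(chrom = chrom, start = start,
                                     end = end, depth = depth)))
  }
  track <- depth_sweep(data.frame(chrom = chrom, start = start, end = end))
  attr(track, "mean_read_length") <- mean(end - start)
  track
}

# sweep-line: stack read intervals into a piecewise-constant depth profile
depth_sweep <- function(reads) {
  per_chrom <- lapply(split(reads, reads$chrom), function(d) {
    ev <- data.frame(pos = c(d$start, d$end),
                     delta = rep(c(1, -1), each = nrow(d)))
    ev <- stats::aggregate(delta ~ pos, data = ev, FUN = sum)
    ev <- ev[order(ev$pos), , drop = FALSE]
    depth <- cumsum(ev$delta)
    n <- nrow(ev)
    out <- data.frame(start = ev$pos[-n], end = ev$pos[-1L],
                      depth = depth[-n])
    out[out$depth > 0, , drop = FALSE]
  })
  df <- data.table::rbindlist(per_chrom, idcol = "chrom")
  coverage_track(as.data.frame(df))
}

#' Write a coverage track as bedGraph
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @export
write_coverage <- function(track, path) {
  rows <- unlist(lapply(names(track), function(chrom) {
    d <- track[[chrom]]
    sprintf("%s\t%d\t%d\t%s", chrom, d$start, d$end,
            format(d$depth, trim = TRUE, scientific = FALSE))
  }), use.names = FALSE)
  writeLines(rows, path)
  invisible(path)
}

#' Depth-area of a coverage track over an interval
#'
#' Sums depth times overlap length over `[start, end)` on one chromosome;
#' regions not covered by any interval contribute 0.
#'
#' @param track A `coverage_track`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open query interval.
#' @return Non-negative depth-area (base-units).
#' @export
window_count <- function(track, chrom, start, end) {
  d <- track[[chrom]]
  if (is.null(d) || nrow(d) == 0L) return(0)
  ov <- pmin(d$end, end) - pmax(d$start, start)
  sum(d$depth[ov > 0] * ov[ov > 0])
}

#' Total depth-area of a coverage track
#'
#' Equals the summed read length when the track was built from read
#' intervals.
#'
#' @param track A `coverage_track`.
#' @return Total base-units of coverage.
#' @export
track_mass <- function(track) {
  sum(vapply(track, function(d) sum(d$depth * (d$end - d$start)), 0))
}
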