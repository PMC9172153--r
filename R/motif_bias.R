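# Compositional bias around exon boundaries.
#
# Three windows per exon, oriented by transcription: 250 bp upstream of
# the exon's 5' boundary, the exon itself, and 250 bp downstream of the
# 3' boundary. For minus-strand exons the windows are mirrored and
# reverse-complemented, so all sequences read in the sense of the
# transcript. Overlapping 5-mer frequencies in each window are correlated
# (Spearman) with the signed exon-usage contrast across events: positive
# rho ties a motif to abnormal exclusion, negative to abnormal inclusion.

ALPHABET <- c("A", "C", "G", "T")

#' All DNA k-mers in lexicographic order
#' @param k Motif length (default 5, giving 4^5 = 1024 motifs).
#' @return Character vector of the 4^k motifs.
#' @export
all_kmers <- function(k = 5L) {
  grid <- do.call(expand.grid,
                  rep(list(ALPHABET), k))[, k:1, drop = FALSE]
  do.call(paste0, grid)
}

#' Extract boundary windows for one exon
#'
#' @param exon Single-row exon data frame.
#' @param genome A named `DNAStringSet` (or named character vector of
#'   chromosome sequences).
#' @param width Flank width in bp (default 250).
#' @return List with `upstream`, `inside`, `downstream` sequences (sense
#'   strand of the transcript) and a `clipped` flag set when a flank ran
#'   into a chromosome end.
#' @export
extract_windows <- function(exon, genome, width = 250L) {
  seqs <- window_seq_matrix(exon, genome, width)
  list(upstream = seqs$upstream[1L], inside = seqs$inside[1L],
       downstream = seqs$downstream[1L], clipped = seqs$clipped[1L])
}

# vectorised window extraction for an event table
window_seq_matrix <- function(events, genome, width) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome))) stop("genome sequences must be named")
  miss <- setdiff(unique(events$chrom), names(genome))
  if (length(miss)) stop("chromosome missing from genome: ", miss[1L])
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  len <- chrom_len[events$chrom]

  # genomic (plus-strand) coordinates of the left and right flanks
  left_s <- pmax(events$start - width, 0L)
  left_e <- events$start
  right_s <- events$end
  right_e <- pmin(events$end + width, len)
  clipped <- (events$start - width < 0L) | (events$end + width > len)
  if (any(clipped)) warning(sum(clipped), " window(s) clipped at chromosome ends")

  fetch <- function(s, e) {
    out <- character(length(s))
    ok <- e > s
    if (any(ok)) {
      v <- Biostrings::subseq(genome[events$chrom[ok]], start = s[ok] + 1L,
                              end = e[ok])
      out[ok] <- as.character(v)
    }
    out
  }
  left <- fetch(left_s, left_e)
  inside <- fetch(events$start, events$end)
  right <- fetch(right_s, right_e)

  minus <- events$strand == "-"
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(x)))
  upstream <- left; downstream <- right
  if (any(minus)) {
    upstream[minus] <- rc(right[minus])
    downstream[minus] <- rc(left[minus])
    inside[minus] <- rc(inside[minus])
  }
  list(upstream = upstream, inside = inside, downstream = downstream,
       clipped = clipped)
}

#' Overlapping k-mer frequencies of a sequence
#'
#' Counts every overlapping window of length `k` and normalises by the
#' number of windows consisting solely of A/C/G/T — windows containing
#' other letters (e.g. N) are excluded from both numerator and
#' denominator. The result is a probability vector over the 4^k motifs
#' whenever at least one valid window exists.
#'
#' @param seq A nucleotide string.
#' @param k Motif length (default 5).
#' @return Named numeric vector of length 4^k. All-zero (with a warning)
#'   when the sequence is shorter than `k` or has no valid window.
#' @export
kmer_frequencies <- function(seq, k = 5L) {
  kmer_frequency_matrix(seq, k)[1L, ]
}

kmer_frequency_matrix <- function(seqs, k = 5L) {
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = k)
  tot <- rowSums(counts)
  if (any(tot == 0))
    warning(sum(tot == 0), " sequence(s) with no valid ", k,
            "-mer window (shorter than k or all non-ACGT)")
  counts / ifelse(tot > 0, tot, 1)
}

#' Correlate motif composition with exon-usage shifts
#'
#' For each of the three boundary windows and each of the 4^k motifs,
#' computes the Spearman correlation across events between the motif's
#' per-exon frequency and the exon's usage value, and flags motifs whose
#' |rho| exceeds the significance threshold.
#'
#' @param events Usage-event table (typically the significant rows of
#'   [usage_table()]); needs columns `chrom`, `start`, `end`, `strand`
#'   and `x`.
#' @param genome Named `DNAStringSet` or character vector.
#' @param width Flank width in bp (default 250).
#' @param k Motif length (default 5).
#' @param threshold Critical |rho|; default
#'   `spearman_critical(nrow(events), 0.05, "one")`. The published preset
#'   0.0655 can be supplied explicitly.
#' @param usage_value `"contrast"` correlates against the continuous
#'   signed `x`; `"binary"` against its sign only.
#' @param inside_mode `"whole"` uses the full exon as the inside window;
#'   `"fixed"` truncates it to `width` bp from the 5' boundary.
#' @return A `data.frame` with 3 * 4^k rows: `motif`, `window_class`
#'   (upstream / inside / downstream), `mean_frequency`, `rho`,
#'   `significant`.
#' @export
motif_usage_correlation <- function(events, genome, width = 250L, k = 5L,
                                    threshold = NULL,
                                    usage_value = c("contrast", "binary"),
                                    inside_mode = c("whole", "fixed")) {
  usage_value <- match.arg(usage_value)
  inside_mode <- match.arg(inside_mode)
  if (nrow(events) < 4L)
    stop("motif_usage_correlation: need at least 4 events")
  if (is.null(threshold))
    threshold <- spearman_critical(nrow(events), 0.05, "one")
  y <- if (usage_value == "binary") sign(events$x) else events$x

  ev <- events
  if (inside_mode == "fixed") {
    long <- ev$end - ev$start > width
    ev$end[long & ev$strand == "+"] <- ev$start[long & ev$strand == "+"] + width
    ev$start[long & ev$strand == "-"] <- ev$end[long & ev$strand == "-"] - width
  }
  seqs <- window_seq_matrix(ev, genome, width)

  ry <- rank(y)
  one_class <- function(class) {
    freq <- kmer_frequency_matrix(seqs[[class]], k)
    ranked <- apply(freq, 2L, rank)
    rho <- suppressWarnings(as.vector(stats::cor(ranked, ry)))
    constant <- apply(freq, 2L, function(col) length(unique(col)) < 2L)
    rho[constant] <- NA_real_
    data.frame(motif = colnames(freq), window_class = class,
               mean_frequency = colMeans(freq), rho = rho,
               significant = !is.na(rho) & abs(rho) > threshold,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(c("upstream", "inside", "downstream"),
                               one_class))
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "n_events") <- nrow(events)
  out
}
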