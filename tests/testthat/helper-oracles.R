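# Independent brute-force oracles. These re-derive each quantity by the
# most literal method available (per-base loops, substring scans, rank
# arithmetic, stats::t.test) and are kept free of package internals.

oracle_count_skip <- function(exon, junctions) {
  total <- 0L
  for (i in seq_len(nrow(junctions))) {
    j <- junctions[i, ]
    if (j$chrom == exon$chrom &&
        (j$strand == exon$strand || j$strand == ".") &&
        j$intron_start < exon$start && j$intron_end > exon$end)
      total <- total + j$count
  }
  total
}

oracle_count_inclusion <- function(exon, junctions) {
  total <- 0L
  for (i in seq_len(nrow(junctions))) {
    j <- junctions[i, ]
    if (j$chrom == exon$chrom &&
        (j$strand == exon$strand || j$strand == ".") &&
        (j$intron_end == exon$start || j$intron_start == exon$end))
      total <- total + j$count
  }
  total
}

# per-base sum of depth over [start, end)
oracle_window_area <- function(track, chrom, start, end) {
  d <- track[[chrom]]
  if (is.null(d)) return(0)
  total <- 0
  for (pos in seq(start, end - 1L)) {
    hit <- d$depth[d$start <= pos & d$end > pos]
    if (length(hit)) total <- total + sum(hit)
  }
  total
}

# substring scan with explicit valid-window bookkeeping
oracle_kmer_freq <- function(seq, k = 5L) {
  motifs <- spliceshift::all_kmers(k)
  counts <- stats::setNames(rep(0L, length(motifs)), motifs)
  n <- nchar(seq)
  valid <- 0L
  if (n >= k) {
    for (i in seq_len(n - k + 1L)) {
      w <- toupper(substr(seq, i, i + k - 1L))
      if (grepl("^[ACGT]+$", w)) {
        valid <- valid + 1L
        counts[w] <- counts[w] + 1L
      }
    }
  }
  if (valid == 0L) counts else counts / valid
}

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

random_junction_set <- function(n, chroms = c("chr1", "chr2")) {
  start <- sample.int(2000L, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             intron_start = start,
             intron_end = start + sample.int(800L, n, replace = TRUE),
             strand = sample(c("+", "-", "."), n, replace = TRUE),
             count = sample.int(50L, n, replace = TRUE),
             stringsAsFactors = FALSE)
}
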