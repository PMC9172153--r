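# Transcription-termination accuracy: read signal in a fixed window
# downstream of each annotated polyadenylation site (PAS), normalised by
# gene expression and contrasted between genotypes. Positive contrast
# means more downstream signal in the mutant — transcriptional
# readthrough; negative means relatively effective PAS usage.

#' Downstream window of a polyadenylation site
#'
#' The window extends in the direction of transcription: `[site,
#' site+width)` on the plus strand, `[site-width, site)` on the minus
#' strand, clipped at the chromosome start (never negative).
#'
#' @param pas A single-row PAS data frame (see [read_pas_bed()]).
#' @param width Window width in bp (default 275).
#' @return A list with `chrom`, `start`, `end` (0-based half-open) and
#'   `clipped` (TRUE when the window hit the chromosome start).
#' @export
downstream_window <- function(pas, width = 275L) {
  if (width <= 0L) stop("downstream_window: width must be positive")
  if (pas$strand == "+") {
    list(chrom = pas$chrom, start = pas$site, end = pas$site + width,
         clipped = FALSE)
  } else {
    start <- pas$site - width
    list(chrom = pas$chrom, start = max(start, 0L), end = pas$site,
         clipped = start < 0L)
  }
}

#' Per-PAS readthrough table
#'
#' For every PAS whose gene is quantifiable (expression above the cutoff
#' in all samples), computes the per-sample downstream rate — depth-area
#' in the downstream window divided by gene expression — the signed
#' genotype contrast and the Welch p-value. Tracks built from read
#' intervals carry a mean read length; their areas are divided by it so
#' the rate approximates a read count per TPM, matching bedGraph tracks
#' scaled the same way.
#'
#' @param pas_catalog PAS data frame (see [read_pas_bed()]).
#' @param coverage_tracks Named list of `coverage_track`s per sample.
#' @param expression Genes x samples TPM matrix.
#' @param design Sample design (see [read_design()]).
#' @param width Downstream window width in bp (default 275).
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param tpm_cutoff Minimum expression for testability (default 0.025).
#' @return A `data.frame`, one row per testable PAS, sorted by p-value,
#'   with `x`, `p`, `degenerate`, `significant` and per-sample
#'   `downstream_rate.*` columns. PAS with no downstream signal in any
#'   sample are dropped; orphan PAS (gene absent from the expression
#'   table) are skipped with a warning.
#' @export
readthrough_table <- function(pas_catalog, coverage_tracks, expression,
                              design, width = 275L, alpha = 0.05,
                              tpm_cutoff = 0.025) {
  samples <- design$sample_id
  check_two_per_genotype(design)
  if (!all(samples %in% names(coverage_tracks)))
    stop("readthrough_table: coverage track missing for sample ",
         setdiff(samples, names(coverage_tracks))[1L])
  orphan <- !(pas_catalog$gene_id %in% rownames(expression))
  if (any(orphan)) {
    warning("skipping ", sum(orphan), " orphan PAS with no expression entry")
    pas_catalog <- pas_catalog[!orphan, , drop = FALSE]
  }
  n <- nrow(pas_catalog)
  if (n == 0L) stop("readthrough_table: no testable PAS")

  expr <- expression[pas_catalog$gene_id, samples, drop = FALSE]
  rate <- matrix(NA_real_, n, length(samples),
                 dimnames = list(NULL, samples))
  for (s in samples) {
    track <- coverage_tracks[[s]]
    scale <- attr(track, "mean_read_length")
    if (is.null(scale) || is.na(scale) || scale <= 0) scale <- 1
    area <- vapply(seq_len(n), function(i) {
      w <- downstream_window(pas_catalog[i, ], width)
      window_count(track, w$chrom, w$start, w$end)
    }, 0)
    rate[, s] <- normalize_rates(area / scale, expr[, s], tpm_cutoff)
  }

  testable <- rowSums(is.na(rate)) == 0L
  if (!any(testable))
    stop("readthrough_table: no testable PAS (every gene fails the ",
         "expression cutoff in at least one sample)")
  is_mut <- samples %in% design$sample_id[design$genotype == "MUT"]
  rate_t <- rate[testable, , drop = FALSE]
  cat_t <- pas_catalog[testable, , drop = FALSE]

  keep <- logical(nrow(rate_t))
  x <- p <- rep(NA_real_, nrow(rate_t))
  degenerate <- logical(nrow(rate_t))
  for (i in seq_len(nrow(rate_t))) {
    xi <- normalized_contrast(rate_t[i, is_mut], rate_t[i, !is_mut])
    if (is.na(xi)) next
    keep[i] <- TRUE
    x[i] <- xi
    w <- welch_t(rate_t[i, is_mut], rate_t[i, !is_mut])
    p[i] <- w$p
    degenerate[i] <- w$degenerate
  }
  out <- cbind(cat_t[keep, , drop = FALSE],
               data.frame(x = x[keep], p = p[keep],
                          degenerate = degenerate[keep]))
  rates <- rate_t[keep, , drop = FALSE]
  colnames(rates) <- paste0("downstream_rate.", samples)
  out <- cbind(out, rates)
  out$significant <- out$p < alpha
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
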