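# Differential exon usage from splice junctions.
#
# An exon is *skipped* by a junction whose intron spans it entirely
# (intron_start < exon start and intron_end > exon end) and *included* by
# junctions landing exactly on its boundaries (intron_end == exon start,
# the acceptor side, or intron_start == exon end, the donor side).
# Per-sample counts are normalised by the gene's expression (TPM), the
# genotype contrast is the signed normalized rate difference, and Welch's
# t-test across samples gives the significance. Junction strand must match
# the exon strand unless the junction strand is unknown (".").

strand_compatible <- function(junction_strand, exon_strand) {
  junction_strand == exon_strand | junction_strand == "."
}

#' Count skip evidence for one exon
#'
#' Sums read counts of strand-compatible junctions whose intron spans the
#' whole exon.
#'
#' @param exon A single-row exon data frame (see [read_exon_annotation()]).
#' @param junctions A junction set (see [read_junctions()]).
#' @return Non-negative integer count.
#' @export
count_skip <- function(exon, junctions) {
  hit <- junctions$chrom == exon$chrom &
    strand_compatible(junctions$strand, exon$strand) &
    junctions$intron_start < exon$start &
    junctions$intron_end > exon$end
  sum(junctions$count[hit])
}

#' Count inclusion evidence for one exon
#'
#' Sums read counts of strand-compatible junctions whose intron ends at
#' the exon's 5' boundary or starts at its 3' boundary.
#'
#' @inheritParams count_skip
#' @return Non-negative integer count.
#' @export
count_inclusion <- function(exon, junctions) {
  compat <- junctions$chrom == exon$chrom &
    strand_compatible(junctions$strand, exon$strand)
  hit <- compat & (junctions$intron_end == exon$start |
                   junctions$intron_start == exon$end)
  sum(junctions$count[hit])
}

# vectorised skip + inclusion counts for all exons against one junction set
count_junction_support <- function(exons, junctions) {
  ex <- data.table::as.data.table(exons)
  ex[, row := .I]
  skip <- integer(nrow(ex))
  incl <- integer(nrow(ex))
  if (nrow(junctions) > 0L) {
    jd <- data.table::as.data.table(as.data.frame(junctions))
    sk <- jd[ex, on = c("chrom", "intron_start < start", "intron_end > end"),
             list(n = sum(count[strand_compatible(strand, i.strand)])),
             by = .EACHI, allow.cartesian = TRUE]
    skip <- ifelse(is.na(sk$n), 0L, sk$n)
    acc <- jd[ex, on = c("chrom", intron_end = "start"),
              list(n = sum(count[strand_compatible(strand, i.strand)])),
              by = .EACHI]
    don <- jd[ex, on = c("chrom", intron_start = "end"),
              list(n = sum(count[strand_compatible(strand, i.strand)])),
              by = .EACHI]
    incl <- ifelse(is.na(acc$n), 0L, acc$n) + ifelse(is.na(don$n), 0L, don$n)
  }
  data.frame(row = ex$row, skip = skip, incl = incl)
}

#' Expression-normalised event rate
#'
#' Divides an evidence count by the gene's expression, subject to the
#' minimum-expression cutoff: genes at or below the cutoff are not
#' quantifiable and return `NA` (the exon is excluded from testing — a
#' gene must pass the cutoff in every sample to be testable).
#'
#' @param count Non-negative evidence count.
#' @param expression Gene expression in TPM.
#' @param cutoff Minimum expression; rates require `expression > cutoff`
#'   (default 0.025 TPM).
#' @return `count / expression`, or `NA` when expression is at or below
#'   the cutoff.
#' @export
normalize_rates <- function(count, expression, cutoff = 0.025) {
  if (any(count < 0)) stop("normalize_rates: negative count")
  if (any(expression < 0)) stop("normalize_rates: negative expression")
  ifelse(expression > cutoff, count / expression, NA_real_)
}

#' Per-exon differential usage table
#'
#' For every annotated exon, computes per-sample skip and inclusion rates
#' (junction counts normalised by gene expression), classifies the exon by
#' its dominant direction of change (exclusion when the absolute skip-rate
#' contrast is at least the absolute inclusion-rate contrast, inclusion
#' otherwise), and tests the dominant direction's per-sample rates with
#' Welch's t-test (mutant vs wild type). The signed contrast `x` is
#' positive for exclusion events and negative (the negated inclusion
#' contrast) for inclusion events, so that the two volcano edges at +1/-1
#' are exons affected in the mutant but not at all in the wild type.
#'
#' @param annotation Exon annotation (see [read_exon_annotation()]).
#' @param junction_sets Named list of junction sets, one per sample; names
#'   must match `design$sample_id`.
#' @param expression Genes x samples TPM matrix.
#' @param design Sample design (see [read_design()]).
#' @param alpha Significance level used by downstream summaries (default
#'   0.05; no multiple-testing correction is applied).
#' @param tpm_cutoff Minimum expression for testability (default 0.025).
#' @return A `data.frame`, one row per testable exon, sorted by p-value:
#'   exon identity and coordinates, `event_class`, `x`, `p`, `degenerate`,
#'   `significant`, and per-sample `skip_rate.*` / `incl_rate.*` columns.
#' @export
usage_table <- function(annotation, junction_sets, expression, design,
                        alpha = 0.05, tpm_cutoff = 0.025) {
  samples <- design$sample_id
  check_two_per_genotype(design)
  if (!all(samples %in% names(junction_sets)))
    stop("usage_table: junction set missing for sample ",
         setdiff(samples, names(junction_sets))[1L])
  if (!all(samples %in% colnames(expression)))
    stop("usage_table: expression column missing for sample ",
         setdiff(samples, colnames(expression))[1L])

  known <- annotation$gene_id %in% rownames(expression)
  if (!all(known)) {
    warning("dropping ", sum(!known), " exon(s) of genes absent from the ",
            "expression table")
    annotation <- annotation[known, , drop = FALSE]
  }
  n_ex <- nrow(annotation)
  if (n_ex == 0L) stop("usage_table: no testable exons")

  expr <- expression[annotation$gene_id, samples, drop = FALSE]
  skip_rate <- incl_rate <- matrix(NA_real_, n_ex, length(samples),
                                   dimnames = list(NULL, samples))
  for (s in samples) {
    counts <- count_junction_support(annotation, junction_sets[[s]])
    skip_rate[, s] <- normalize_rates(counts$skip, expr[, s], tpm_cutoff)
    incl_rate[, s] <- normalize_rates(counts$incl, expr[, s], tpm_cutoff)
  }

  testable <- rowSums(is.na(skip_rate)) == 0L
  if (!any(testable))
    stop("usage_table: no testable exons (every gene fails the ",
         "expression cutoff in at least one sample)")
  is_mut <- samples %in% design$sample_id[design$genotype == "MUT"]

  res <- volcano_rows(skip_rate[testable, , drop = FALSE],
                      incl_rate[testable, , drop = FALSE], is_mut)
  out <- cbind(annotation[testable, , drop = FALSE][res$keep, , drop = FALSE],
               res$stats)
  rates <- cbind(skip_rate[testable, , drop = FALSE][res$keep, , drop = FALSE],
                 incl_rate[testable, , drop = FALSE][res$keep, , drop = FALSE])
  colnames(rates) <- c(paste0("skip_rate.", samples),
                       paste0("incl_rate.", samples))
  out <- cbind(out, rates)
  out$significant <- out$p < alpha
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

check_two_per_genotype <- function(design) {
  tab <- table(factor(design$genotype, levels = c("WT", "MUT")))
  if (any(tab < 2L))
    stop("need at least 2 samples per genotype (found WT=", tab[["WT"]],
         ", MUT=", tab[["MUT"]], ")")
  invisible(design)
}

# classify rows by dominant direction and test them; rows with neither
# contrast defined (no evidence at all) are dropped
volcano_rows <- function(skip_rate, incl_rate, is_mut) {
  n <- nrow(skip_rate)
  event_class <- character(n)
  x <- p <- rep(NA_real_, n)
  degenerate <- logical(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    xs <- normalized_contrast(skip_rate[i, is_mut], skip_rate[i, !is_mut])
    xi <- normalized_contrast(incl_rate[i, is_mut], incl_rate[i, !is_mut])
    if (is.na(xs) && is.na(xi)) next
    keep[i] <- TRUE
    skip_dom <- if (is.na(xi)) TRUE else if (is.na(xs)) FALSE else
      abs(xs) >= abs(xi)
    rates <- if (skip_dom) skip_rate[i, ] else incl_rate[i, ]
    x[i] <- if (skip_dom) xs else -xi
    # axis semantics: positive shift = exclusion side, negative =
    # inclusion side; an exact zero falls to exclusion (majority class)
    event_class[i] <- if (x[i] < 0) "inclusion" else "exclusion"
    w <- welch_t(rates[is_mut], rates[!is_mut])
    p[i] <- w$p
    degenerate[i] <- w$degenerate
  }
  list(keep = keep,
       stats = data.frame(event_class = event_class[keep], x = x[keep],
                          p = p[keep], degenerate = degenerate[keep],
                          stringsAsFactors = FALSE))
}

#' Significant events of a volcano table
#'
#' @param events A table from [usage_table()] or [readthrough_table()].
#' @param alpha Significance level (default 0.05).
#' @return The rows with `p < alpha`.
#' @export
significant_events <- function(events, alpha = 0.05) {
  events[events$p < alpha, , drop = FALSE]
}
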