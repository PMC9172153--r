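# Censored delta-Ct analysis of isoform-specific qPCR.
#
# Each measurement pairs the Ct of an abnormal (mis-processed) transcript
# isoform with the Ct of the normal isoform from the same cDNA. The
# statistic is delta-Ct = Ct_abnormal - Ct_normal: fewer cycles between
# the two means relatively more abnormal transcript. When the abnormal
# isoform never crosses threshold within the run's cycle ceiling
# (default 40 cycles), the ceiling is substituted for Ct_abnormal and the
# resulting delta-Ct is a censored lower limit ("> x"). When the normal
# isoform itself is undetected the pair is uninformative ("ND") and is
# excluded from averages. Substituting censored values at their limit
# makes every group mean a lower bound on the truth — a conservative,
# auditable convention.

#' Delta-Ct of one qPCR measurement with detection-limit handling
#'
#' @param ct_abnormal,ct_normal Ct values in `(0, ceiling]`, or `NA` for
#'   not-detected.
#' @param ceiling Cycle ceiling of the assay (default 40).
#' @return A single-row `data.frame` with `value`, `is_lower_limit`
#'   (abnormal isoform censored) and `is_missing` (normal isoform
#'   undetected; `value` is `NA`).
#' @export
delta_ct <- function(ct_abnormal, ct_normal, ceiling = 40) {
  chk <- function(ct, what) {
    if (!is.na(ct) && (ct <= 0 || ct > ceiling))
      stop("delta_ct: ", what, " must lie in (0, ", ceiling, "]")
  }
  chk(ct_abnormal, "ct_abnormal"); chk(ct_normal, "ct_normal")
  if (is.na(ct_normal))
    return(data.frame(value = NA_real_, is_lower_limit = FALSE,
                      is_missing = TRUE))
  if (is.na(ct_abnormal))
    return(data.frame(value = ceiling - ct_normal, is_lower_limit = TRUE,
                      is_missing = FALSE))
  data.frame(value = ct_abnormal - ct_normal, is_lower_limit = FALSE,
             is_missing = FALSE)
}

#' Delta-Ct values for a whole Ct table
#'
#' Applies [delta_ct()] row-wise to a table from [read_qpcr_table()].
#'
#' @param ct_table Data frame with `ct_abnormal`, `ct_normal` and any
#'   grouping columns (`target`, `organ`, `genotype`, `mouse_id`).
#' @param ceiling Cycle ceiling (default: the table's `ceiling`
#'   attribute, else 40).
#' @return The input grouping columns with `value`, `is_lower_limit`,
#'   `is_missing` appended.
#' @export
delta_ct_table <- function(ct_table, ceiling = NULL) {
  if (is.null(ceiling)) ceiling <- attr(ct_table, "ceiling") %||% 40
  dc <- do.call(rbind, lapply(seq_len(nrow(ct_table)), function(i)
    delta_ct(ct_table$ct_abnormal[i], ct_table$ct_normal[i], ceiling)))
  keep <- intersect(c("target", "organ", "genotype", "mouse_id"),
                    names(ct_table))
  cbind(ct_table[, keep, drop = FALSE], dc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group summary of censored delta-Ct values
#'
#' Mean over non-missing values with censored values entered at their
#' limit; the result therefore never exceeds the mean of any consistent
#' completion of the censored data (it is itself a lower limit whenever
#' any constituent was censored). Fully missing pairs ("ND") are
#' excluded and counted separately.
#'
#' @param values Data frame with `value`, `is_lower_limit`, `is_missing`
#'   (e.g. rows of [delta_ct_table()] or [read_delta_ct_table()]).
#' @return A list: `mean_delta_ct`, `is_lower_limit`, `n_used`, `n_nd`.
#' @export
group_summary <- function(values) {
  usable <- !values$is_missing
  if (!any(usable)) stop("group_summary: all values missing")
  list(mean_delta_ct = mean(values$value[usable]),
       is_lower_limit = any(values$is_lower_limit[usable]),
       n_used = sum(usable), n_nd = sum(!usable))
}

#' Delta-delta-Ct between genotype summaries
#'
#' `ddCt = mean(WT delta-Ct) - mean(MUT delta-Ct)`: the number of cycles
#' by which the abnormal isoform is relatively enriched in the mutant.
#' When the WT mean is itself a lower limit the difference is one too.
#'
#' @param wt,mut Group summaries from [group_summary()].
#' @return A list with `ddct` and `is_lower_limit`.
#' @export
delta_delta_ct <- function(wt, mut) {
  list(ddct = wt$mean_delta_ct - mut$mean_delta_ct,
       is_lower_limit = isTRUE(wt$is_lower_limit))
}

#' Censored delta-Ct report across targets and organs
#'
#' Produces the full multi-organ analysis from per-replicate delta-Ct
#' values: per (organ, target, genotype) summaries, a Welch test per
#' (organ, target) and per organ (pooled over targets) comparing WT and
#' mutant with censored values substituted at their limits, and pooled
#' per-genotype grand means with their delta-delta-Ct.
#'
#' @param dct Data frame with columns `organ`, `target`, `genotype`,
#'   `value`, `is_lower_limit`, `is_missing` (see
#'   [read_delta_ct_table()] / [delta_ct_table()]; a `mouse_id` column is
#'   accepted in place of `replicate`).
#' @return A list of data frames: `cells` (per organ/target/genotype
#'   summaries), `tests` (per organ/target Welch results; `NA` with a
#'   reason when untestable), `organ_tests` (pooled per organ), and
#'   `pooled` (grand WT / MUT means, ddCt and its censoring flag).
#' @export
qpcr_report <- function(dct) {
  stopifnot(all(c("organ", "target", "genotype", "value") %in% names(dct)))
  if (is.null(dct$is_missing)) dct$is_missing <- is.na(dct$value)
  if (is.null(dct$is_lower_limit)) dct$is_lower_limit <- FALSE
  dct$genotype <- factor(dct$genotype, levels = c("WT", "MUT"))

  cells <- do.call(rbind, lapply(
    split(dct, list(dct$organ, dct$target, dct$genotype), drop = TRUE),
    function(g) {
      if (all(g$is_missing))
        return(data.frame(organ = g$organ[1L], target = g$target[1L],
                          genotype = g$genotype[1L], mean_delta_ct = NA_real_,
                          is_lower_limit = NA, n_used = 0L,
                          n_nd = nrow(g)))
      s <- group_summary(g)
      data.frame(organ = g$organ[1L], target = g$target[1L],
                 genotype = g$genotype[1L], mean_delta_ct = s$mean_delta_ct,
                 is_lower_limit = s$is_lower_limit, n_used = s$n_used,
                 n_nd = s$n_nd)
    }))
  rownames(cells) <- NULL

  welch_groups <- function(g, by) {
    wt <- g$value[g$genotype == "WT" & !g$is_missing]
    mut <- g$value[g$genotype == "MUT" & !g$is_missing]
    base <- data.frame(g[1L, by, drop = FALSE], n_wt = length(wt),
                       n_mut = length(mut))
    if (length(wt) < 2L || length(mut) < 2L)
      return(cbind(base, t = NA_real_, p = NA_real_, degenerate = NA,
                   reason = "fewer than 2 usable values in a genotype"))
    w <- welch_t(wt, mut)
    cbind(base, t = w$t, p = w$p, degenerate = w$degenerate,
          reason = NA_character_)
  }
  tests <- do.call(rbind, lapply(
    split(dct, list(dct$organ, dct$target), drop = TRUE),
    welch_groups, by = c("organ", "target")))
  organ_tests <- do.call(rbind, lapply(split(dct, dct$organ),
                                       welch_groups, by = "organ"))
  rownames(tests) <- rownames(organ_tests) <- NULL

  pooled_sum <- lapply(split(dct, dct$genotype), group_summary)
  dd <- delta_delta_ct(pooled_sum$WT, pooled_sum$MUT)
  pooled <- data.frame(
    genotype = c("WT", "MUT"),
    mean_delta_ct = c(pooled_sum$WT$mean_delta_ct,
                      pooled_sum$MUT$mean_delta_ct),
    is_lower_limit = c(pooled_sum$WT$is_lower_limit,
                       pooled_sum$MUT$is_lower_limit),
    n_used = c(pooled_sum$WT$n_used, pooled_sum$MUT$n_used),
    n_nd = c(pooled_sum$WT$n_nd, pooled_sum$MUT$n_nd))
  list(cells = cells, tests = tests, organ_tests = organ_tests,
       pooled = pooled, ddct = dd$ddct,
       ddct_is_lower_limit = dd$is_lower_limit)
}
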