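# End-to-end driver: exon usage -> motif bias, readthrough, summary
# counts and a reproducibility manifest. All defaults are the analysis
# parameters of the motivating study: p < 0.05 (no FDR), 0.025 TPM
# expression cutoff, 275 bp PAS window, 250 bp motif windows, 5-mers.

#' Load a dataset directory
#'
#' Reads the file layout written by [write_simulation()] (and produced
#' by standard upstream tools): `annotation.gtf`, `pas.bed`,
#' `expression.tsv`, `design.tsv`, `genome.fa`, plus per-sample
#' `junctions_<sample>.bed` (BED12 junction dialect) and
#' `coverage_<sample>.bedgraph`.
#'
#' @param dir Dataset directory.
#' @return A list with `annotation`, `pas`, `expression`, `design`,
#'   `junction_sets`, `coverage_tracks` and (if `genome.fa` exists)
#'   `genome`.
#' @export
load_dataset <- function(dir) {
  p <- function(...) file.path(dir, ...)
  design <- read_design(p("design.tsv"))
  junction_sets <- lapply(stats::setNames(design$sample_id,
                                          design$sample_id),
                          function(s) read_junctions(
                            p(sprintf("junctions_%s.bed", s)),
                            "bed12_junctions", sample_id = s))
  coverage_tracks <- lapply(stats::setNames(design$sample_id,
                                            design$sample_id),
                            function(s) read_coverage(
                              p(sprintf("coverage_%s.bedgraph", s)),
                              "bedgraph"))
  out <- list(annotation = read_exon_annotation(p("annotation.gtf"), "gtf"),
              pas = read_pas_bed(p("pas.bed")),
              expression = read_expression_table(p("expression.tsv")),
              design = design, junction_sets = junction_sets,
              coverage_tracks = coverage_tracks)
  if (file.exists(p("genome.fa")))
    out$genome <- Biostrings::readDNAStringSet(p("genome.fa"))
  out
}

#' Run the full mRNA-processing analysis
#'
#' Executes the exon-usage stage, the readthrough stage and (when a
#' genome is available) the motif-bias stage on a dataset, writes the
#' volcano and motif tables plus summary counts as TSV, and a JSON
#' manifest recording parameters, package version and output checksums.
#' On any stage failure the partially written outputs are removed.
#'
#' @param dataset A list as returned by [load_dataset()] or
#'   [simulate_dataset()].
#' @param out_dir Output directory (created if needed).
#' @param alpha Significance level (default 0.05; no FDR correction).
#' @param tpm_cutoff Expression cutoff in TPM (default 0.025).
#' @param pas_window Downstream PAS window width (default 275 bp).
#' @param motif_window Exon-boundary flank width (default 250 bp).
#' @param k Motif length (default 5).
#' @param spearman_threshold Critical |rho| for motif significance;
#'   `NULL` computes it from the number of significant events at
#'   one-tailed alpha = 0.05.
#' @return Invisibly, a list with the three result tables and the
#'   summary counts.
#' @export
run_pipeline <- function(dataset, out_dir, alpha = 0.05,
                         tpm_cutoff = 0.025, pas_window = 275L,
                         motif_window = 250L, k = 5L,
                         spearman_threshold = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- file.path(out_dir, c("usage.tsv", "readthrough.tsv",
                                  "motifs.tsv", "summary.tsv",
                                  "manifest.json"))
  on_fail <- function(stage) function(e) {
    unlink(outputs)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  usage <- tryCatch(
    usage_table(dataset$annotation, dataset$junction_sets,
                dataset$expression, dataset$design, alpha, tpm_cutoff),
    error = on_fail("exon-usage"))
  write_result_tsv(usage, outputs[1L])

  rt <- tryCatch(
    readthrough_table(dataset$pas, dataset$coverage_tracks,
                      dataset$expression, dataset$design, pas_window,
                      alpha, tpm_cutoff),
    error = on_fail("readthrough"))
  write_result_tsv(rt, outputs[2L])

  motifs <- NULL
  sig <- significant_events(usage, alpha)
  if (!is.null(dataset$genome)) {
    motifs <- tryCatch(
      motif_usage_correlation(sig, dataset$genome, motif_window, k,
                              spearman_threshold),
      error = on_fail("motif-bias"))
    write_result_tsv(motifs, outputs[3L])
  }

  sig_rt <- significant_events(rt, alpha)
  counts <- data.frame(
    stat = c("usage_events", "usage_significant", "exclusion_significant",
             "inclusion_significant", "usage_genes_significant",
             "pas_events", "pas_significant", "readthrough_significant",
             "effective_pas_significant", "motif_significant"),
    value = c(nrow(usage), nrow(sig),
              sum(sig$event_class == "exclusion"),
              sum(sig$event_class == "inclusion"),
              length(unique(sig$gene_id)),
              nrow(rt), nrow(sig_rt), sum(sig_rt$x > 0),
              sum(sig_rt$x < 0),
              if (is.null(motifs)) NA_integer_ else sum(motifs$significant)))
  write_result_tsv(counts, outputs[4L])

  manifest <- list(
    package = "spliceshift",
    version = as.character(utils::packageVersion("spliceshift")),
    parameters = list(alpha = alpha, tpm_cutoff = tpm_cutoff,
                      pas_window = pas_window, motif_window = motif_window,
                      k = k,
                      spearman_threshold = spearman_threshold %||%
                        attr(motifs, "threshold")),
    samples = dataset$design,
    counts = stats::setNames(as.list(counts$value), counts$stat),
    output_md5 = as.list(tools::md5sum(outputs[file.exists(outputs)])))
  jsonlite::write_json(manifest, outputs[5L], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(usage = usage, readthrough = rt, motifs = motifs,
                 counts = counts))
}

write_result_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", na = "NA")
  invisible(path)
}
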