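#!/usr/bin/env Rscript
# Stage 1: junction-based differential exon usage. Skip and inclusion
# evidence per exon, normalised by gene expression (TPM > 0.025 in every
# sample), signed contrast x and Welch p per exon -> the exon-usage
# volcano table.
suppressMessages(library(spliceshift))

ds <- load_dataset("results/sim")
u <- usage_table(ds$annotation, ds$junction_sets, ds$expression, ds$design)
data.table::fwrite(u, "results/usage.tsv", sep = "\t")
sig <- significant_events(u)
truth <- data.table::fread("results/sim/truth_exons.tsv")
hit <- mean(truth$exon_id[truth$class != "none"] %in% sig$exon_id)
message(sprintf(
  "%d testable exons, %d significant (p<0.05): %d exclusion, %d inclusion across %d genes; %.0f%% of planted events recovered",
  nrow(u), nrow(sig), sum(sig$event_class == "exclusion"),
  sum(sig$event_class == "inclusion"), length(unique(sig$gene_id)),
  100 * hit))
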