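#!/usr/bin/env Rscript
# Stage 2: transcription-termination accuracy. Depth-area in the 275 bp
# window downstream of each PAS, expression-normalised, contrasted
# between genotypes -> the readthrough volcano table.
suppressMessages(library(spliceshift))

ds <- load_dataset("results/sim")
rt <- readthrough_table(ds$pas, ds$coverage_tracks, ds$expression,
                        ds$design)
data.table::fwrite(rt, "results/readthrough.tsv", sep = "\t")
sig <- significant_events(rt)
message(sprintf(
  "%d testable PAS, %d significant: %d readthrough (x>0), %d effective usage (x<0)",
  nrow(rt), nrow(sig), sum(sig$x > 0), sum(sig$x < 0)))
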