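#!/usr/bin/env Rscript
# Stage 3: 5-mer compositional bias around the boundaries of the
# significant exons, correlated (Spearman) with the usage shift x.
suppressMessages(library(spliceshift))

ds <- load_dataset("results/sim")
u <- data.table::fread("results/usage.tsv", data.table = FALSE)
sig <- significant_events(u)
m <- motif_usage_correlation(sig, ds$genome)
data.table::fwrite(m, "results/motifs.tsv", sep = "\t")
down <- m[m$window_class == "downstream", ]
g5 <- down[down$motif == "GGGGG", ]; t5 <- down[down$motif == "TTTTT", ]
message(sprintf(
  "n = %d events, |rho| threshold %.3f; downstream GGGGG rho = %+.2f (%s), TTTTT rho = %+.2f (%s)",
  attr(m, "n_events"), attr(m, "threshold"),
  g5$rho, ifelse(g5$significant, "significant", "ns"),
  t5$rho, ifelse(t5$significant, "significant", "ns")))
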