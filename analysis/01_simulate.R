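#!/usr/bin/env Rscript
# Stage 0: build the ground-truthed synthetic dataset the downstream
# stages analyse — 3 WT vs 3 MUT samples, ~600 exons with ~10% planted
# exclusion and ~6% planted inclusion events (contrast 0.8, CV 0.1),
# one PAS per gene with 10% planted readthrough, and G-rich / T-rich
# composition planted downstream of affected exons.
suppressMessages(library(spliceshift))

sim <- simulate_dataset(simulation_spec(seed = 1L))
write_simulation(sim, "results/sim")
tab <- table(sim$truth_exons$class)
message(sprintf(
  "wrote results/sim: %d genes, %d exons (%d exclusion / %d inclusion planted), %d PAS (%d readthrough planted)",
  length(unique(sim$annotation$gene_id)), nrow(sim$annotation),
  tab[["exclusion"]], tab[["inclusion"]], nrow(sim$pas),
  sum(sim$truth_pas$readthrough)))
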