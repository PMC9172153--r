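# spliceshift

Quantifies systemic mRNA-processing defects from bulk RNA-seq evidence in a
wild-type vs mutant (case/control) design, at three layers:

1. **Differential exon usage from splice junctions.** For each annotated
   exon, *skip* evidence is the read count of junctions whose intron spans
   the whole exon, and *inclusion* evidence the count of junctions landing
   exactly on its boundaries. Per-sample rates are the counts divided by
   the gene's expression (TPM, testable only above 0.025 TPM in every
   sample). Each exon gets a signed contrast
   `x = (m̄ − w̄)/(m̄ + w̄) ∈ [−1, 1]` between mutant and wild-type mean
   rates — saturating at +1 for exons skipped only in the mutant and −1
   for exons included only in the mutant — and a two-sided Welch t-test
   p-value across samples. No FDR correction is applied: at n = 3 vs 3 the
   Welch test is intrinsically conservative.
2. **Transcriptional readthrough.** Read depth-area in a fixed 275 bp
   window downstream (in the direction of transcription) of each annotated
   polyadenylation site, expression-normalised and contrasted the same
   way; positive `x` is readthrough, negative is effective PAS usage.
3. **Compositional bias.** Frequencies of all 4^5 = 1024 5-mers in 250 bp
   windows upstream of, inside, and downstream of each significant exon,
   correlated (Spearman ρ) with the usage shift `x`; |ρ| above the
   t-approximation critical value flags associated motifs.

A censored ΔCt module handles isoform-specific qPCR validation:
ΔCt = Ct(abnormal isoform) − Ct(normal isoform), with non-detections of
the abnormal isoform censored at the cycle ceiling (40) so every group
mean is a conservative lower limit, and Welch tests per organ.

A deterministic synthetic-data generator (`simulate_dataset()`) produces a
complete ground-truthed world — genome FASTA, GTF annotation, per-sample
junction BED12 and bedGraph coverage, expression and design tables, truth
tables — so every stage is verifiable without sequencing data.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the
simulated world (seed 1, 3 WT vs 3 MUT, planted contrast 0.8, 10% noise):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_exon_usage.R
Rscript analysis/03_readthrough.R
Rscript analysis/04_motif_bias.R
Rscript analysis/05_qpcr.R
```

which prints:

```
wrote results/sim: 100 genes, 595 exons (40 exclusion / 24 inclusion planted), 100 PAS (10 readthrough planted)
584 testable exons, 80 significant (p<0.05): 46 exclusion, 34 inclusion across 55 genes; 98% of planted events recovered
98 testable PAS, 10 significant: 10 readthrough (x>0), 0 effective usage (x<0)
n = 80 events, |rho| threshold 0.185; downstream GGGGG rho = +0.83 (significant), TTTTT rho = -0.74 (significant)
pooled delta-Ct: WT > 8.57 (n=80), MUT > 4.29 (n=79); ddCt > 4.28
```

Reading the output: the usage and readthrough stages recover essentially
all planted splicing and termination defects at p < 0.05 while calling
few unplanted features; the motif stage finds the planted G-rich bias
downstream of excluded exons (positive ρ) and T-rich bias downstream of
included exons (negative ρ); and the bundled multi-organ qPCR table
yields a pooled wild-type mean ΔCt that is a censored lower limit (> 8.57
cycles, n = 80 usable values) against > 4.29 in the mutant — a pooled
ΔΔCt > 4.28 cycles, i.e. roughly 20-fold relative enrichment of abnormal
transcripts in mutant tissues.

Equivalent single calls: `run_pipeline(simulate_dataset(simulation_spec(seed = 1)), "out/")`
and `qpcr_report(read_delta_ct_table(...))`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the complete computation from scratch against the installed
package: it simulates the seeded dataset, executes all three RNA-seq
stages through `run_pipeline()`, recomputes the censored qPCR report from
the bundled table, logs the headline counts, and writes the JSON result
file.
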