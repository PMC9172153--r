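---
title: "Quantifying systemic mRNA-processing defects: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying systemic mRNA-processing defects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceshift)
```

## The problem

A mutation that perturbs the transcription/splicing machinery does not
necessarily deregulate *which* genes are expressed; it can instead degrade
*how accurately* transcripts are processed — exons dropped or retained,
transcription running past the polyadenylation site (PAS), with sequence
composition around the affected exons biasing which ones suffer.
`spliceshift` measures these three layers from junction-level and
coverage-level RNA-seq evidence in a small replicated wild-type (WT) vs
mutant (MUT) design, and provides a censored ΔCt framework for targeted
qPCR validation of individual mis-processing events.

## Models and statistics

### Exon usage

For exon $e$ and sample $s$, skip evidence $k_{es}$ is the summed read
count of junctions whose intron strictly spans the exon
(`intron_start < start` and `intron_end > end`), and inclusion evidence
$i_{es}$ the summed count of junctions whose intron ends at the exon 5'
boundary or starts at its 3' boundary. Junction strand must match the
exon unless unknown (`.`), in which case it is accepted — TopHat-style
junction files do not always carry strand. Rates are
$k_{es}/E_{gs}$ with $E_{gs}$ the gene's TPM; a gene must exceed
0.025 TPM in **every** sample to be testable, otherwise the exon is
dropped rather than contributing unstable ratios.

The per-exon effect statistic is the signed normalized contrast of
genotype mean rates,
$$x = \frac{\bar m - \bar w}{\bar m + \bar w} \in [-1, 1],$$
which is scale-invariant and saturates at $+1$ when the event occurs in
the mutant but never in WT. Significance is a two-sided Welch t-test on
the per-sample rates of the *dominant* direction (the one with larger
$|x|$; skip if tied or if inclusion is undefined). The event class
follows the sign of the final $x$: positive is the exclusion side of the
volcano, negative the inclusion side, an exact zero falls to exclusion
(the majority class). We use the sign of $x$ rather than the identity of
the dominant evidence stream because the volcano axis is a direction of
change — a mutant *decrease* in skipping is an inclusion-side event even
though skip junctions carry the evidence.

### Readthrough

For each PAS, the depth-area of coverage in a `width = 275` bp window
downstream in the direction of transcription ($[site, site+275)$ on `+`,
$[site-275, site)$ on `-`), divided by the gene's TPM, gives the
per-sample downstream rate; $x$ and Welch $p$ follow as above. Area
counting (depth × overlap) was chosen over discrete read counting so
bedGraph input suffices; when a track is built from read intervals the
area is divided by the mean read length, making the two dialects agree in
expectation. Multiple PAS per gene are tested independently.

### Motif bias

For every significant usage event, three windows are read in transcribed
orientation (reverse-complemented and mirrored for `-` exons): 250 bp
upstream of the 5' boundary, the exon itself, 250 bp downstream of the 3'
boundary. Overlapping 5-mer frequencies (denominator = number of
all-ACGT windows; N-containing windows excluded from both sides) are
probability vectors over the $4^5 = 1024$ motifs. Each motif × window
class gets the Spearman correlation $\rho$ across events between its
frequency and the signed usage value $x$, so positive $\rho$ ties a motif
to exclusion and negative to inclusion. Significance uses the
t-approximation critical value
$\rho^* = t^*/\sqrt{n-2+t^{*2}}$ at one-tailed $\alpha = 0.05$ by
default ($\rho^* \approx 0.069$ at $n = 571$). A published-style preset
threshold (e.g. 0.0655) can be passed explicitly; that value does not
match the one- or two-tailed t-approximation at $\alpha=0.05$ and its
derivation is not standard, so it is a configurable preset rather than
the default. Correlating against the continuous $x$ is the default; a
binary (sign-only) mode exists because either reading of "correlation
with inclusion or exclusion" is defensible.

### Censored qPCR ΔCt

$\Delta Ct_{A\text{-}N} = Ct_{abnormal} - Ct_{normal}$; fewer cycles
between the two means relatively more abnormal transcript. When the
abnormal isoform never crosses threshold within the run's 40-cycle
ceiling, 40 is substituted for $Ct_A$ and the ΔCt is a censored lower
limit; when the normal isoform itself is undetected the pair is
uninformative ("ND") and excluded from averages (group $n$ varies
accordingly). Group means substitute censored values at their limit and
are therefore themselves lower bounds under any consistent completion —
conservative and auditable. $\Delta\Delta Ct$ = WT mean − MUT mean
inherits the WT flag. Welch tests on limit-substituted values compare
genotypes per organ and per (organ, target); survival-style censored
tests were deliberately not used — with 40-cycle ceilings the
substitution bias is small, conservative, and transparent.

## Key parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `alpha` | 0.05 | — | volcano significance level, no FDR |
| `tpm_cutoff` | 0.025 | TPM | minimum expression for testability (strict `>`) |
| `pas_window` | 275 | bp | readthrough window downstream of the PAS |
| `motif_window` | 250 | bp | flank width around exon boundaries |
| `k` | 5 | nt | motif length (1024 motifs) |
| `ceiling` | 40 | cycles | qPCR detection ceiling for censoring |

All coordinates are 0-based half-open internally; GTF (1-based
inclusive) and SJ.out.tab conventions are converted only at I/O
boundaries, and writers invert readers exactly (round-trip tested).

## The synthetic world

`simulation_spec()` states the world the tests run in: 3 WT vs 3 MUT
samples; ~100 genes of 4–8 exons (90–300 bp) with 300–800 bp introns on
both strands of two chromosomes; log-normal expression around 30 TPM
(σ(log) = 1), with 2% of genes forced below the testability cutoff;
baseline skip fraction 0.05; 10% of internal exons planted as exclusion
and 6% as inclusion events at contrast 0.8 (i.e. the affected fraction
rises 9-fold, mirroring the observed dominance of exclusion over
inclusion events); one PAS per gene with baseline downstream/gene signal
ratio 0.05 and 10% planted readthrough at the same contrast;
multiplicative gamma noise with CV 0.1; G-rich (55% G) and T-rich (55%
T) composition overwriting the transcribed-downstream 250 bp window of
planted exclusion and inclusion exons respectively.

Two generator choices deserve explanation:

* **Sufficient statistics, not reads.** The pipeline consumes junction
  counts and coverage, so the generator emits exactly those, as rounded
  gamma-perturbed expected values. No alignment artifacts, mappability,
  PCR duplicates or sequencing error are modelled.
* **One biological noise draw per exon-sample.** The realized splicing
  fraction fluctuates (CV 0.1 on the minority share), and skip and
  inclusion evidence are the two complementary shares of the same
  transcripts. Modelling the two streams with *independent* noise would
  make the dominant-direction rule select the larger of two independent
  null statistics and inflate the pipeline's type-I error (~6% measured);
  with the shared draw the two directions' Welch tests coincide exactly
  and calibration is preserved. Each exon also owns private skip,
  acceptor and donor junctions anchored inside its flanking introns so a
  planted effect never bleeds into a neighbouring exon's evidence —
  stylized relative to real shared junctions, but it makes the planted
  truth table exact.

A green test on this world therefore establishes correctness of the
counting, normalization, contrast and testing machinery, and
recoverability of planted effects at realistic noise — not performance on
real aligned reads, where junction ambiguity, overlapping genes and
coverage artifacts add failure modes this generator does not model.

## Numerical and degenerate-case choices

* Welch's test with both groups constant: $p = 1$ if means are equal,
  $p = 0$ with a `degenerate` flag otherwise, keeping volcano row counts
  stable and auditable.
* At n = 3 vs 3 the Welch test rejects null features at ~0.033–0.035,
  not 0.05 — verified against `stats::t.test` under ideal Gaussian
  noise. This intrinsic small-sample conservatism is the design's
  justification for using no FDR correction; the test suite asserts
  conservatism (never anticonservative) rather than exact nominal
  calibration, which is unattainable at this design size.
* Spearman ties get average ranks; constant vectors give `NA` with a
  warning rather than a fabricated 0.
* Events with no evidence in either direction (both contrasts undefined)
  are dropped; windows clipped at chromosome ends are flagged.
* Exons shorter than 250 bp use the whole exon as the "inside" window by
  default (`inside_mode = "fixed"` truncates instead).

## Limitations

* Junction-count semantics are taken from the input file as given
  (unique-mapping column for SJ.out.tab); no re-filtering of multimappers.
* No PSI/ΔPSI, isoform reconstruction, de-novo PAS discovery, motif
  discovery beyond exhaustive k-mers, or differential gene expression —
  out of scope by design.
* The qPCR module assumes equal amplification efficiency between the two
  isoform assays; no standard curves or absolute quantification.
* Headline event counts from the motivating deposited dataset require
  the full sequencing data and genome alignment and are not reproducible
  at desk scale; the synthetic world covers the machinery with planted
  ground truth instead.
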