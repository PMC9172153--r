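# Ground-truthed synthetic data for the whole pipeline.
#
# The generator emulates the design of the motivating study: three
# wild-type vs three mutant livers, genotype-dependent exon skipping and
# post-PAS readthrough, expression-normalised evidence, and G-rich /
# T-rich compositional bias downstream of affected exons. It produces
# the sufficient statistics the pipeline consumes (junction counts and
# coverage depth, not reads): per exon and sample, skip evidence is
# proportional to expression times the genotype's skip fraction and
# inclusion evidence to expression times the inclusion fraction, each
# perturbed by multiplicative gamma noise with a configured CV and
# rounded. Every exon owns three private junctions (skip, acceptor,
# donor) anchored inside its flanking introns so that planted effects
# never bleed into a neighbouring exon's evidence. One PAS per gene sits
# at the annotated 3' end; downstream-window depth is proportional to
# expression times the genotype's readthrough rate.

#' Simulation parameters
#'
#' Defaults state the emulated world: a 3 vs 3 bulk RNA-seq design,
#' ~10% of internal exons planted as exclusion and ~6% as inclusion
#' events (mirroring the observed dominance of exclusion), contrast 0.8,
#' 10% multiplicative noise, log-normal expression around 30 TPM, and a
#' 5% baseline skip / readthrough rate.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Inclusive range of exon counts per gene.
#' @param exon_len,intron_len Inclusive length ranges (bp). Introns must
#'   be at least 60 bp for the private junction anchors; at least 250 bp
#'   leaves room for un-truncated motif windows.
#' @param intergenic Gap between genes and at chromosome ends (bp).
#' @param n_chroms Number of chromosomes genes are distributed over.
#' @param n_samples_per_genotype Replicates per genotype (default 3).
#' @param baseline_skip Wild-type skip fraction of an unaffected exon.
#' @param baseline_inclusion Wild-type inclusion fraction of a planted
#'   inclusion exon (mostly skipped in WT, recovered in the mutant).
#' @param frac_exclusion,frac_inclusion Fractions of internal exons
#'   planted as exclusion / inclusion events.
#' @param effect_size Target |contrast| of planted events, in (0, 1].
#' @param frac_readthrough Fraction of PAS planted as readthrough.
#' @param baseline_readthrough Wild-type downstream/gene signal ratio.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   per-observation gamma noise.
#' @param expr_meanlog,expr_sdlog Log-normal expression parameters (TPM).
#' @param frac_low_expression Fraction of genes forced below the
#'   testability cutoff (0.025 TPM) to exercise filtering.
#' @param depth_per_tpm Junction reads per TPM of expression at rate 1.
#' @param rt_depth_per_tpm Coverage depth per TPM at readthrough rate 1.
#' @param gc Background base composition (probabilities for A, C, G, T).
#' @param motif_g_rich,motif_t_rich Base probabilities used to overwrite
#'   the 250 bp transcribed-downstream window of planted exclusion /
#'   inclusion exons.
#' @param seed Integer seed fixing every output.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_genes = 100L,
                            exons_per_gene = c(4L, 8L),
                            exon_len = c(90L, 300L),
                            intron_len = c(300L, 800L),
                            intergenic = 600L,
                            n_chroms = 2L,
                            n_samples_per_genotype = 3L,
                            baseline_skip = 0.05,
                            baseline_inclusion = 0.05,
                            frac_exclusion = 0.10,
                            frac_inclusion = 0.06,
                            effect_size = 0.8,
                            frac_readthrough = 0.10,
                            baseline_readthrough = 0.05,
                            noise_cv = 0.10,
                            expr_meanlog = log(30),
                            expr_sdlog = 1,
                            frac_low_expression = 0.02,
                            depth_per_tpm = 10,
                            rt_depth_per_tpm = 2,
                            gc = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                            motif_g_rich = c(A = 0.15, C = 0.15, G = 0.55,
                                             T = 0.15),
                            motif_t_rich = c(A = 0.15, C = 0.15, G = 0.15,
                                             T = 0.55),
                            seed = 1L) {
  spec <- as.list(environment())
  stopifnot(spec$n_genes >= 0L,
            spec$effect_size > 0, spec$effect_size <= 1,
            spec$frac_exclusion >= 0, spec$frac_exclusion <= 1,
            spec$frac_inclusion >= 0, spec$frac_inclusion <= 1,
            spec$frac_exclusion + spec$frac_inclusion <= 1,
            spec$frac_readthrough >= 0, spec$frac_readthrough <= 1,
            spec$noise_cv > 0,
            spec$intron_len[1L] >= 120L,
            spec$n_samples_per_genotype >= 2L)
  class(spec) <- "simulation_spec"
  spec
}

rint <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(range[1L]:range[2L], n, replace = TRUE)
}

random_bases <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Simulate a genome, annotation, PAS catalog and truth table
#'
#' Lays genes with alternating exon/intron structure on both strands
#' across the configured chromosomes, selects planted exclusion /
#' inclusion exons among internal exons and planted readthrough PAS,
#' and overwrites the transcribed-downstream 250 bp window of planted
#' exons with G-rich (exclusion) or T-rich (inclusion) composition.
#'
#' @param spec A [simulation_spec()].
#' @return A list: `genome` (named `DNAStringSet`), `annotation` (exon
#'   data frame), `pas` (PAS catalog), `truth_exons` (exon_id, class,
#'   true_x), `truth_pas` (pas_id, readthrough, true_x) and per-gene
#'   internals used by [simulate_samples()].
#' @export
simulate_genome <- function(spec) {
  set.seed(spec$seed)
  if (spec$n_genes == 0L) {
    return(list(genome = Biostrings::DNAStringSet(),
                annotation = empty_exon_annotation(),
                pas = read_pas_bed_empty(),
                truth_exons = data.frame(exon_id = character(),
                                         gene_id = character(),
                                         class = character(),
                                         true_x = numeric()),
                truth_pas = data.frame(pas_id = character(),
                                       gene_id = character(),
                                       readthrough = logical(),
                                       true_x = numeric()),
                spec = spec))
  }
  n_ex <- rint(spec$n_genes, spec$exons_per_gene)
  chrom_of <- sprintf("chr%d", 1L + (seq_len(spec$n_genes) - 1L) %%
                        spec$n_chroms)
  strand_of <- sample(c("+", "-"), spec$n_genes, replace = TRUE)

  exon_rows <- vector("list", spec$n_genes)
  pas_rows <- vector("list", spec$n_genes)
  cursor <- stats::setNames(rep(spec$intergenic, spec$n_chroms),
                            sprintf("chr%d", seq_len(spec$n_chroms)))
  for (g in seq_len(spec$n_genes)) {
    chrom <- chrom_of[g]
    ne <- n_ex[g]
    elen <- rint(ne, spec$exon_len)
    ilen <- rint(max(ne - 1L, 0L), spec$intron_len)
    starts <- cursor[chrom] + cumsum(c(0L, elen[-ne] + ilen))
    ends <- starts + elen
    gid <- sprintf("gene%03d", g)
    exon_rows[[g]] <- data.frame(
      gene_id = gid,
      exon_id = sprintf("%s.e%02d", gid, seq_len(ne)),
      chrom = chrom, start = as.integer(starts), end = as.integer(ends),
      strand = strand_of[g], stringsAsFactors = FALSE)
    site <- if (strand_of[g] == "+") as.integer(ends[ne]) else
      as.integer(starts[1L])
    pas_rows[[g]] <- data.frame(gene_id = gid,
                                pas_id = sprintf("%s:%d:%s", chrom, site,
                                                 strand_of[g]),
                                chrom = chrom, site = site,
                                strand = strand_of[g],
                                stringsAsFactors = FALSE)
    cursor[chrom] <- ends[ne] + spec$intergenic
  }
  annotation <- do.call(rbind, exon_rows)
  pas <- do.call(rbind, pas_rows)

  # planted event assignment: internal exons only
  internal <- stats::ave(seq_len(nrow(annotation)), annotation$gene_id,
                         FUN = function(i) seq_along(i) > 1L &
                           seq_along(i) < length(i)) == 1
  truth_exons <- data.frame(exon_id = annotation$exon_id,
                            gene_id = annotation$gene_id,
                            class = "none", true_x = 0,
                            stringsAsFactors = FALSE)
  idx <- which(internal)
  n_excl <- round(spec$frac_exclusion * length(idx))
  n_incl <- round(spec$frac_inclusion * length(idx))
  planted <- sample(idx, n_excl + n_incl)
  excl_idx <- planted[seq_len(n_excl)]
  incl_idx <- setdiff(planted, excl_idx)
  truth_exons$class[excl_idx] <- "exclusion"
  truth_exons$true_x[excl_idx] <- spec$effect_size
  truth_exons$class[incl_idx] <- "inclusion"
  truth_exons$true_x[incl_idx] <- -spec$effect_size

  rt_idx <- sample(nrow(pas), round(spec$frac_readthrough * nrow(pas)))
  truth_pas <- data.frame(pas_id = pas$pas_id, gene_id = pas$gene_id,
                          readthrough = seq_len(nrow(pas)) %in% rt_idx,
                          true_x = 0, stringsAsFactors = FALSE)
  truth_pas$true_x[truth_pas$readthrough] <- spec$effect_size

  # genome: background composition, then motif planting in the
  # transcribed-downstream window of planted exons
  chrom_len <- cursor
  genome_chars <- lapply(names(chrom_len), function(chrom)
    random_bases(chrom_len[[chrom]], spec$gc))
  names(genome_chars) <- names(chrom_len)
  plant <- function(row, probs) {
    w <- 250L
    chrom <- annotation$chrom[row]
    if (annotation$strand[row] == "+") {
      s <- annotation$end[row]; e <- s + w
      genome_chars[[chrom]][(s + 1L):e] <<- random_bases(w, probs)
    } else {
      e <- annotation$start[row]; s <- e - w
      sense <- random_bases(w, probs)
      genome_chars[[chrom]][(s + 1L):e] <<-
        rev(c(A = "T", C = "G", G = "C", T = "A")[sense])
    }
  }
  for (row in excl_idx) plant(row, spec$motif_g_rich)
  for (row in incl_idx) plant(row, spec$motif_t_rich)
  genome <- Biostrings::DNAStringSet(vapply(genome_chars, paste0, "",
                                            collapse = ""))
  list(genome = genome, annotation = annotation, pas = pas,
       truth_exons = truth_exons, truth_pas = truth_pas, spec = spec)
}

read_pas_bed_empty <- function() {
  data.frame(gene_id = character(), pas_id = character(),
             chrom = character(), site = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

# genotype-dependent event fractions realizing the planted contrast:
# mutant = wt * (1 + e) / (1 - e) gives (m - w)/(m + w) = e
shifted_rate <- function(base, effect) base * (1 + effect) / (1 - effect)

#' Simulate per-sample junctions, coverage, expression and design
#'
#' Generates, for each sample, a junction set (one private skip,
#' acceptor and donor junction per exon), a coverage track (gene body
#' plus downstream-of-PAS window), and a measured TPM column; counts are
#' expression times rate times mean-1 gamma noise (CV
#' `spec$noise_cv`), rounded for junction reads and left continuous for
#' coverage depth.
#'
#' @param spec A [simulation_spec()].
#' @param sim Output of [simulate_genome()] for the same spec.
#' @param pas_window Downstream window width the coverage is laid over
#'   (default 275, matching the analysis default).
#' @return A list: `design`, `expression` (genes x samples TPM matrix),
#'   `junction_sets` (named list), `coverage_tracks` (named list).
#' @export
simulate_samples <- function(spec, sim, pas_window = 275L) {
  set.seed(spec$seed + 1L)
  ann <- sim$annotation
  n_per <- spec$n_samples_per_genotype
  design <- data.frame(
    sample_id = c(sprintf("WT%d", seq_len(n_per)),
                  sprintf("MUT%d", seq_len(n_per))),
    genotype = rep(c("WT", "MUT"), each = n_per),
    stringsAsFactors = FALSE)
  if (nrow(ann) == 0L) {
    empty_js <- data.frame(chrom = character(), intron_start = integer(),
                           intron_end = integer(), strand = character(),
                           count = integer(), stringsAsFactors = FALSE)
    empty_tr <- coverage_track(data.frame(chrom = character(),
                                          start = integer(),
                                          end = integer(),
                                          depth = numeric()))
    return(list(
      design = design,
      expression = matrix(numeric(), 0L, nrow(design),
                          dimnames = list(NULL, design$sample_id)),
      junction_sets = stats::setNames(
        lapply(design$sample_id, function(s) structure(empty_js,
                                                       sample_id = s)),
        design$sample_id),
      coverage_tracks = stats::setNames(
        rep(list(empty_tr), nrow(design)), design$sample_id)))
  }

  genes <- unique(ann$gene_id)
  gene_mean <- stats::rlnorm(length(genes), spec$expr_meanlog,
                             spec$expr_sdlog)
  low <- stats::runif(length(genes)) < spec$frac_low_expression
  gene_mean[low] <- 0.01
  names(gene_mean) <- genes

  noise <- function(n) stats::rgamma(n, shape = 1 / spec$noise_cv^2,
                                     scale = spec$noise_cv^2)

  # per-exon skip/inclusion fractions by genotype
  cls <- sim$truth_exons$class[match(ann$exon_id, sim$truth_exons$exon_id)]
  e <- spec$effect_size
  skip_wt <- ifelse(cls == "inclusion", 1 - spec$baseline_inclusion,
                    spec$baseline_skip)
  skip_mut <- ifelse(
    cls == "exclusion", shifted_rate(spec$baseline_skip, e),
    ifelse(cls == "inclusion",
           1 - shifted_rate(spec$baseline_inclusion, e),
           spec$baseline_skip))
  rt <- sim$truth_pas[match(sim$pas$pas_id, sim$truth_pas$pas_id), ]
  rt_wt <- rep(spec$baseline_readthrough, nrow(sim$pas))
  rt_mut <- ifelse(rt$readthrough,
                   shifted_rate(spec$baseline_readthrough, e),
                   spec$baseline_readthrough)

  expression <- matrix(NA_real_, length(genes), nrow(design),
                       dimnames = list(genes, design$sample_id))
  junction_sets <- list()
  coverage_tracks <- list()
  gene_span <- do.call(rbind, lapply(split(ann, ann$gene_id), function(g)
    data.frame(gene_id = g$gene_id[1L], chrom = g$chrom[1L],
               start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)))
  gene_span <- gene_span[match(genes, gene_span$gene_id), ]

  for (si in seq_len(nrow(design))) {
    s <- design$sample_id[si]
    mut <- design$genotype[si] == "MUT"
    tpm <- gene_mean * noise(length(genes))
    expression[, s] <- tpm
    ex_tpm <- tpm[ann$gene_id]
    skip_frac <- if (mut) skip_mut else skip_wt
    base <- ex_tpm * spec$depth_per_tpm
    # one biological noise draw per exon and sample: the realized skip
    # fraction fluctuates, and skip and inclusion evidence are the two
    # complementary shares of the same transcripts. The noise perturbs
    # the minority share so fractions stay inside (0, 1).
    nz <- noise(nrow(ann))
    minority <- pmin(skip_frac, 1 - skip_frac)
    real_min <- pmin(minority * nz, 0.99)
    real_skip <- ifelse(skip_frac <= 0.5, real_min, 1 - real_min)
    skip_n <- as.integer(round(base * real_skip))
    incl_n <- as.integer(round(base * (1 - real_skip)))
    acc_n <- incl_n %/% 2L
    don_n <- incl_n - acc_n

    # three private junctions per exon, anchored inside flanking introns
    junction_sets[[s]] <- validate_junction_set(structure(data.frame(
      chrom = rep(ann$chrom, 3L),
      intron_start = c(ann$start - 50L, ann$start - 49L, ann$end),
      intron_end = c(ann$end + 50L, ann$start, ann$end + 49L),
      strand = rep(ann$strand, 3L),
      count = c(skip_n, acc_n, don_n),
      stringsAsFactors = FALSE), sample_id = s))

    rt_rate <- if (mut) rt_mut else rt_wt
    pas_tpm <- tpm[sim$pas$gene_id]
    body_depth <- tpm[gene_span$gene_id] * spec$rt_depth_per_tpm *
      noise(nrow(gene_span))
    win_depth <- pas_tpm * spec$rt_depth_per_tpm * rt_rate *
      noise(nrow(sim$pas))
    win_start <- ifelse(sim$pas$strand == "+", sim$pas$site,
                        pmax(sim$pas$site - pas_window, 0L))
    win_end <- ifelse(sim$pas$strand == "+", sim$pas$site + pas_window,
                      sim$pas$site)
    coverage_tracks[[s]] <- coverage_track(data.frame(
      chrom = c(gene_span$chrom, sim$pas$chrom),
      start = c(gene_span$start, win_start),
      end = c(gene_span$end, win_end),
      depth = c(body_depth, win_depth)))
  }
  list(design = design, expression = expression,
       junction_sets = junction_sets, coverage_tracks = coverage_tracks)
}

#' Run both simulation stages
#'
#' @param spec A [simulation_spec()].
#' @return The combined outputs of [simulate_genome()] and
#'   [simulate_samples()].
#' @export
simulate_dataset <- function(spec) {
  sim <- simulate_genome(spec)
  c(sim, simulate_samples(spec, sim))
}

#' Write a simulated dataset to a directory
#'
#' Emits genome FASTA, GTF annotation, PAS BED, per-sample junction
#' BED12 and bedGraph files, expression and design TSVs and the truth
#' tables, in the external formats the readers consume.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
  write_exon_annotation(sim$annotation, p("annotation.gtf"), "gtf")
  write_pas_bed(sim$pas, p("pas.bed"))
  write_expression_table(sim$expression, p("expression.tsv"))
  write_design(sim$design, p("design.tsv"))
  data.table::fwrite(sim$truth_exons, p("truth_exons.tsv"), sep = "\t")
  data.table::fwrite(sim$truth_pas, p("truth_pas.tsv"), sep = "\t")
  for (s in names(sim$junction_sets)) {
    write_junctions(sim$junction_sets[[s]],
                    p(sprintf("junctions_%s.bed", s)), "bed12_junctions")
    write_coverage(sim$coverage_tracks[[s]],
                   p(sprintf("coverage_%s.bedgraph", s)))
  }
  invisible(dir)
}
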