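# Exon skip/inclusion counting and the usage volcano table.

one_exon <- function(start, end, strand = "+", chrom = "chr1",
                     gene = "g1", id = "g1.e01") {
  data.frame(gene_id = gene, exon_id = id, chrom = chrom,
             start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

junc <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r[[1]], intron_start = as.integer(r[[2]]),
               intron_end = as.integer(r[[3]]), strand = r[[4]],
               count = as.integer(r[[5]]), stringsAsFactors = FALSE)))
}

test_that("count_skip requires the intron to span the whole exon", {
  ex <- one_exon(100, 200)
  expect_equal(count_skip(ex, junc(list("chr1", 50, 300, "+", 7))), 7L)
  expect_equal(count_skip(ex, junc(list("chr1", 150, 300, "+", 7))), 0L)
  expect_equal(count_skip(ex, junc(list("chr1", 50, 300, "+", 3),
                                   list("chr1", 40, 310, "+", 4))), 7L)
  # boundary-touching introns do not span
  expect_equal(count_skip(ex, junc(list("chr1", 100, 300, "+", 5))), 0L)
  expect_equal(count_skip(ex, junc(list("chr1", 50, 200, "+", 5))), 0L)
  # strand compatibility: opposite rejected, unknown accepted
  expect_equal(count_skip(ex, junc(list("chr1", 50, 300, "-", 7))), 0L)
  expect_equal(count_skip(ex, junc(list("chr1", 50, 300, ".", 7))), 7L)
  expect_equal(count_skip(ex, junc(list("chr2", 50, 300, "+", 7))), 0L)
})

test_that("count_inclusion matches junctions at exon boundaries", {
  ex <- one_exon(100, 200)
  js <- junc(list("chr1", 40, 100, "+", 5), list("chr1", 200, 350, "+", 3))
  expect_equal(count_inclusion(ex, js), 8L)
  expect_equal(count_inclusion(ex, junc(list("chr1", 40, 99, "+", 5))), 0L)
  expect_equal(count_inclusion(ex, junc(list("chr1", 201, 350, "+", 5))), 0L)
  # single-exon gene with no flanking junctions
  expect_equal(count_inclusion(ex, js[0, ]), 0L)
})

test_that("counting agrees with the brute-force oracle on random instances", {
  set.seed(14)
  for (i in 1:60) {
    js <- random_junction_set(25)
    js <- js[!duplicated(paste(js$chrom, js$intron_start, js$intron_end,
                               js$strand)), ]
    s <- sample.int(2500L, 1)
    ex <- one_exon(s, s + sample.int(400L, 1),
                   strand = sample(c("+", "-"), 1),
                   chrom = sample(c("chr1", "chr2"), 1))
    expect_equal(count_skip(ex, js), oracle_count_skip(ex, js))
    expect_equal(count_inclusion(ex, js), oracle_count_inclusion(ex, js))
  }
})

test_that("vectorised junction support equals the per-exon functions", {
  set.seed(15)
  spec <- simulation_spec(n_genes = 8L, seed = 15L)
  sim <- simulate_dataset(spec)
  js <- sim$junction_sets[[1L]]
  counts <- spliceshift:::count_junction_support(sim$annotation, js)
  for (i in sample(nrow(sim$annotation), 25)) {
    expect_equal(counts$skip[i], count_skip(sim$annotation[i, ], js))
    expect_equal(counts$incl[i], count_inclusion(sim$annotation[i, ], js))
  }
})

test_that("normalize_rates divides by expression above the cutoff only", {
  expect_equal(normalize_rates(10L, 2.0), 5.0)
  expect_true(is.na(normalize_rates(10L, 0.01)))    # at/below 0.025 TPM
  expect_true(is.na(normalize_rates(10L, 0.025)))   # cutoff is strict
  expect_equal(normalize_rates(0L, 5), 0)
  expect_error(normalize_rates(-1L, 5), "negative")
})

make_usage_fixture <- function(skip_mut, skip_wt, incl_mut = NULL,
                               incl_wt = NULL) {
  # one exon (200, 300) in gene g1 with explicit per-sample evidence
  ann <- one_exon(200, 300)
  design <- data.frame(sample_id = c("w1", "w2", "w3", "m1", "m2", "m3"),
                       genotype = rep(c("WT", "MUT"), each = 3),
                       stringsAsFactors = FALSE)
  expr <- matrix(1, 1, 6, dimnames = list("g1", design$sample_id))
  counts <- c(skip_wt, skip_mut)
  incls <- if (is.null(incl_wt)) rep(10L, 6) else c(incl_wt, incl_mut)
  js <- lapply(seq_len(6), function(i) {
    rows <- junc(list("chr1", 100, 400, "+", counts[i]),
                 list("chr1", 50, 200, "+", incls[i]))
    structure(rows, sample_id = design$sample_id[i])
  })
  names(js) <- design$sample_id
  list(ann = ann, js = js, expr = expr, design = design)
}

test_that("exon skipped only in mutant lands on the +1 volcano edge", {
  f <- make_usage_fixture(skip_mut = c(5L, 6L, 7L), skip_wt = c(0L, 0L, 0L))
  u <- usage_table(f$ann, f$js, f$expr, f$design)
  expect_equal(nrow(u), 1L)
  expect_equal(u$event_class, "exclusion")
  expect_equal(u$x, 1)
  expect_lt(u$p, 0.05)
})

test_that("identical rate vectors give x = 0 and p = 1", {
  f <- make_usage_fixture(skip_mut = c(4L, 4L, 4L), skip_wt = c(4L, 4L, 4L))
  u <- usage_table(f$ann, f$js, f$expr, f$design)
  expect_equal(u$x, 0)
  expect_equal(u$p, 1)
  expect_false(u$significant)
})

test_that("inclusion-dominant exons are classified and signed negatively", {
  # no skipping anywhere; inclusion only in mutant -> left edge x = -1
  f <- make_usage_fixture(skip_mut = c(0L, 0L, 0L), skip_wt = c(0L, 0L, 0L),
                          incl_mut = c(8L, 9L, 10L), incl_wt = c(0L, 0L, 0L))
  u <- usage_table(f$ann, f$js, f$expr, f$design)
  expect_equal(u$event_class, "inclusion")
  expect_equal(u$x, -1)
  expect_lt(u$p, 0.05)
})

test_that("usage_table drops unquantifiable exons and errors on small designs", {
  f <- make_usage_fixture(skip_mut = c(5L, 6L, 7L), skip_wt = c(0L, 0L, 0L))
  f$expr["g1", "w2"] <- 0.01      # below cutoff in one sample -> untestable
  expect_error(usage_table(f$ann, f$js, f$expr, f$design), "no testable")
  small <- f$design[c(1, 4, 5), ]
  expect_error(usage_table(f$ann, f$js[small$sample_id], f$expr, small),
               "2 samples per genotype")
  orphan <- f$ann; orphan$gene_id <- "unknown"; orphan$exon_id <- "u.e01"
  expect_warning(
    expect_error(usage_table(orphan, f$js, f$expr, f$design), "no testable"),
    "absent")
})

test_that("doubling junction counts and expression leaves the volcano unchanged", {
  spec <- simulation_spec(n_genes = 12L, seed = 31L)
  sim <- simulate_dataset(spec)
  u1 <- usage_table(sim$annotation, sim$junction_sets, sim$expression,
                    sim$design)
  js2 <- lapply(sim$junction_sets, function(j) {
    j$count <- 2L * j$count
    j
  })
  u2 <- usage_table(sim$annotation, js2, 2 * sim$expression, sim$design)
  expect_equal(u2$x, u1$x, tolerance = 1e-12)
  expect_equal(u2$p, u1$p, tolerance = 1e-12)
})

test_that("volcano semantics: exclusion x > 0, inclusion x < 0, genes <= events", {
  spec <- simulation_spec(seed = 2L)
  sim <- simulate_dataset(spec)
  u <- usage_table(sim$annotation, sim$junction_sets, sim$expression,
                   sim$design)
  sig <- significant_events(u)
  expect_true(all(sig$x[sig$event_class == "exclusion"] > 0))
  expect_true(all(sig$x[sig$event_class == "inclusion"] < 0))
  expect_lte(length(unique(sig$gene_id)), nrow(sig))
  expect_true(all(abs(u$x) <= 1))
  expect_false(is.unsorted(u$p))
})

test_that("planted exclusion events are recovered from a simulation", {
  spec <- simulation_spec(seed = 1L)
  sim <- simulate_dataset(spec)
  u <- usage_table(sim$annotation, sim$junction_sets, sim$expression,
                   sim$design)
  sig <- significant_events(u)
  truth <- sim$truth_exons
  planted <- truth$exon_id[truth$class == "exclusion"]
  hit <- planted %in% sig$exon_id[sig$event_class == "exclusion"]
  expect_gte(mean(hit), 0.8)
  null_ids <- truth$exon_id[truth$class == "none"]
  fpr <- sum(sig$exon_id %in% null_ids) / sum(u$exon_id %in% null_ids)
  expect_lte(fpr, 0.05)
})
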