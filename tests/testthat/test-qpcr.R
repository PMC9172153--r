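# Censored delta-Ct analysis.

test_that("delta_ct handles detection-limit censoring", {
  d <- delta_ct(32, 28)
  expect_equal(d$value, 4)
  expect_false(d$is_lower_limit || d$is_missing)
  d2 <- delta_ct(NA, 30.6)                 # abnormal isoform undetected
  expect_equal(d2$value, 9.4)
  expect_true(d2$is_lower_limit)
  d3 <- delta_ct(32, NA)                   # normal isoform undetected: ND
  expect_true(d3$is_missing)
  expect_true(is.na(d3$value))
  expect_error(delta_ct(45, 30), "\\(0, 40\\]")
  d4 <- delta_ct(NA, 50, ceiling = 60)     # configurable ceiling
  expect_equal(d4$value, 10)
})

test_that("group_summary averages with censored values at their limit", {
  vals <- data.frame(value = c(4, 6), is_lower_limit = c(FALSE, TRUE),
                     is_missing = FALSE)
  s <- group_summary(vals)
  expect_equal(s$mean_delta_ct, 5)
  expect_true(s$is_lower_limit)
  one <- data.frame(value = 3, is_lower_limit = FALSE, is_missing = FALSE)
  expect_equal(group_summary(one)$mean_delta_ct, 3)
  expect_false(group_summary(one)$is_lower_limit)
  nd <- data.frame(value = NA_real_, is_lower_limit = FALSE,
                   is_missing = TRUE)
  expect_error(group_summary(nd), "all values missing")
  s2 <- group_summary(rbind(vals, nd))
  expect_equal(s2$n_used, 2L)
  expect_equal(s2$n_nd, 1L)
})

test_that("limit-substituted averaging is a lower bound on any completion", {
  set.seed(44)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    vals <- data.frame(value = round(runif(n, -2, 12), 1),
                       is_lower_limit = runif(n) < 0.4,
                       is_missing = FALSE)
    reported <- group_summary(vals)$mean_delta_ct
    for (j in 1:50) {
      completed <- vals$value + ifelse(vals$is_lower_limit,
                                       runif(n, 0, 20), 0)
      expect_gte(mean(completed), reported - 1e-12)
    }
  }
})

test_that("delta_delta_ct subtracts mutant from wild type and carries the flag", {
  wt <- group_summary(data.frame(value = c(10, 10, 10),
                                 is_lower_limit = FALSE, is_missing = FALSE))
  mut <- group_summary(data.frame(value = c(7, 7, 7),
                                  is_lower_limit = FALSE, is_missing = FALSE))
  dd <- delta_delta_ct(wt, mut)
  expect_equal(dd$ddct, 3)
  expect_false(dd$is_lower_limit)
  expect_equal(delta_delta_ct(wt, wt)$ddct, 0)
})

test_that("delta-delta-Ct is invariant to a constant shift of all Ct values", {
  set.seed(45)
  ct <- data.frame(target = "t", organ = "o",
                   genotype = rep(c("WT", "MUT"), each = 3),
                   mouse_id = paste0("m", 1:6),
                   ct_abnormal = runif(6, 20, 35),
                   ct_normal = runif(6, 18, 30))
  base <- delta_ct_table(ct)
  shifted <- ct
  shifted$ct_abnormal <- ct$ct_abnormal + 2
  shifted$ct_normal <- ct$ct_normal + 2
  shift <- delta_ct_table(shifted)
  for (g in c("WT", "MUT"))
    expect_equal(group_summary(shift[shift$genotype == g, ])$mean_delta_ct,
                 group_summary(base[base$genotype == g, ])$mean_delta_ct)
})

test_that("the bundled multi-organ table reproduces its printed summaries", {
  d <- read_delta_ct_table(system.file("extdata", "multiorgan_delta_ct.tsv",
                                       package = "spliceshift"))
  rep <- qpcr_report(d)
  wt <- rep$pooled[rep$pooled$genotype == "WT", ]
  expect_equal(wt$n_used, 80L)
  expect_equal(wt$mean_delta_ct, 8.6, tolerance = 0.01)
  expect_true(wt$is_lower_limit)
  expect_equal(rep$ddct, 4.3, tolerance = 0.01)
  expect_true(rep$ddct_is_lower_limit)
  # no silent drops: summary ns add back up to the 162 input cells
  expect_equal(sum(rep$cells$n_used) + sum(rep$cells$n_nd), nrow(d))
})

test_that("a planted organ-level difference is detected in every organ", {
  set.seed(4)
  organs <- c("liver", "testis", "brain")
  rows <- do.call(rbind, lapply(organs, function(o) {
    data.frame(target = "Pick1", organ = o,
               genotype = rep(c("WT", "MUT"), each = 3),
               mouse_id = paste0(o, "_m", 1:6),
               value = c(rnorm(3, 9, 1), rnorm(3, 4, 1)),   # ddCt = 5
               is_lower_limit = FALSE, is_missing = FALSE)
  }))
  rep <- qpcr_report(rows)
  expect_equal(nrow(rep$organ_tests), 3L)
  expect_true(all(rep$organ_tests$p < 0.05))
  expect_true(all(rep$organ_tests$t > 0))        # WT delta-Ct larger
  expect_equal(rep$ddct, 5, tolerance = 1)
})

test_that("untestable cells are reported as NA with a reason", {
  rows <- data.frame(target = "t", organ = c("o1", "o1", "o1", "o1"),
                     genotype = c("WT", "WT", "MUT", "MUT"),
                     value = c(5, NA, 2, 2.5),
                     is_lower_limit = FALSE,
                     is_missing = c(FALSE, TRUE, FALSE, FALSE))
  rep <- qpcr_report(rows)
  expect_true(is.na(rep$tests$p[1L]))
  expect_match(rep$tests$reason[1L], "fewer than 2")
})
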