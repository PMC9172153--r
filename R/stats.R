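#' Welch's two-sample t-test
#'
#' Unequal-variance two-sample location test with Welch--Satterthwaite
#' degrees of freedom and a two-sided p-value. This is the significance
#' engine behind both volcano stages (exon usage and readthrough): with
#' three replicates per genotype it is conservative enough that no
#' multiple-testing correction is applied downstream.
#'
#' Degenerate inputs (both groups with zero variance) are resolved
#' deterministically rather than erroring: equal means give `t = 0, p = 1`;
#' unequal means give `p = 0` with `degenerate = TRUE`, so the event count
#' of a volcano table stays stable and auditable.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A list with elements `t`, `df`, `p` (two-sided) and `degenerate`.
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("welch_t: each group needs at least 2 values")
  if (anyNA(a) || anyNA(b)) stop("welch_t: NA values not allowed")
  welch_t_from_summary(mean(a), stats::sd(a), length(a),
                       mean(b), stats::sd(b), length(b))
}

#' Welch's t-test from summary statistics
#'
#' Same test as [welch_t()] computed from group means, standard deviations
#' and sizes, for published summary data.
#'
#' @param mean_a,mean_b Group means.
#' @param sd_a,sd_b Group sample standard deviations (>= 0).
#' @param n_a,n_b Group sizes (>= 2).
#' @return A list with elements `t`, `df`, `p` and `degenerate`.
#' @export
welch_t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2L || n_b < 2L) stop("welch_t: each group needs n >= 2")
  if (sd_a < 0 || sd_b < 0) stop("welch_t: negative standard deviation")
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  se2 <- va + vb
  if (se2 == 0) {
    # both variances zero: identical constants in each group
    if (mean_a == mean_b) {
      return(list(t = 0, df = NA_real_, p = 1, degenerate = FALSE))
    }
    return(list(t = sign(mean_a - mean_b) * Inf, df = NA_real_, p = 0,
                degenerate = TRUE))
  }
  t  <- (mean_a - mean_b) / sqrt(se2)
  df <- se2^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  p  <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, degenerate = FALSE)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-fractional ranks (ties receive the mean
#' rank). Used to associate 5-mer frequencies around exon boundaries with
#' the signed exon-usage contrast.
#'
#' @param xs,ys Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` (with a warning) when either
#'   vector is constant, in which case the rank correlation is undefined.
#' @export
spearman_rho <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("spearman_rho: length mismatch")
  if (length(xs) < 3L) stop("spearman_rho: need at least 3 pairs")
  if (length(unique(xs)) < 2L || length(unique(ys)) < 2L) {
    warning("spearman_rho: constant input, correlation undefined")
    return(NA_real_)
  }
  stats::cor(rank(xs), rank(ys), method = "pearson")
}

#' Critical Spearman correlation at a given significance level
#'
#' The absolute-rho significance threshold via the t-approximation
#' `rho* = t* / sqrt(n - 2 + t*^2)`, where `t*` is the upper quantile of
#' Student's t with `n - 2` degrees of freedom at the requested alpha
#' (halved for two tails). Used to flag significant motif associations.
#'
#' @param n Number of paired observations (>= 4).
#' @param alpha Significance level in (0, 1).
#' @param tails `"one"` or `"two"`.
#' @return Critical absolute rho in `[0, 1)`.
#' @export
spearman_critical <- function(n, alpha = 0.05, tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (n < 4L) stop("spearman_critical: need n >= 4")
  if (alpha <= 0 || alpha >= 1) stop("spearman_critical: alpha must be in (0,1)")
  a <- if (tails == "two") alpha / 2 else alpha
  tstar <- stats::qt(1 - a, df = n - 2)
  tstar / sqrt(n - 2 + tstar^2)
}

#' Signed normalized contrast between genotype mean rates
#'
#' The volcano x-axis statistic: `x = (m - w) / (m + w)` where `m` and `w`
#' are the mutant and wild-type mean rates. It lies in `[-1, 1]` and
#' saturates at +1 when the event occurs in the mutant but never in the
#' wild type (the right-edge dots of the exon-usage volcano) and at -1 in
#' the mirror case. Scale-invariant: common rescaling of all rates leaves
#' it unchanged.
#'
#' @param mut_rates,wt_rates Non-negative per-sample rates.
#' @return The contrast, or `NA` when both group means are zero (the event
#'   carries no evidence and is dropped by callers).
#' @export
normalized_contrast <- function(mut_rates, wt_rates) {
  if (any(mut_rates < 0) || any(wt_rates < 0))
    stop("normalized_contrast: rates must be non-negative")
  m <- mean(mut_rates)
  w <- mean(wt_rates)
  if (m + w == 0) return(NA_real_)
  (m - w) / (m + w)
}
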