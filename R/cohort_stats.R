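# Demographic and neuropsychological group comparisons: pooled two-sample
# t-tests (from raw data or printed summaries) and the 2x2 chi-squared.

#' Pooled-variance two-sample t-test
#'
#' Student's t with pooled variance and `df = n_a + n_b - 2`, callable
#' either with group summaries (mean, SD, n) or with two raw vectors. The
#' statistic is for group a minus group b.
#'
#' @param mean_a,sd_a,n_a Summary statistics of group a, or (as
#'   `mean_a`/`mean_b`) two raw numeric vectors with the remaining
#'   arguments missing.
#' @param mean_b,sd_b,n_b Summary statistics of group b.
#' @return List: `t`, `df`, `p` (two-tailed).
#' @export
two_sample_t <- function(mean_a, sd_a = NULL, n_a = NULL,
                         mean_b = NULL, sd_b = NULL, n_b = NULL) {
  if (length(mean_a) > 1L) {                  # raw-vector form: (a, b)
    a <- mean_a
    b <- if (!is.null(sd_a)) sd_a else mean_b
    if (is.null(b) || length(b) < 2L)
      stop("data error: second sample missing or too short")
    if (length(a) < 2L || length(b) < 2L)
      stop("data error: each group needs at least 2 observations")
    return(two_sample_t(mean(a), stats::sd(a), length(a),
                        mean(b), stats::sd(b), length(b)))
  }
  if (n_a < 2 || n_b < 2) stop("data error: group sizes must be at least 2")
  if (sd_a < 0 || sd_b < 0) stop("data error: negative SD")
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  if (sp2 == 0) {
    if (mean_a == mean_b)
      stop("undefined-t error: both SDs zero with equal means")
    return(list(t = sign(mean_a - mean_b) * Inf, df = df, p = 0))
  }
  tstat <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-squared with
#' 1 degree of freedom on the table `rbind(c(a, b), c(c, d))`.
#'
#' @param a,b First row counts (e.g. men/women in group 1).
#' @param c,d Second row counts.
#' @return List: `chi2`, `df` (1), `p`.
#' @export
chi_squared_2x2 <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x)))
    stop("data error: counts must be nonnegative integers")
  tab <- matrix(x, 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("data error: zero margin in 2x2 table")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - E)^2 / E)
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1L, lower.tail = FALSE))
}

#' Demographic comparison table
#'
#' Per continuous phenotype column, group means (SD) and the pooled
#' two-sample t; for the binary `gender` column, counts and the
#' uncorrected chi-squared. Mirrors the usual clinical characteristics
#' table.
#'
#' @param phenotype Phenotype data frame with `group` (CN/SCD).
#' @param continuous Columns compared by t-test.
#' @param binary Columns compared by chi-squared (0/1 coded).
#' @return Data frame: variable, per-group summary, statistic, p.
#' @export
demographics_table <- function(phenotype,
                               continuous = c("age", "education", "itv", "fd_mean"),
                               binary = "gender") {
  cn <- phenotype[phenotype$group == "CN", , drop = FALSE]
  scd <- phenotype[phenotype$group == "SCD", , drop = FALSE]
  fmt <- function(x) sprintf("%.2f (%.2f)", mean(x), stats::sd(x))
  rows <- lapply(continuous, function(v) {
    tt <- two_sample_t(cn[[v]], scd[[v]])
    data.frame(variable = v, CN = fmt(cn[[v]]), SCD = fmt(scd[[v]]),
               statistic = tt$t, p = tt$p, stringsAsFactors = FALSE)
  })
  for (v in binary) {
    cs <- chi_squared_2x2(sum(cn[[v]] == 1), sum(cn[[v]] == 0),
                          sum(scd[[v]] == 1), sum(scd[[v]] == 0))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v,
      CN = sprintf("%d/%d", sum(cn[[v]] == 1), sum(cn[[v]] == 0)),
      SCD = sprintf("%d/%d", sum(scd[[v]] == 1), sum(scd[[v]] == 0)),
      statistic = cs$chi2, p = cs$p, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
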