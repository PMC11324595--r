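# Composite cognitive z-scores, covariate residualization, and bootstrap
# Pearson correlation between significant FC circuits and cognition.

#' Composite cognitive z-scores per domain
#'
#' Each raw test is z-scored against the pooled mean and SD of all included
#' participants (optionally against the CN group only); a domain's
#' composite is the mean of its tests' z-scores.
#'
#' @param scores Data frame of raw test scores (one column per test).
#' @param manifest Named list: domain -> character vector of test columns.
#' @param norms `"pooled"` (default) or `"cn"`; the latter standardizes
#'   against control-group means/SDs and needs `group`.
#' @param group Factor CN/SCD, required for `norms = "cn"`.
#' @return Data frame of composite z-scores, one column per domain.
#' @export
compute_composites <- function(scores, manifest, norms = c("pooled", "cn"),
                               group = NULL) {
  norms <- match.arg(norms)
  if (norms == "cn" && is.null(group))
    stop("data error: norms = 'cn' requires the group factor")
  tests <- unlist(manifest)
  miss <- setdiff(tests, colnames(scores))
  if (length(miss)) stop("data error: missing test column(s): ",
                         paste(miss, collapse = ", "))
  if (anyNA(scores[, tests])) stop("data error: missing raw scores")
  ref <- if (norms == "pooled") seq_len(nrow(scores)) else which(group == "CN")
  zcol <- function(test) {
    x <- scores[[test]]
    s <- stats::sd(x[ref])
    if (!is.finite(s) || s == 0)
      stop("degenerate-test error: zero variance in test '", test, "'")
    (x - mean(x[ref])) / s
  }
  out <- lapply(manifest, function(ts) rowMeans(vapply(ts, zcol,
                                                       numeric(nrow(scores)))))
  as.data.frame(out)
}

#' Residualize values on covariates
#'
#' Least-squares residuals of `values` on intercept + covariates. The
#' residuals are orthogonal to every covariate and have mean zero.
#'
#' @param values Numeric vector, one value per subject.
#' @param covariates Data frame or matrix of covariates (default covariate
#'   set for brain-behavior correlation: age, gender as 0/1, education).
#' @return Numeric residual vector.
#' @export
residualize <- function(values, covariates) {
  X <- cbind(intercept = 1, as.matrix(covariates))
  if (any(!is.finite(X))) stop("data error: non-finite covariates")
  n <- length(values)
  if (nrow(X) != n) stop("data error: covariate rows do not match values")
  if (n <= ncol(X)) stop("data error: need n > covariate count + 1")
  qrx <- check_full_rank(X, "residualization design")
  as.numeric(qr.resid(qrx, values))
}

#' Pearson correlation with bootstrap confidence interval
#'
#' Pearson r and its two-tailed p on the original pairs, plus a percentile
#' confidence interval from `n_boot` resamples of subject pairs.
#' Reproducible from `seed`.
#'
#' @param x,y Paired numeric vectors, length at least 5.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param conf Confidence level of the percentile interval.
#' @return List of class `corr_boot`: `r`, `p`, `ci` (lower, upper),
#'   `n_boot`, `seed`, `n`.
#' @export
corr_bootstrap <- function(x, y, n_boot = 10000, seed = 1L, conf = 0.95) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 5L) stop("data error: need at least 5 pairs")
  if (anyNA(x) || anyNA(y)) stop("data error: missing values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate-correlation error: constant input vector")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), n - 2)
  }
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) return(NA_real_)
    stats::cor(x[idx], y[idx])
  }, numeric(1))
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  structure(list(r = r, p = p, ci = qs, n_boot = n_boot, seed = seed, n = n),
            class = "corr_boot")
}

#' @export
print.corr_boot <- function(x, ...) {
  cat(sprintf("r = %.3f, p = %.3g, %d-rep bootstrap CI [%.3f, %.3f] (n = %d)\n",
              x$r, x$p, x$n_boot, x$ci[1], x$ci[2], x$n))
  invisible(x)
}

#' Screen significant circuits against cognitive domains
#'
#' For every FDR-significant ROI pair ("circuit") and every cognitive
#' domain, residualizes both the per-subject circuit Fisher-z FC and the
#' domain composite on age, gender and education within the selected group
#' (patients by default), then correlates with a bootstrap CI. Raw p-values
#' are reported (the screen is exploratory); a BH-adjusted column is
#' appended for reference.
#'
#' @param roifc A `roi_fc_result` from [roi_group_fc_test].
#' @param composites Data frame of domain composites (all subjects).
#' @param phenotype Phenotype data frame with `group`, `age`, `gender`,
#'   `education`.
#' @param group_filter Group whose subjects enter the correlation
#'   (`"SCD"` default, `"CN"`, or `"all"`).
#' @param covariates Columns residualized out of both sides.
#' @param n_boot,seed,conf Bootstrap settings (see [corr_bootstrap]).
#' @return Data frame: circuit, domain, r, p, ci_lower, ci_upper, n,
#'   n_boot, p_bh.
#' @export
circuit_cognition_screen <- function(roifc, composites, phenotype,
                                     group_filter = "SCD",
                                     covariates = c("age", "gender", "education"),
                                     n_boot = 10000, seed = 1L, conf = 0.95) {
  stopifnot(inherits(roifc, "roi_fc_result"))
  sig <- which(roifc$significant)
  if (length(sig) == 0L) stop("data error: no significant circuits to screen")
  sel <- if (identical(group_filter, "all")) seq_len(nrow(phenotype))
         else which(phenotype$group == group_filter)
  if (length(sel) == 0L) stop("data error: empty ", group_filter, " subset")
  Z <- attr(roifc, "z")
  covs <- phenotype[sel, covariates, drop = FALSE]
  rows <- list()
  for (ci in sig) {
    fc_res <- residualize(Z[sel, ci], covs)
    for (d in colnames(composites)) {
      cg_res <- residualize(composites[sel, d], covs)
      cb <- corr_bootstrap(fc_res, cg_res, n_boot = n_boot,
                           seed = seed + length(rows), conf = conf)
      rows[[length(rows) + 1L]] <- data.frame(
        circuit = paste(roifc$roi_a[ci], roifc$roi_b[ci], sep = "--"),
        domain = d, r = cb$r, p = cb$p,
        ci_lower = cb$ci[1], ci_upper = cb$ci[2],
        n = cb$n, n_boot = n_boot, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- bh_fdr(out$p)
  out
}
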