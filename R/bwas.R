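# Brain-wide association core: all-pairs voxel FC, covariate-adjusted
# link-level group tests with Bonferroni FWE control, the per-voxel
# Measure-of-Association (MA) statistic and MA-thresholded clusters.

#' Size of the link-wise test family
#'
#' Number of voxel-pair links used for multiple-comparison correction.
#' `"n2_half"` is the printed reporting convention `floor(n^2 / 2)`
#' (23,178 voxels give 268,609,842 links); `"choose2"` is the exact
#' unordered pair count `n (n - 1) / 2`. The enumerated test set is always
#' the `i < j` pairs; the `n^2/2` convention is therefore conservative by a
#' factor of about two.
#'
#' @param n_voxels Positive integer voxel count.
#' @param convention `"n2_half"` (default) or `"choose2"`.
#' @return Family size as a double (may exceed integer range).
#' @export
count_links <- function(n_voxels, convention = c("n2_half", "choose2")) {
  convention <- match.arg(convention)
  if (length(n_voxels) != 1L || !is.finite(n_voxels) || n_voxels < 1 ||
      n_voxels != round(n_voxels))
    stop("configuration error: n_voxels must be a positive integer")
  n <- as.double(n_voxels)
  switch(convention,
         n2_half = floor(n * n / 2),
         choose2 = n * (n - 1) / 2)
}

# i<j pair enumeration in upper.tri column-major order:
# (1,2),(1,3),(2,3),(1,4),...
link_pairs <- function(n_voxels) {
  j <- rep.int(seq_len(n_voxels), seq_len(n_voxels) - 1L)
  i <- sequence(seq_len(n_voxels) - 1L)
  cbind(i = i, j = j)
}

#' Per-subject link-wise Fisher-z functional connectivity
#'
#' For every subject, Pearson correlation between every pair of voxel time
#' series (i < j) followed by the Fisher z-transformation
#' `z = atanh(r)`.
#'
#' @param cohort A [voxel_cohort]; every voxel series must have nonzero
#'   variance and at least 3 timepoints.
#' @return Object of class `link_fc`: list with `z`
#'   (`n_subjects x n_links` matrix), `pairs` (`n_links x 2` voxel index
#'   matrix, i < j), and grid metadata carried from the cohort.
#' @export
voxel_fc_fisher <- function(cohort) {
  stopifnot(inherits(cohort, "voxel_cohort"))
  if (n_timepoints(cohort) < 3L) stop("data error: need at least 3 timepoints")
  nv <- n_voxels(cohort)
  pairs <- link_pairs(nv)
  ut <- upper.tri(matrix(0, nv, nv))
  z <- matrix(NA_real_, length(cohort$data), nrow(pairs))
  for (s in seq_along(cohort$data)) {
    Y <- cohort$data[[s]]
    sds <- apply(Y, 1L, stats::sd)
    if (any(sds == 0))
      stop("degenerate-voxel error: zero-variance voxel(s) for subject ",
           cohort$subject_ids[s], ": ",
           paste(utils::head(which(sds == 0), 10L), collapse = ", "))
    r <- stats::cor(t(Y))[ut]
    if (any(abs(r) >= 1))
      stop("saturation error: |r| = 1 for subject ", cohort$subject_ids[s],
           "; Fisher z is undefined")
    z[s, ] <- atanh(r)
  }
  structure(list(z = z, pairs = pairs, subject_ids = cohort$subject_ids,
                 n_voxels = nv, grid_shape = cohort$grid_shape,
                 mask_index = cohort$mask_index, affine = cohort$affine),
            class = "link_fc")
}

#' Bonferroni per-link p-value cutoff
#'
#' The family-wise error control is Bonferroni over the link family:
#' a link is significant iff its uncorrected p is below `alpha / n_links`
#' (equivalently, corrected p `min(1, p * n_links) < alpha`).
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param n_links Positive family size (see [count_links]).
#' @return Uncorrected per-link p cutoff.
#' @export
fwe_threshold <- function(alpha, n_links) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("configuration error: alpha must lie in (0, 1)")
  if (!is.finite(n_links) || n_links < 1)
    stop("configuration error: n_links must be positive")
  alpha / n_links
}

# vectorized covariate-adjusted group GLM over many response columns.
# X: n x p with the group column second. Returns t, p, df for the group
# coefficient of every response.
group_glm <- function(X, Z) {
  qrx <- check_full_rank(X, "group-test design")
  n <- nrow(X); p <- ncol(X)
  beta <- qr.coef(qrx, Z)
  res <- qr.resid(qrx, Z)
  rss <- colSums(res^2)
  df <- n - p
  sigma2 <- rss / df
  cgg <- chol2inv(qr.R(qrx))
  # chol2inv of R gives (X'X)^-1 in pivoted order; map back
  unpivot <- order(qrx$pivot)
  cgg <- cgg[unpivot, unpivot, drop = FALSE][2L, 2L]
  tstat <- beta[2L, ] / sqrt(sigma2 * cgg)
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df), df = df)
}

#' Link-level covariate-adjusted group test
#'
#' For every voxel-pair link, tests the group difference of Fisher-z FC.
#' The default is a per-link GLM `z ~ intercept + group + covariates`
#' (group coded CN = 0, SCD = 1, so negative t means weaker FC in SCD);
#' the two-tailed t and p for the group coefficient are reported with
#' `df = n - p`. With an empty covariate list this equals the
#' pooled-variance two-sample t-test. The `"residualize"` variant first
#' residualizes z on the covariates and then applies a plain two-sample
#' t-test (`df = n - 2`).
#'
#' @param fc A `link_fc` from [voxel_fc_fisher].
#' @param phenotype Data frame with a `group` factor (levels CN, SCD) and
#'   the covariate columns, rows aligned with `fc` subjects.
#' @param covariates Character vector of phenotype columns to adjust for.
#' @param method `"glm"` (default) or `"residualize"`.
#' @param alpha Family-wise significance level.
#' @param convention Link-family convention passed to [count_links].
#' @param retain_p Only links with p below this cutoff are materialized in
#'   the returned table; the family size is kept regardless. Default is 1
#'   (retain everything; fine at toy scale). Must be at least the
#'   Bonferroni cutoff or downstream MA counting would undercount.
#' @return Object of class `link_test_table`: data frame `(i, j, t, p)`
#'   with attributes `n_links` (family size), `n_tests` (enumerated i<j
#'   pairs), `alpha`, `cutoff`, `retain_p`, `df`, `n_voxels` and grid
#'   metadata.
#' @export
link_group_test <- function(fc, phenotype,
                            covariates = c("age", "education", "fd_mean", "itv"),
                            method = c("glm", "residualize"),
                            alpha = 3.33e-2,
                            convention = "n2_half",
                            retain_p = 1) {
  stopifnot(inherits(fc, "link_fc"))
  method <- match.arg(method)
  if (nrow(phenotype) != nrow(fc$z))
    stop("data error: phenotype rows do not match cohort subjects")
  grp <- phenotype$group
  if (!all(levels(factor(grp)) %in% c("CN", "SCD")))
    stop("data error: group must be CN/SCD")
  g <- as.integer(grp == "SCD")
  if (sum(g == 0) < 2 || sum(g == 1) < 2)
    stop("data error: each group needs at least 2 subjects")
  miss <- setdiff(covariates, colnames(phenotype))
  if (length(miss)) stop("data error: missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  C <- if (length(covariates))
    as.matrix(phenotype[, covariates, drop = FALSE]) else NULL
  if (!is.null(C) && any(!is.finite(C)))
    stop("data error: non-finite covariate values")
  n <- length(g)
  if (sum(g == 0) < length(covariates) + 2 || sum(g == 1) < length(covariates) + 2)
    stop("data error: groups too small for the covariate count")

  if (method == "glm") {
    X <- cbind(intercept = 1, group = g, C)
    fit <- group_glm(X, fc$z)
  } else {
    Xc <- cbind(intercept = 1, C)
    qrc <- check_full_rank(Xc, "covariate design")
    Zr <- qr.resid(qrc, fc$z)
    gr <- split(seq_len(n), g)
    fit <- two_sample_t_matrix(Zr[gr[["1"]], , drop = FALSE],
                               Zr[gr[["0"]], , drop = FALSE])
  }

  n_links <- count_links(fc$n_voxels, convention)
  cutoff <- fwe_threshold(alpha, n_links)
  if (retain_p < cutoff)
    stop("configuration error: retain_p below the FWE cutoff would ",
         "undercount MA")
  keep <- which(fit$p <= retain_p)
  out <- data.frame(i = fc$pairs[keep, 1L], j = fc$pairs[keep, 2L],
                    t = fit$t[keep], p = fit$p[keep])
  structure(out, class = c("link_test_table", "data.frame"),
            n_links = n_links, n_tests = nrow(fc$pairs),
            alpha = alpha, cutoff = cutoff, retain_p = retain_p,
            df = fit$df, n_voxels = fc$n_voxels,
            grid_shape = fc$grid_shape, mask_index = fc$mask_index,
            affine = fc$affine)
}

# pooled two-sample t across matrix columns (group a minus group b)
two_sample_t_matrix <- function(A, B) {
  na <- nrow(A); nb <- nrow(B)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- colSums(sweep(A, 2L, ma)^2)
  vb <- colSums(sweep(B, 2L, mb)^2)
  df <- na + nb - 2L
  sp2 <- (va + vb) / df
  tstat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df), df = df)
}

#' Per-voxel Measure of Association
#'
#' `MA(i)` counts the links incident to voxel i whose group-difference
#' p-value falls below the Bonferroni FWE cutoff `alpha / n_links`. The sum
#' of MA over voxels is exactly twice the significant-link count.
#'
#' @param links A `link_test_table` from [link_group_test].
#' @param alpha,n_links Override the significance level / family size
#'   stored in `links` (defaults: the stored values).
#' @return Object of class `ma_map`: list with `ma` (integer per voxel in
#'   mask order), `alpha`, `cutoff`, `n_sig_links`, and grid metadata.
#' @export
compute_ma <- function(links, alpha = attr(links, "alpha"),
                       n_links = attr(links, "n_links")) {
  stopifnot(inherits(links, "link_test_table"))
  cutoff <- fwe_threshold(alpha, n_links)
  if (attr(links, "retain_p") < cutoff)
    stop("undercount error: links were retained at a cutoff below the FWE ",
         "threshold; recompute with a larger retain_p")
  nv <- attr(links, "n_voxels")
  sig <- links$p < cutoff
  ma <- tabulate(c(links$i[sig], links$j[sig]), nbins = nv)
  stopifnot(sum(ma) == 2 * sum(sig))
  structure(list(ma = as.integer(ma), alpha = alpha, cutoff = cutoff,
                 n_sig_links = sum(sig),
                 sig_links = links[sig, , drop = FALSE],
                 grid_shape = attr(links, "grid_shape"),
                 mask_index = attr(links, "mask_index"),
                 affine = attr(links, "affine")),
            class = "ma_map")
}

#' @export
print.ma_map <- function(x, ...) {
  cat(sprintf("ma_map: %d voxels, %d significant links (alpha %.3g, cutoff %.3g), max MA %d\n",
              length(x$ma), x$n_sig_links, x$alpha, x$cutoff, max(x$ma)))
  invisible(x)
}

# neighbor offsets for 6- or 26-connectivity
neighbor_offsets <- function(connectivity) {
  if (connectivity == 6) {
    rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else if (connectivity == 26) {
    o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    o[rowSums(o == 0) != 3L, , drop = FALSE]
  } else stop("configuration error: connectivity must be 6 or 26")
}

# connected components of a voxel set (mask rows) on the 3D grid
connected_components <- function(rows, grid_shape, mask_index, connectivity) {
  if (length(rows) == 0L) return(list())
  lin <- mask_index[rows]
  coords <- linear_to_coords(lin, grid_shape)
  lookup <- integer(prod(grid_shape))       # linear index -> position in rows
  lookup[lin] <- seq_along(rows)
  offs <- neighbor_offsets(connectivity)
  comp <- integer(length(rows))
  ncomp <- 0L
  for (start in seq_along(rows)) {
    if (comp[start] != 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    comp[start] <- ncomp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cc <- coords[cur, ]
      nb <- sweep(offs, 2L, cc, "+")
      ok <- nb[, 1] >= 0 & nb[, 1] < grid_shape[1] &
            nb[, 2] >= 0 & nb[, 2] < grid_shape[2] &
            nb[, 3] >= 0 & nb[, 3] < grid_shape[3]
      if (!any(ok)) next
      pos <- lookup[coords_to_linear(nb[ok, , drop = FALSE], grid_shape)]
      pos <- pos[pos != 0L]
      new <- pos[comp[pos] == 0L]
      comp[new] <- ncomp
      queue <- c(queue, new)
    }
  }
  split(rows, comp)
}

#' Extract MA-thresholded clusters
#'
#' Binarizes the MA map at `ma > ma_min` (strict), finds connected
#' components on the voxel grid, and keeps components of at least
#' `min_cluster_voxels` voxels. The defaults are the full-scale thresholds
#' (MA > 40, cluster >= 20 voxels); at toy scale pass scaled values.
#'
#' @param ma An `ma_map`.
#' @param ma_min Strict MA threshold.
#' @param min_cluster_voxels Minimum component size kept.
#' @param connectivity 26 (default) or 6.
#' @return Object of class `cluster_set`: list of clusters, each with
#'   `rows` (mask-row indices), `coords` (0-based), `size`, `peak_row`,
#'   `peak_ma`, `peak_world`; plus attributes `thresholded_rows` (all
#'   voxels with MA above threshold, before the size filter) and the
#'   thresholds used. Peak ties resolve to the lowest linear index.
#' @export
extract_clusters <- function(ma, ma_min = 40, min_cluster_voxels = 20,
                             connectivity = 26) {
  stopifnot(inherits(ma, "ma_map"))
  if (ma_min < 0 || min_cluster_voxels < 0)
    stop("configuration error: thresholds must be nonnegative")
  rows <- which(ma$ma > ma_min)
  comps <- connected_components(rows, ma$grid_shape, ma$mask_index, connectivity)
  comps <- Filter(function(rs) length(rs) >= min_cluster_voxels, comps)
  clusters <- lapply(comps, function(rs) {
    rs <- sort(rs)
    vals <- ma$ma[rs]
    peak <- rs[which.max(vals)]     # which.max -> first max -> lowest index
    coords <- linear_to_coords(ma$mask_index[rs], ma$grid_shape)
    list(rows = rs, coords = coords, size = length(rs),
         peak_row = peak, peak_ma = ma$ma[peak],
         peak_world = drop(voxel_to_world(
           linear_to_coords(ma$mask_index[peak], ma$grid_shape), ma$affine)))
  })
  names(clusters) <- if (length(clusters)) paste0("cluster", seq_along(clusters))
  structure(clusters, class = "cluster_set",
            thresholded_rows = rows, ma_min = ma_min,
            min_cluster_voxels = min_cluster_voxels,
            connectivity = connectivity)
}

#' Voxels inside extracted clusters
#' @param clusters A `cluster_set`.
#' @return Sorted mask-row indices of all cluster member voxels.
#' @export
cluster_voxels <- function(clusters) {
  sort(unique(unlist(lapply(clusters, `[[`, "rows"))))
}

#' Run the link-level BWAS stack
#'
#' Convenience wrapper: [voxel_fc_fisher] -> [link_group_test] ->
#' [compute_ma] -> [extract_clusters].
#'
#' @param cohort A [voxel_cohort].
#' @param phenotype Phenotype data frame (see [link_group_test]).
#' @param covariates Covariate columns regressed out in the link tests.
#' @param alpha Family-wise significance level.
#' @param ma_min,min_cluster_voxels,connectivity Cluster extraction
#'   settings (see [extract_clusters]).
#' @param convention Link-family convention.
#' @param method Group-test variant.
#' @return List with `fc`, `links`, `ma`, `clusters`.
#' @export
bwas_run <- function(cohort, phenotype,
                     covariates = c("age", "education", "fd_mean", "itv"),
                     alpha = 3.33e-2, ma_min = 40, min_cluster_voxels = 20,
                     connectivity = 26, convention = "n2_half",
                     method = "glm") {
  fc <- voxel_fc_fisher(cohort)
  links <- link_group_test(fc, phenotype, covariates = covariates,
                           method = method, alpha = alpha,
                           convention = convention)
  ma <- compute_ma(links)
  clusters <- extract_clusters(ma, ma_min = ma_min,
                               min_cluster_voxels = min_cluster_voxels,
                               connectivity = connectivity)
  list(fc = fc, links = links, ma = ma, clusters = clusters)
}
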