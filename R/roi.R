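# Atlas-anchored ROI derivation from MA-significant voxels and ROI-wise
# functional connectivity group testing with BH-FDR control.

#' Define atlas-anchored ROIs from significant voxels
#'
#' Groups MA-significant voxels by atlas label and keeps regions holding at
#' least `min_voxels` of them. ROI membership is the significant voxels
#' only, not the whole atlas region. Per region the peak-MA voxel (ties:
#' lowest linear index) and its world coordinate are recorded, mirroring
#' the usual region / voxel-count / peak-MA / peak-coordinate report.
#'
#' @param sig_rows Mask-row indices of significant voxels, e.g.
#'   [cluster_voxels] of an extracted [extract_clusters] result.
#' @param ma The `ma_map` the voxels came from.
#' @param atlas 3D integer label array on the cohort grid (0 = unlabeled).
#' @param label_table Data frame with columns `id`, `name`.
#' @param min_voxels Minimum significant-voxel count for a region to become
#'   an ROI.
#' @return Object of class `roi_set`: named list of ROIs, each with
#'   `region_id`, `region_name`, `rows`, `n_voxels`, `peak_row`, `peak_ma`,
#'   `peak_world`.
#' @export
define_rois <- function(sig_rows, ma, atlas, label_table, min_voxels = 20) {
  stopifnot(inherits(ma, "ma_map"))
  if (!identical(as.integer(dim(atlas)), as.integer(ma$grid_shape)))
    stop("alignment error: atlas shape ", paste(dim(atlas), collapse = "x"),
         " does not match grid ", paste(ma$grid_shape, collapse = "x"))
  sig_rows <- sort(unique(as.integer(sig_rows)))
  if (length(sig_rows) == 0L)
    return(structure(list(), class = "roi_set"))
  lab <- atlas[ma$mask_index[sig_rows]]
  keep <- lab > 0L
  by_region <- split(sig_rows[keep], lab[keep])
  by_region <- Filter(function(rs) length(rs) >= min_voxels, by_region)
  rois <- lapply(names(by_region), function(id_chr) {
    rs <- sort(by_region[[id_chr]])
    id <- as.integer(id_chr)
    peak <- rs[which.max(ma$ma[rs])]
    nm <- label_table$name[match(id, label_table$id)]
    list(region_id = id, region_name = if (is.na(nm)) paste0("region_", id) else nm,
         rows = rs, n_voxels = length(rs),
         peak_row = peak, peak_ma = ma$ma[peak],
         peak_world = drop(voxel_to_world(
           linear_to_coords(ma$mask_index[peak], ma$grid_shape), ma$affine)))
  })
  names(rois) <- vapply(rois, `[[`, character(1), "region_name")
  structure(rois, class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("roi_set: %d ROIs\n", length(x)))
  for (r in x)
    cat(sprintf("  %s (region %d): %d voxels, peak MA %d at (%s)\n",
                r$region_name, r$region_id, r$n_voxels, r$peak_ma,
                paste(round(r$peak_world, 1), collapse = ", ")))
  invisible(x)
}

#' ROI table in report form
#'
#' @param rois A `roi_set`.
#' @return Data frame: region id, name, voxel count, peak MA, peak world
#'   coordinates.
#' @export
roi_table <- function(rois) {
  if (length(rois) == 0L)
    return(data.frame(region_id = integer(), region = character(),
                      n_voxels = integer(), peak_ma = integer(),
                      peak_x = numeric(), peak_y = numeric(), peak_z = numeric()))
  do.call(rbind, lapply(unname(rois), function(r)
    data.frame(region_id = r$region_id, region = r$region_name,
               n_voxels = r$n_voxels, peak_ma = r$peak_ma,
               peak_x = r$peak_world[1], peak_y = r$peak_world[2],
               peak_z = r$peak_world[3])))
}

#' Mean BOLD series of an ROI
#'
#' Unweighted mean across the ROI's member voxels at each timepoint.
#'
#' @param series `n_voxels x T` subject matrix in cohort voxel order.
#' @param rows Mask-row indices of the ROI's member voxels.
#' @return Length-T numeric vector.
#' @export
roi_timeseries <- function(series, rows) {
  rows <- as.integer(rows)
  if (length(rows) == 0L) stop("data error: empty ROI")
  if (any(rows < 1L | rows > nrow(series)))
    stop("data error: ROI voxel outside the cohort grid")
  colMeans(series[rows, , drop = FALSE])
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment: sorted ascending p-values are
#' scaled by `n / rank` and a running minimum from the largest p down
#' enforces monotonicity; values are capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("data error: p-values must lie in [0, 1]")
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(n / seq(n, 1) * p[o]))
  adj[order(o)]
}

#' ROI-pair functional connectivity group test
#'
#' Per subject, Pearson correlation between every pair of ROI mean time
#' series, Fisher z-transformed; per pair, the same covariate-adjusted
#' group GLM as [link_group_test]; Benjamini-Hochberg FDR across all pairs
#' with significance at adjusted p below `q`.
#'
#' @param cohort A [voxel_cohort].
#' @param rois A `roi_set` with at least 2 ROIs.
#' @param phenotype Phenotype data frame (group CN/SCD + covariates).
#' @param covariates Covariate columns regressed out.
#' @param q FDR threshold.
#' @param method `"glm"` or `"residualize"` (see [link_group_test]).
#' @return Object of class `roi_fc_result`: data frame with `roi_a`,
#'   `roi_b`, `t`, `p`, `p_adj`, `significant`; attribute `z` holds the
#'   per-subject `n_subjects x n_pairs` Fisher-z matrix.
#' @export
roi_group_fc_test <- function(cohort, rois, phenotype,
                              covariates = c("age", "education", "fd_mean", "itv"),
                              q = 0.05, method = c("glm", "residualize")) {
  method <- match.arg(method)
  if (length(rois) < 2L) stop("data error: need at least 2 ROIs")
  if (!is.finite(q) || q <= 0 || q >= 1)
    stop("configuration error: q must lie in (0, 1)")
  T <- n_timepoints(cohort)
  n_sub <- length(cohort$data)
  if (nrow(phenotype) != n_sub)
    stop("data error: phenotype rows do not match cohort subjects")
  K <- length(rois)
  pairs <- link_pairs(K)
  ut <- upper.tri(matrix(0, K, K))
  z <- matrix(NA_real_, n_sub, nrow(pairs))
  for (s in seq_len(n_sub)) {
    M <- vapply(rois, function(r) roi_timeseries(cohort$data[[s]], r$rows),
                numeric(T))
    r <- stats::cor(M)[ut]
    if (any(abs(r) >= 1))
      stop("saturation error: |r| = 1 between ROI series for subject ",
           cohort$subject_ids[s])
    z[s, ] <- atanh(r)
  }

  g <- as.integer(phenotype$group == "SCD")
  C <- if (length(covariates))
    as.matrix(phenotype[, covariates, drop = FALSE]) else NULL
  if (method == "glm") {
    fit <- group_glm(cbind(intercept = 1, group = g, C), z)
  } else {
    qrc <- check_full_rank(cbind(intercept = 1, C), "covariate design")
    Zr <- qr.resid(qrc, z)
    fit <- two_sample_t_matrix(Zr[g == 1, , drop = FALSE],
                               Zr[g == 0, , drop = FALSE])
  }
  p_adj <- bh_fdr(fit$p)
  nm <- names(rois)
  out <- data.frame(roi_a = nm[pairs[, 1L]], roi_b = nm[pairs[, 2L]],
                    t = fit$t, p = fit$p, p_adj = p_adj,
                    significant = p_adj < q,
                    stringsAsFactors = FALSE)
  structure(out, class = c("roi_fc_result", "data.frame"),
            z = z, q = q, df = fit$df, roi_names = nm, pairs = pairs)
}
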