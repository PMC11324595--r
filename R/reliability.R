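# Time-domain half-split robustness: recompute MA on each half of the
# scan, quantify agreement, and cross-validate ROI-wise FC across halves.

#' Split a cohort into temporal halves
#'
#' First `floor(T/2)` timepoints versus the remainder; both halves share
#' the voxel grid and subject ordering.
#'
#' @param cohort A [voxel_cohort] with at least 4 timepoints.
#' @return List with cohorts `a` and `b`.
#' @export
split_halves <- function(cohort) {
  T <- n_timepoints(cohort)
  if (T < 4L) stop("data error: need at least 4 timepoints to split")
  h <- T %/% 2L
  list(a = subset_timepoints(cohort, seq_len(h)),
       b = subset_timepoints(cohort, (h + 1L):T))
}

#' Dice coefficient of two index sets
#'
#' `2 |A  intersect B| / (|A| + |B|)`; `NA` when both sets are empty (the
#' overlap of two empty significant-voxel maps is undefined, not perfect).
#'
#' @param a,b Integer vectors (voxel row indices).
#' @return Dice coefficient in `[0, 1]`, or `NA`.
#' @export
dice_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) + length(b) == 0L) return(NA_real_)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Half-split MA reliability
#'
#' Runs the full link-level BWAS stack independently on the first and
#' second temporal halves and quantifies agreement: Dice coefficient
#' between the two MA-thresholded significant-voxel sets and Spearman rank
#' correlation between the two MA maps over the union of nonzero voxels.
#'
#' @param cohort A [voxel_cohort].
#' @param phenotype Phenotype data frame.
#' @param ... BWAS settings forwarded to [bwas_run] (covariates, alpha,
#'   ma_min, min_cluster_voxels, ...).
#' @return List with `half_a`, `half_b` (each a [bwas_run] result),
#'   `dice` (on MA > ma_min voxel sets), `spearman` (MA rank agreement,
#'   `NA` if the union is empty), `n_sig_a`, `n_sig_b`.
#' @export
half_split_ma <- function(cohort, phenotype, ...) {
  halves <- split_halves(cohort)
  res_a <- bwas_run(halves$a, phenotype, ...)
  res_b <- bwas_run(halves$b, phenotype, ...)
  vox_a <- attr(res_a$clusters, "thresholded_rows")
  vox_b <- attr(res_b$clusters, "thresholded_rows")
  union_vox <- union(which(res_a$ma$ma > 0), which(res_b$ma$ma > 0))
  ma_a <- res_a$ma$ma[union_vox]; ma_b <- res_b$ma$ma[union_vox]
  spearman <- if (length(union_vox) < 2) NA_real_
    else if (identical(ma_a, ma_b)) 1
    else if (stats::sd(ma_a) == 0 || stats::sd(ma_b) == 0) NA_real_
    else stats::cor(ma_a, ma_b, method = "spearman")
  list(half_a = res_a, half_b = res_b,
       dice = dice_coefficient(vox_a, vox_b), spearman = spearman,
       n_sig_a = length(vox_a), n_sig_b = length(vox_b))
}

#' Cross-validate ROI-wise FC across halves
#'
#' Applies the ROI-pair group test to one half's data using ROIs defined on
#' the other half, and reports which circuits replicate at FDR level `q`.
#'
#' @param rois_a ROI set defined on the training half.
#' @param cohort_b The held-out half cohort.
#' @param phenotype Phenotype data frame.
#' @param covariates Covariates for the group test.
#' @param q FDR threshold.
#' @param ... Forwarded to [roi_group_fc_test].
#' @return List with `result` (a `roi_fc_result` on the held-out half) and
#'   `replicated` (character vector of significant circuit labels).
#' @export
cross_validate_fc <- function(rois_a, cohort_b, phenotype,
                              covariates = c("age", "education", "fd_mean", "itv"),
                              q = 0.05, ...) {
  if (length(rois_a) == 0L) stop("data error: empty ROI set")
  res <- roi_group_fc_test(cohort_b, rois_a, phenotype,
                           covariates = covariates, q = q, ...)
  list(result = res,
       replicated = paste(res$roi_a[res$significant],
                          res$roi_b[res$significant], sep = "--"))
}

#' Symmetric half-split reliability report
#'
#' Runs [half_split_ma], defines ROIs on each half, and cross-validates
#' each half's ROIs on the other half (A to B and B to A).
#'
#' @param cohort,phenotype Cohort and phenotype.
#' @param atlas,label_table Atlas volume and label table for ROI
#'   definition.
#' @param roi_min_voxels Minimum significant voxels per region.
#' @param q FDR threshold for replication.
#' @param ... BWAS settings forwarded to [bwas_run].
#' @return List: `ma` (the [half_split_ma] report), `rois_a`, `rois_b`,
#'   `a_to_b`, `b_to_a` (cross-validation results or NULL when a half has
#'   fewer than 2 ROIs).
#' @export
reliability_report <- function(cohort, phenotype, atlas, label_table,
                               roi_min_voxels = 20, q = 0.05, ...) {
  hs <- half_split_ma(cohort, phenotype, ...)
  halves <- split_halves(cohort)
  rois_a <- define_rois(cluster_voxels(hs$half_a$clusters), hs$half_a$ma,
                        atlas, label_table, min_voxels = roi_min_voxels)
  rois_b <- define_rois(cluster_voxels(hs$half_b$clusters), hs$half_b$ma,
                        atlas, label_table, min_voxels = roi_min_voxels)
  xv <- function(rois, half) {
    if (length(rois) < 2L) return(NULL)
    cross_validate_fc(rois, half, phenotype, q = q)
  }
  list(ma = hs, rois_a = rois_a, rois_b = rois_b,
       a_to_b = xv(rois_a, halves$b), b_to_a = xv(rois_b, halves$a))
}
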