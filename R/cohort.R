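# VoxelCohort: per-subject voxel-by-time matrices under a shared mask/grid.

#' Construct a voxel cohort
#'
#' Bundles per-subject voxel-by-time matrices that share a voxel grid, mask
#' and voxel ordering. Voxel ordering is ascending linear index (first grid
#' axis fastest), which keeps voxel indices stable across subjects.
#'
#' @param data List of numeric matrices, one per subject, each
#'   `n_voxels x n_timepoints` with identical row ordering.
#' @param subject_ids Character vector of subject identifiers.
#' @param grid_shape Integer vector of length 3, the full voxel grid.
#' @param mask_index 1-based linear indices of in-mask voxels into the grid,
#'   strictly increasing; one per matrix row.
#' @param affine 4x4 voxel-to-world matrix over 0-based voxel indices.
#' @param tr Repetition time in seconds.
#' @return An object of class `voxel_cohort`.
#' @export
voxel_cohort <- function(data, subject_ids, grid_shape, mask_index,
                         affine = diag(c(4, 4, 4, 1)), tr = 2) {
  stopifnot(is.list(data), length(data) == length(subject_ids),
            length(grid_shape) == 3L)
  mask_index <- as.integer(mask_index)
  if (is.unsorted(mask_index, strictly = TRUE))
    stop("mask_index must be strictly increasing")
  if (max(mask_index) > prod(grid_shape))
    stop("mask_index exceeds grid volume")
  nv <- length(mask_index)
  nt <- ncol(data[[1L]])
  for (s in seq_along(data)) {
    if (nrow(data[[s]]) != nv || ncol(data[[s]]) != nt)
      stop("subject ", subject_ids[s], ": matrix shape differs from cohort")
  }
  structure(list(data = data, subject_ids = as.character(subject_ids),
                 grid_shape = as.integer(grid_shape),
                 mask_index = mask_index, affine = affine, tr = tr),
            class = "voxel_cohort")
}

#' @export
print.voxel_cohort <- function(x, ...) {
  cat(sprintf("voxel_cohort: %d subjects, %d voxels, %d timepoints, grid %s\n",
              length(x$data), n_voxels(x), n_timepoints(x),
              paste(x$grid_shape, collapse = "x")))
  invisible(x)
}

#' Number of in-mask voxels in a cohort
#' @param cohort A `voxel_cohort`.
#' @return Integer voxel count.
#' @export
n_voxels <- function(cohort) length(cohort$mask_index)

#' Number of timepoints in a cohort
#' @param cohort A `voxel_cohort`.
#' @return Integer timepoint count.
#' @export
n_timepoints <- function(cohort) ncol(cohort$data[[1L]])

#' 0-based grid coordinates of in-mask voxels
#'
#' @param cohort A `voxel_cohort`.
#' @return `n_voxels x 3` integer matrix of 0-based (i, j, k) coordinates in
#'   mask order.
#' @export
voxel_coords <- function(cohort) {
  linear_to_coords(cohort$mask_index, cohort$grid_shape)
}

# 1-based linear index -> 0-based (i,j,k); first axis fastest (column-major)
linear_to_coords <- function(idx, grid_shape) {
  idx0 <- as.integer(idx) - 1L
  i <- idx0 %% grid_shape[1L]
  j <- (idx0 %/% grid_shape[1L]) %% grid_shape[2L]
  k <- idx0 %/% (grid_shape[1L] * grid_shape[2L])
  cbind(i = i, j = j, k = k)
}

coords_to_linear <- function(coords, grid_shape) {
  coords <- rbind(coords)
  1L + coords[, 1L] + grid_shape[1L] * (coords[, 2L] + grid_shape[2L] * coords[, 3L])
}

#' Map 0-based voxel coordinates to world coordinates
#'
#' @param coords `n x 3` matrix of 0-based voxel coordinates.
#' @param affine 4x4 voxel-to-world matrix.
#' @return `n x 3` matrix of world (scanner/MNI-style) coordinates.
#' @export
voxel_to_world <- function(coords, affine) {
  coords <- rbind(coords)
  out <- cbind(coords, 1) %*% t(affine[1:3, , drop = FALSE])
  colnames(out) <- c("x", "y", "z")
  out
}

#' Extract a timepoint range as a new cohort
#' @keywords internal
subset_timepoints <- function(cohort, tp) {
  cohort$data <- lapply(cohort$data, function(m) m[, tp, drop = FALSE])
  cohort
}
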