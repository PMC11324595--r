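# Time-series preprocessing: Friston-24 motion expansion, framewise
# displacement, nuisance regression, band-pass filtering, Gaussian
# smoothing, intracranial volume.

#' Friston 24-parameter motion expansion
#'
#' Expands 6 rigid-body realignment parameters into the 24-regressor set:
#' the parameters, their squares, their lag-1 values and the squared lag-1
#' values. Lagged rows are zero-padded at the first timepoint.
#'
#' @param motion `T x 6` matrix: 3 translations (mm), 3 rotations (radians).
#' @return `T x 24` matrix with columns `p1..p6, p1_sq.., p1_lag..,
#'   p1_lag_sq..`.
#' @export
friston24 <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("format error: motion must have 6 columns")
  if (nrow(motion) < 2L) stop("format error: need at least 2 timepoints")
  if (any(!is.finite(motion))) stop("data error: non-finite motion values")
  lag1 <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, motion^2, lag1, lag1^2)
  colnames(out) <- c(paste0("p", 1:6), paste0("p", 1:6, "_sq"),
                     paste0("p", 1:6, "_lag"), paste0("p", 1:6, "_lag_sq"))
  out
}

#' Framewise displacement (Power convention)
#'
#' FD at timepoint t is the sum of absolute backward differences of the 3
#' translations plus `head_radius_mm` times the sum of absolute backward
#' differences of the 3 rotations (small-angle arc length on a sphere).
#' FD at the first timepoint is 0 by convention.
#'
#' @param motion `T x 6` matrix: translations (mm) then rotations (radians).
#' @param head_radius_mm Sphere radius converting radians to mm.
#' @return List with `fd` (length-T series, mm) and `mean_fd`.
#' @export
fd_power <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("format error: motion must have 6 columns")
  if (nrow(motion) < 2L) stop("format error: need at least 2 timepoints")
  if (any(!is.finite(motion))) stop("data error: non-finite motion values")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  list(fd = fd, mean_fd = mean(fd))
}

#' Build a nuisance design matrix
#'
#' Assembles the standard confound design: intercept, linear trend,
#' Friston-24 motion expansion, and optional white-matter / CSF mean
#' signals.
#'
#' @param motion `T x 6` motion parameter matrix, or NULL to omit.
#' @param wm,csf Optional length-T mean tissue signals.
#' @param n_timepoints Required if `motion` is NULL.
#' @return `T x p` design matrix with named columns.
#' @export
nuisance_design <- function(motion = NULL, wm = NULL, csf = NULL,
                            n_timepoints = if (is.null(motion)) NULL else nrow(motion)) {
  if (is.null(n_timepoints)) stop("n_timepoints required when motion is NULL")
  T <- n_timepoints
  X <- cbind(intercept = rep(1, T), trend = seq_len(T) - (T + 1) / 2)
  if (!is.null(motion)) X <- cbind(X, friston24(motion))
  if (!is.null(wm)) X <- cbind(X, wm = wm)
  if (!is.null(csf)) X <- cbind(X, csf = csf)
  X
}

# rank check shared by the GLM-style fits; names the aliased columns
check_full_rank <- function(X, context = "design") {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    if (is.null(bad)) bad <- qrx$pivot[(qrx$rank + 1L):ncol(X)]
    stop("degenerate-design error: ", context, " is rank deficient; ",
         "collinear columns: ", paste(bad, collapse = ", "))
  }
  qrx
}

#' Regress nuisance signals out of a voxel-time matrix
#'
#' Ordinary least-squares residualization of every voxel's time series on
#' the design columns. Residuals are orthogonal to the design.
#'
#' @param series `n_voxels x T` matrix.
#' @param design `T x p` full-rank design matrix (see [nuisance_design]).
#' @return Residual `n_voxels x T` matrix.
#' @export
regress_nuisance <- function(series, design) {
  series <- as.matrix(series)
  design <- as.matrix(design)
  if (ncol(series) != nrow(design))
    stop("format error: series has ", ncol(series), " timepoints but design has ",
         nrow(design), " rows")
  qrx <- check_full_rank(design, "nuisance design")
  t(qr.resid(qrx, t(series)))
}

#' Band-pass filter time series
#'
#' Frequency-domain masking with hard cutoffs: Fourier components with
#' frequency in `[low_hz, high_hz]` are retained, everything else
#' (including DC) is zeroed. Exactly linear and deterministic.
#'
#' @param series `n_voxels x T` matrix (rows are series).
#' @param tr_seconds Sampling interval (repetition time), seconds.
#' @param low_hz,high_hz Passband edges in Hz; `high_hz` must be below the
#'   Nyquist frequency `1/(2 tr)`.
#' @return Filtered matrix of the same shape.
#' @export
bandpass <- function(series, tr_seconds, low_hz = 0.01, high_hz = 0.1) {
  series <- as.matrix(series)
  T <- ncol(series)
  nyquist <- 1 / (2 * tr_seconds)
  if (high_hz >= nyquist)
    stop("configuration error: high_hz (", high_hz, ") must be below Nyquist (",
         nyquist, ")")
  if (low_hz < 0 || low_hz >= high_hz)
    stop("configuration error: need 0 <= low_hz < high_hz")
  freq <- (seq_len(T) - 1) / (T * tr_seconds)
  freq <- pmin(freq, 1 / tr_seconds - freq)     # fold to [0, Nyquist]
  keep <- freq >= low_hz & freq <= high_hz
  F <- t(stats::mvfft(t(series)))
  F[, !keep] <- 0
  Re(t(stats::mvfft(t(F), inverse = TRUE))) / T
}

# 1D Gaussian kernel sampled at integer offsets, radius 4 sigma
gauss_kernel <- function(sigma) {
  if (sigma == 0) return(1)
  r <- ceiling(4 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# convolve a 3D array along one axis with reflect padding
conv_axis <- function(vol, kernel, axis) {
  r <- (length(kernel) - 1L) / 2L
  if (r == 0L) return(vol)
  n <- dim(vol)[axis]
  pad_idx <- c(rev(seq_len(min(r, n))), seq_len(n), n + 1L - seq_len(min(r, n)))
  # reflect padding; if r > n the reflection cycles (tiny grids)
  while (length(pad_idx) < n + 2L * r)
    pad_idx <- c(pad_idx[1L], pad_idx, pad_idx[length(pad_idx)])
  idx <- function(m) switch(axis,
    vol[pad_idx[m], , , drop = FALSE],
    vol[, pad_idx[m], , drop = FALSE],
    vol[, , pad_idx[m], drop = FALSE])
  out <- array(0, dim(vol))
  for (o in seq_along(kernel)) {
    out <- out + kernel[o] * idx(seq_len(n) + (o - 1L))
  }
  out
}

#' Gaussian spatial smoothing of a volume series
#'
#' Per-volume separable 3D Gaussian convolution with
#' `sigma = fwhm / (2 sqrt(2 log 2))` per axis (in voxel units), reflect
#' boundary handling. `fwhm_mm = 0` is the identity.
#'
#' @param series `n_voxels x T` matrix over a full grid, or a 3D/4D array.
#' @param fwhm_mm Full-width at half-maximum, mm.
#' @param voxel_size_mm Isotropic voxel edge length, mm (or length-3).
#' @param grid_shape Required when `series` is a matrix.
#' @return Smoothed object of the same class/shape as the input.
#' @export
gaussian_smooth <- function(series, fwhm_mm, voxel_size_mm = 4,
                            grid_shape = NULL) {
  if (fwhm_mm < 0) stop("configuration error: fwhm_mm must be >= 0")
  vs <- rep(voxel_size_mm, length.out = 3)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs
  smooth_vol <- function(vol) {
    for (ax in 1:3) vol <- conv_axis(vol, gauss_kernel(sigma_vox[ax]), ax)
    vol
  }
  if (is.matrix(series)) {
    if (is.null(grid_shape)) stop("grid_shape required for matrix input")
    if (nrow(series) != prod(grid_shape))
      stop("format error: matrix rows must cover the full grid")
    if (fwhm_mm == 0) return(series)
    out <- series
    for (t in seq_len(ncol(series))) {
      out[, t] <- as.vector(smooth_vol(array(series[, t], grid_shape)))
    }
    out
  } else if (length(dim(series)) == 3L) {
    if (fwhm_mm == 0) return(series)
    smooth_vol(series)
  } else if (length(dim(series)) == 4L) {
    if (fwhm_mm == 0) return(series)
    out <- series
    for (t in seq_len(dim(series)[4])) out[, , , t] <- smooth_vol(series[, , , t])
    out
  } else stop("format error: series must be a matrix or 3D/4D array")
}

#' Intracranial volume from tissue volumes
#'
#' @param gm_volume_ml,wm_volume_ml,csf_volume_ml Nonnegative tissue
#'   volumes in ml.
#' @return Total intracranial volume (ml), the plain sum.
#' @export
intracranial_volume <- function(gm_volume_ml, wm_volume_ml, csf_volume_ml) {
  v <- c(gm_volume_ml, wm_volume_ml, csf_volume_ml)
  if (any(!is.finite(v)) || any(v < 0))
    stop("data error: tissue volumes must be finite and nonnegative")
  gm_volume_ml + wm_volume_ml + csf_volume_ml
}

#' Preprocess one subject's voxel-time matrix
#'
#' The in-scope tail of the preprocessing chain, in fixed order: nuisance
#' regression (Friston-24 + optional WM/CSF + linear trend + intercept),
#' spatial smoothing, band-pass filtering.
#'
#' @param series `n_voxels x T` matrix (full grid if smoothing is on).
#' @param motion `T x 6` motion parameters.
#' @param tr_seconds Repetition time, seconds.
#' @param wm,csf Optional mean tissue signals.
#' @param band Passband in Hz.
#' @param fwhm_mm Smoothing kernel FWHM (0 disables).
#' @param voxel_size_mm Voxel size for smoothing.
#' @param grid_shape Grid for smoothing when `fwhm_mm > 0`.
#' @return Preprocessed matrix.
#' @export
prep_subject <- function(series, motion, tr_seconds, wm = NULL, csf = NULL,
                         band = c(0.01, 0.1), fwhm_mm = 0, voxel_size_mm = 4,
                         grid_shape = NULL) {
  X <- nuisance_design(motion, wm = wm, csf = csf)
  out <- regress_nuisance(series, X)
  if (fwhm_mm > 0)
    out <- gaussian_smooth(out, fwhm_mm, voxel_size_mm, grid_shape)
  bandpass(out, tr_seconds, band[1], band[2])
}
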