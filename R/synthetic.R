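# Synthetic two-group fMRI-like cohort generator with known ground truth.
#
# Signal model: each declared cluster carries one latent, band-limited,
# unit-variance Gaussian time course. Cluster-pair correlations are induced
# by mixing independent latents through the Cholesky factor of a target
# latent correlation matrix. Voxels inside a cluster observe their cluster's
# latent plus independent (optionally AR(1)) noise; background voxels are
# unit-variance noise. Because the attenuation of the correlation between
# cluster *mean* signals by voxel noise is known in closed form
# (var of a cluster mean = 1 + sd^2/m for m member voxels), the latent
# correlations are inflated analytically so that the expected Pearson
# correlation between cluster means equals the declared group value.

#' Build a rectangular voxel cluster
#'
#' @param x,y,z Integer vectors of 0-based grid coordinates spanned by the
#'   block along each axis.
#' @return Integer matrix of 0-based voxel coordinates, one row per voxel.
#' @export
block_cluster <- function(x, y, z) {
  as.matrix(expand.grid(i = as.integer(x), j = as.integer(y), k = as.integer(z)))
}

#' Default two-cluster layout on a grid
#'
#' Two 30-voxel blocks in opposite corners of the grid, named "A" and "B".
#'
#' @param grid_shape Integer vector of length 3.
#' @return Named list of coordinate matrices.
#' @export
default_clusters <- function(grid_shape = c(10L, 10L, 6L)) {
  g <- as.integer(grid_shape)
  stopifnot(all(g >= c(10L, 10L, 6L)))
  list(A = block_cluster(0:4, 0:2, 0:1),
       B = block_cluster((g[1] - 5):(g[1] - 1), (g[2] - 3):(g[2] - 1),
                         (g[3] - 2):(g[3] - 1)))
}

# Covariate location/scale per group; defaults emulate the study cohort's
# demographics: ~130 older adults, women-predominant patient group, and a
# group difference in intracranial volume.
default_covariates <- function() {
  list(age       = list(CN = c(63.3, 6.5),     SCD = c(65.6, 7.5)),
       education = list(CN = c(12.52, 2.64),   SCD = c(11.96, 2.60)),
       itv       = list(CN = c(1416.22, 108.83), SCD = c(1364.83, 101.96)),
       gender_p_male = list(CN = 31 / 74, SCD = 12 / 56))
}

#' Simulation configuration
#'
#' Declares the stated world for a synthetic two-group cohort: grid, scan
#' length, cluster layout, group-specific circuit correlations, noise,
#' covariate distributions and cognition couplings.
#'
#' @param grid_shape Voxel grid, 3 positive integers.
#' @param n_timepoints Scan length T (volumes).
#' @param tr_seconds Repetition time (seconds).
#' @param n_subjects_per_group Named or ordered pair `c(CN, SCD)`.
#' @param signal_clusters Named list of 0-based coordinate matrices; each
#'   entry is one cluster carrying a shared latent signal.
#' @param circuit_effects List of `list(pair = c(id1, id2), r_cn, r_scd)`
#'   declaring the expected correlation between the two clusters' mean
#'   signals in each group. Unlisted pairs have expected correlation 0.
#' @param noise_sd Voxel noise standard deviation inside clusters (the
#'   latent has unit variance, so `noise_sd = 0.5` gives within-cluster
#'   voxel-pair correlation 0.8).
#' @param noise_ar1 AR(1) coefficient of voxel noise, in `[0, 1)`.
#' @param band Passband (Hz) applied to latent time courses; `NULL`
#'   disables band-limiting.
#' @param cognition_couplings List of
#'   `list(pair = c(id1, id2), domain, slope, noise_sd)`: the named
#'   domain's raw test score is `slope * z + noise` where z is the
#'   subject's realized Fisher-z circuit FC. Domains without a coupling are
#'   standard-normal noise. The default coupling noise sd (0.06) is matched
#'   to the subject-level Fisher-z sampling variability at T = 200
#'   (`sd(z) ~ 1/sqrt(T-3)`, signal sd `0.5 * 0.071`), giving a generated
#'   brain-behavior correlation of about 0.5.
#' @param covariate_distributions Per-covariate, per-group location/scale;
#'   see `default_covariates()`.
#' @param motion_step_sd Random-walk step standard deviations
#'   `c(translation_mm, rotation_rad)` for the simulated 6-parameter motion
#'   traces.
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(grid_shape = c(10L, 10L, 6L),
                       n_timepoints = 200L,
                       tr_seconds = 2,
                       n_subjects_per_group = c(CN = 74L, SCD = 56L),
                       signal_clusters = default_clusters(grid_shape),
                       circuit_effects = list(
                         list(pair = c("A", "B"), r_cn = 0.6, r_scd = 0.2)),
                       noise_sd = 0.5,
                       noise_ar1 = 0,
                       band = c(0.01, 0.1),
                       cognition_couplings = list(
                         list(pair = c("A", "B"), domain = "EM",
                              slope = 0.5, noise_sd = 0.06)),
                       covariate_distributions = default_covariates(),
                       motion_step_sd = c(0.04, 5e-4),
                       seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0L),
            n_timepoints >= 2L, tr_seconds > 0,
            length(n_subjects_per_group) == 2L, all(n_subjects_per_group >= 2L),
            noise_sd >= 0, noise_ar1 >= 0, noise_ar1 < 1)
  if (is.null(names(signal_clusters)) || any(names(signal_clusters) == ""))
    stop("signal_clusters must be a named list")
  for (cm in signal_clusters) {
    if (any(cm < 0L) || any(t(cm) >= grid_shape))
      stop("configuration error: cluster voxel outside grid")
  }
  lin <- unlist(lapply(signal_clusters, coords_to_linear, grid_shape = grid_shape))
  if (anyDuplicated(lin)) stop("configuration error: clusters overlap")
  if (length(lin) > prod(grid_shape))
    stop("configuration error: clusters exceed grid volume")
  ids <- names(signal_clusters)
  for (ce in circuit_effects) {
    if (!all(ce$pair %in% ids))
      stop("configuration error: circuit names unknown cluster ", paste(ce$pair, collapse = ","))
    if (any(abs(c(ce$r_cn, ce$r_scd)) >= 1))
      stop("configuration error: circuit correlations must lie in (-1, 1)")
  }
  for (cc in cognition_couplings) {
    if (!all(cc$pair %in% ids))
      stop("configuration error: cognition coupling names unknown cluster")
  }
  if (is.null(names(n_subjects_per_group)))
    names(n_subjects_per_group) <- c("CN", "SCD")
  structure(list(grid_shape = grid_shape, n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds,
                 n_subjects_per_group = n_subjects_per_group,
                 signal_clusters = signal_clusters,
                 circuit_effects = circuit_effects,
                 noise_sd = noise_sd, noise_ar1 = noise_ar1, band = band,
                 cognition_couplings = cognition_couplings,
                 covariate_distributions = covariate_distributions,
                 motion_step_sd = motion_step_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# target latent correlation matrix for one group, inflated to undo the
# attenuation of cluster-mean correlations by voxel noise
latent_corr <- function(config, group) {
  ids <- names(config$signal_clusters)
  K <- length(ids)
  m <- vapply(config$signal_clusters, nrow, integer(1))
  infl <- sqrt(1 + config$noise_sd^2 / m)          # sd of a cluster mean
  R <- diag(K)
  dimnames(R) <- list(ids, ids)
  for (ce in config$circuit_effects) {
    r <- if (group == "CN") ce$r_cn else ce$r_scd
    a <- ce$pair[1]; b <- ce$pair[2]
    r_lat <- r * infl[a] * infl[b]
    if (abs(r_lat) >= 1)
      stop("configuration error: declared correlation ", r,
           " is unreachable at noise_sd ", config$noise_sd,
           " (required latent correlation ", round(r_lat, 3), ")")
    R[a, b] <- R[b, a] <- r_lat
  }
  ok <- tryCatch({ chol(R); TRUE }, error = function(e) FALSE)
  if (!ok) stop("configuration error: circuit correlations are jointly infeasible ",
                "(latent correlation matrix not positive definite)")
  R
}

# white noise -> band-limited unit-sd columns (hard FFT mask, DC removed)
band_limited_noise <- function(T, K, band, tr) {
  W <- matrix(stats::rnorm(T * K), T, K)
  if (is.null(band)) return(scale(W, center = TRUE, scale = apply(W, 2, stats::sd)))
  Wf <- bandpass(t(W), tr_seconds = tr, low_hz = band[1], high_hz = band[2])
  W <- t(Wf)
  sds <- apply(W, 2, stats::sd)
  if (any(sds == 0)) stop("degenerate band-limited latent (all power removed)")
  scale(W, center = FALSE, scale = sds)
}

# AR(1) noise matrix (T x n), marginal sd `sd`
ar1_noise <- function(T, n, sd, phi) {
  E <- matrix(stats::rnorm(T * n), T, n)
  if (phi > 0) {
    E <- apply(E, 2, function(e) as.numeric(stats::filter(e, phi, method = "recursive")))
    E <- E * sqrt(1 - phi^2)       # restore unit marginal variance
  }
  E * sd
}

#' Generate a synthetic two-group cohort
#'
#' Draws a full cohort from a `sim_config`: voxel-time matrices, phenotype
#' table (demographics, motion summary, raw cognition scores), 6-parameter
#' motion traces and the generating ground truth. Fully reproducible from
#' `config$seed`.
#'
#' @param config A `sim_config`.
#' @return A list with elements `cohort` (a [voxel_cohort]), `phenotype`
#'   (data frame: subject_id, group, age, gender, education, itv, fd_mean
#'   and one raw score column per cognitive domain), `motion` (list of
#'   `T x 6` matrices), `ground_truth` (affected voxel rows/coords, affected
#'   circuits, generating slopes) and `manifest` (domain -> test columns).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- config$grid_shape
  T <- config$n_timepoints
  nvox <- prod(g)
  mask_index <- seq_len(nvox)
  ids <- names(config$signal_clusters)
  K <- length(ids)
  cluster_rows <- lapply(config$signal_clusters, function(cm)
    match(coords_to_linear(cm, g), mask_index))

  n_cn <- config$n_subjects_per_group[[1]]
  n_scd <- config$n_subjects_per_group[[2]]
  groups <- c(rep("CN", n_cn), rep("SCD", n_scd))
  n_sub <- length(groups)
  subject_ids <- sprintf("sub-%03d", seq_len(n_sub))

  R_lat <- list(CN = latent_corr(config, "CN"), SCD = latent_corr(config, "SCD"))
  chol_lat <- lapply(R_lat, chol)

  domains <- c("EM", "EF", "VF", "IPS")
  coupled <- vapply(config$cognition_couplings, function(cc) cc$domain, character(1))

  data <- vector("list", n_sub)
  motion <- vector("list", n_sub)
  scores <- matrix(NA_real_, n_sub, length(domains),
                   dimnames = list(NULL, paste0(tolower(domains), "_score")))
  circuit_z <- matrix(NA_real_, n_sub, length(config$circuit_effects))

  for (s in seq_len(n_sub)) {
    grp <- groups[s]
    L <- band_limited_noise(T, K, config$band, config$tr_seconds) %*% chol_lat[[grp]]
    Y <- matrix(0, nvox, T)
    bg <- setdiff(seq_len(nvox), unlist(cluster_rows))
    Y[bg, ] <- t(ar1_noise(T, length(bg), 1, config$noise_ar1))
    for (k in seq_len(K)) {
      rows <- cluster_rows[[k]]
      noise <- if (config$noise_sd > 0)
        t(ar1_noise(T, length(rows), config$noise_sd, config$noise_ar1))
      else 0
      Y[rows, ] <- matrix(L[, k], length(rows), T, byrow = TRUE) + noise
    }
    data[[s]] <- Y

    # realized circuit FC (Fisher z between cluster mean signals)
    means <- vapply(cluster_rows, function(rows) colMeans(Y[rows, , drop = FALSE]),
                    numeric(T))
    for (ci in seq_along(config$circuit_effects)) {
      pr <- config$circuit_effects[[ci]]$pair
      circuit_z[s, ci] <- atanh(stats::cor(means[, pr[1]], means[, pr[2]]))
    }

    # 6-parameter rigid-body motion as a small-amplitude random walk
    steps <- cbind(matrix(stats::rnorm(T * 3, sd = config$motion_step_sd[1]), T, 3),
                   matrix(stats::rnorm(T * 3, sd = config$motion_step_sd[2]), T, 3))
    motion[[s]] <- apply(steps, 2, cumsum)
  }

  cd <- config$covariate_distributions
  draw <- function(par, grp, n) stats::rnorm(n, par[[grp]][1], par[[grp]][2])
  age <- education <- itv <- numeric(n_sub); gender <- integer(n_sub)
  for (grp in c("CN", "SCD")) {
    sel <- groups == grp; n <- sum(sel)
    age[sel] <- draw(cd$age, grp, n)
    education[sel] <- draw(cd$education, grp, n)
    itv[sel] <- draw(cd$itv, grp, n)
    gender[sel] <- stats::rbinom(n, 1, cd$gender_p_male[[grp]])
  }

  # raw cognition scores: coupled domains track realized circuit FC
  for (d in seq_along(domains)) {
    hit <- which(coupled == domains[d])
    if (length(hit) >= 1) {
      cc <- config$cognition_couplings[[hit[1]]]
      ci <- which(vapply(config$circuit_effects, function(ce)
        setequal(ce$pair, cc$pair), logical(1)))
      z <- if (length(ci)) circuit_z[, ci[1]] else {
        # circuit not among declared effects: recompute is impossible here,
        # treated as configuration error upstream
        stop("cognition coupling references an undeclared circuit")
      }
      scores[, d] <- cc$slope * z + stats::rnorm(n_sub, sd = cc$noise_sd)
    } else {
      scores[, d] <- stats::rnorm(n_sub)
    }
  }

  cohort <- voxel_cohort(data, subject_ids, g, mask_index, tr = config$tr_seconds)
  fd_mean <- vapply(motion, function(m) fd_power(m)$mean_fd, numeric(1))
  phenotype <- data.frame(subject_id = subject_ids,
                          group = factor(groups, levels = c("CN", "SCD")),
                          age = age, gender = gender, education = education,
                          itv = itv, fd_mean = fd_mean,
                          stringsAsFactors = FALSE)
  phenotype <- cbind(phenotype, as.data.frame(scores))

  affected <- unique(unlist(lapply(config$circuit_effects, function(ce)
    if (ce$r_cn != ce$r_scd) ce$pair else character(0))))
  affected_rows <- sort(unique(unlist(cluster_rows[affected])))
  ground_truth <- list(
    affected_voxels = affected_rows,
    affected_coords = linear_to_coords(mask_index[affected_rows], g),
    affected_circuits = lapply(Filter(function(ce) ce$r_cn != ce$r_scd,
                                      config$circuit_effects),
                               function(ce) ce$pair),
    cognition_slopes = config$cognition_couplings,
    circuit_z = circuit_z)

  manifest <- stats::setNames(as.list(colnames(scores)), domains)
  list(cohort = cohort, phenotype = phenotype, motion = motion,
       ground_truth = ground_truth, manifest = manifest)
}

#' Generate a toy atlas on a voxel grid
#'
#' Tiles the in-mask voxels into `n_regions` contiguous, nonempty regions of
#' near-equal size (consecutive runs of ascending linear index, which are
#' 26-connected on a full grid). Stands in for an anatomical parcellation at
#' toy scale. Deterministic; `seed` is accepted for interface stability.
#'
#' @param grid_shape Voxel grid, 3 positive integers.
#' @param n_regions Number of regions, at least 1.
#' @param seed Unused (tiling is deterministic); kept so that callers can
#'   treat atlas generation like the other generators.
#' @param mask_index In-mask linear indices (default: whole grid).
#' @return List with `labels` (3D integer array, 0 outside the mask) and
#'   `label_table` (data frame: id, name).
#' @export
generate_toy_atlas <- function(grid_shape, n_regions, seed = 1L,
                               mask_index = seq_len(prod(grid_shape))) {
  grid_shape <- as.integer(grid_shape)
  n_regions <- as.integer(n_regions)
  if (n_regions < 1L) stop("configuration error: n_regions must be >= 1")
  nv <- length(mask_index)
  if (n_regions > nv)
    stop("configuration error: n_regions exceeds in-mask voxel count")
  reg <- if (n_regions == 1L) rep(1L, nv)
         else as.integer(cut(seq_len(nv), breaks = n_regions, labels = FALSE))
  labels <- array(0L, dim = grid_shape)
  labels[mask_index] <- reg
  label_table <- data.frame(id = seq_len(n_regions),
                            name = sprintf("ToyRegion_%03d", seq_len(n_regions)),
                            stringsAsFactors = FALSE)
  list(labels = labels, label_table = label_table)
}
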