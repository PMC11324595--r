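# Shared fixture builders. Everything is generated in code; no data files.

# cohort directly from a list of voxel-time matrices on a full-grid mask
mat_cohort <- function(mats, grid_shape, tr = 2) {
  stopifnot(nrow(mats[[1]]) == prod(grid_shape))
  voxel_cohort(mats, sprintf("s%02d", seq_along(mats)), grid_shape,
               seq_len(prod(grid_shape)), tr = tr)
}

# small two-cluster world on a 5x4x3 grid (60 voxels): two 8-voxel blocks
small_clusters <- function() {
  list(A = block_cluster(0:1, 0:1, 0:1),
       B = block_cluster(3:4, 2:3, 1:2))
}

# compact simulation config for fast tests
quick_config <- function(n_per_group = c(CN = 15L, SCD = 15L),
                         n_timepoints = 100L,
                         r_cn = 0.6, r_scd = 0.2, seed = 1L,
                         circuit_effects = list(list(pair = c("A", "B"),
                                                     r_cn = r_cn,
                                                     r_scd = r_scd)),
                         ...) {
  sim_config(grid_shape = c(5L, 4L, 3L),
             n_timepoints = n_timepoints,
             n_subjects_per_group = n_per_group,
             signal_clusters = small_clusters(),
             circuit_effects = circuit_effects,
             seed = seed, ...)
}

# full-scale recovery world from the acceptance criteria: 10x10x6 grid,
# two 30-voxel clusters, delta-r = 0.4, n = 40/40, T = 200
recovery_config <- function(seed, n_per_group = c(CN = 40L, SCD = 40L),
                            n_timepoints = 200L, r_cn = 0.6, r_scd = 0.2,
                            ...) {
  sim_config(grid_shape = c(10L, 10L, 6L),
             n_timepoints = n_timepoints,
             n_subjects_per_group = n_per_group,
             circuit_effects = list(list(pair = c("A", "B"),
                                         r_cn = r_cn, r_scd = r_scd)),
             seed = seed, ...)
}

# toy-scale MA thresholds for the 600-voxel recovery grid (see vignette)
TOY_MA_MIN <- 10
TOY_CLUSTER_MIN <- 10

# mask-row sets of the named clusters of a config
cluster_rows <- function(config) {
  lapply(config$signal_clusters,
         function(cm) bwasr:::coords_to_linear(cm, config$grid_shape))
}

# hand-built ma_map for cluster-extraction tests
make_ma_map <- function(ma_values, grid_shape, alpha = 3.33e-2) {
  structure(list(ma = as.integer(ma_values), alpha = alpha, cutoff = NA_real_,
                 n_sig_links = sum(ma_values) / 2,
                 sig_links = NULL,
                 grid_shape = as.integer(grid_shape),
                 mask_index = seq_len(prod(grid_shape)),
                 affine = diag(c(4, 4, 4, 1))),
            class = "ma_map")
}
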