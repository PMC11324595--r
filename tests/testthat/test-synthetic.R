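test_that("sim_config validates its invariants", {
  expect_s3_class(quick_config(), "sim_config")
  overlap <- list(A = block_cluster(0:1, 0:1, 0:1),
                  B = block_cluster(1:2, 1:2, 1:2))
  expect_error(sim_config(grid_shape = c(5, 4, 3), signal_clusters = overlap,
                          circuit_effects = list()),
               "overlap")
  expect_error(quick_config(r_cn = 1.0), "\\(-1, 1\\)")
  expect_error(sim_config(grid_shape = c(5, 4, 3),
                          signal_clusters = list(A = block_cluster(0:9, 0, 0)),
                          circuit_effects = list()),
               "outside grid")
  expect_error(quick_config(circuit_effects = list(
    list(pair = c("A", "Z"), r_cn = 0.1, r_scd = 0.1))),
    "unknown cluster")
  # declared correlation unreachable once noise attenuation is inverted
  expect_error(generate_cohort(quick_config(r_cn = 0.97, noise_sd = 1)),
               "unreachable")
})

test_that("identical config and seed give bit-identical cohorts", {
  a <- generate_cohort(quick_config(seed = 11))
  b <- generate_cohort(quick_config(seed = 11))
  expect_identical(a$cohort$data, b$cohort$data)
  expect_identical(a$phenotype, b$phenotype)
  expect_identical(a$motion, b$motion)
  c <- generate_cohort(quick_config(seed = 12))
  expect_false(identical(a$cohort$data[[1]], c$cohort$data[[1]]))
})

test_that("zero-noise single-cluster config gives exact within-cluster correlation 1", {
  cfg <- sim_config(grid_shape = c(5, 4, 3),
                    signal_clusters = list(A = block_cluster(0:1, 0:1, 0:1)),
                    circuit_effects = list(), cognition_couplings = list(),
                    noise_sd = 0, n_subjects_per_group = c(CN = 2, SCD = 2),
                    n_timepoints = 50, seed = 3)
  sim <- generate_cohort(cfg)
  rows <- cluster_rows(cfg)$A
  for (s in seq_along(sim$cohort$data)) {
    C <- cor(t(sim$cohort$data[[s]][rows, ]))
    expect_equal(C, matrix(1, 8, 8), tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("empirical cluster-pair correlations track declared group values", {
  # Monte-Carlo over seeds: mean per-group correlation within +/-0.07 of
  # the declared CN 0.6 / SCD 0.2 at T = 200
  n_seeds <- 12
  r_cn <- r_scd <- numeric(0)
  for (seed in seq_len(n_seeds)) {
    cfg <- quick_config(n_per_group = c(CN = 10, SCD = 10),
                        n_timepoints = 200, seed = 100 + seed)
    sim <- generate_cohort(cfg)
    rows <- cluster_rows(cfg)
    r <- vapply(sim$cohort$data, function(m)
      cor(colMeans(m[rows$A, ]), colMeans(m[rows$B, ])), numeric(1))
    r_cn <- c(r_cn, r[sim$phenotype$group == "CN"])
    r_scd <- c(r_scd, r[sim$phenotype$group == "SCD"])
  }
  expect_lt(abs(mean(r_cn) - 0.6), 0.07)
  expect_lt(abs(mean(r_scd) - 0.2), 0.07)
})

test_that("calibration: group-wise circuit correlations are unbiased at T = 500", {
  r_cn <- r_scd <- numeric(0)
  for (seed in 1:10) {
    cfg <- quick_config(n_per_group = c(CN = 12, SCD = 12),
                        n_timepoints = 500, seed = 300 + seed)
    sim <- generate_cohort(cfg)
    rows <- cluster_rows(cfg)
    r <- vapply(sim$cohort$data, function(m)
      cor(colMeans(m[rows$A, ]), colMeans(m[rows$B, ])), numeric(1))
    r_cn <- c(r_cn, r[sim$phenotype$group == "CN"])
    r_scd <- c(r_scd, r[sim$phenotype$group == "SCD"])
  }
  expect_lt(abs(mean(r_cn) - 0.6), 0.02)
  expect_lt(abs(mean(r_scd) - 0.2), 0.02)
})

test_that("phenotype carries covariates, motion-derived FD and cognition scores", {
  cfg <- quick_config(seed = 5)
  sim <- generate_cohort(cfg)
  ph <- sim$phenotype
  expect_setequal(levels(ph$group), c("CN", "SCD"))
  expect_true(all(c("age", "gender", "education", "itv", "fd_mean",
                    "em_score", "ef_score", "vf_score", "ips_score")
                  %in% colnames(ph)))
  expect_true(all(ph$gender %in% 0:1))
  expect_true(all(ph$fd_mean > 0))
  expect_equal(ph$fd_mean[1], fd_power(sim$motion[[1]])$mean_fd)
  # ground truth names the two affected clusters' voxels
  rows <- cluster_rows(cfg)
  expect_identical(sim$ground_truth$affected_voxels,
                   sort(c(rows$A, rows$B)))
})

test_that("toy atlas tiles the mask into contiguous nonempty regions", {
  at <- generate_toy_atlas(c(6, 6, 6), 4)
  expect_equal(dim(at$labels), c(6, 6, 6))
  expect_true(all(at$labels >= 1 & at$labels <= 4))
  expect_equal(sort(unique(as.vector(at$labels))), 1:4)
  expect_equal(nrow(at$label_table), 4)
  # contiguity under 26-connectivity, via the package's component finder
  for (id in 1:4) {
    rows <- which(at$labels == id)
    comps <- bwasr:::connected_components(rows, c(6L, 6L, 6L),
                                          seq_len(216L), 26)
    expect_length(comps, 1)
  }
  # single region
  at1 <- generate_toy_atlas(c(3, 3, 3), 1)
  expect_true(all(at1$labels == 1L))
  # determinism
  expect_identical(generate_toy_atlas(c(6, 6, 6), 4, seed = 9)$labels,
                   generate_toy_atlas(c(6, 6, 6), 4, seed = 9)$labels)
  expect_error(generate_toy_atlas(c(2, 2, 2), 9), "exceeds")
})
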