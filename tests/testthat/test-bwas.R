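test_that("count_links follows the printed n^2/2 convention", {
  expect_identical(count_links(23178), 268609842)
  expect_identical(count_links(2), 2)
  expect_identical(count_links(1), 0)
  expect_identical(count_links(5, convention = "choose2"), 10)
  expect_error(count_links(0), "positive")
  expect_error(count_links(2.5), "positive integer")
})

test_that("fwe_threshold is Bonferroni and monotone in the family size", {
  expect_equal(fwe_threshold(3.33e-2, 268609842), 3.33e-2 / 268609842)
  expect_equal(fwe_threshold(3.33e-2, 268609842), 1.2397e-10,
               tolerance = 1e-4)
  expect_equal(fwe_threshold(0.05, 1), 0.05)
  ns <- c(1, 10, 1e4, 1e8)
  expect_true(all(diff(vapply(ns, fwe_threshold, numeric(1),
                              alpha = 0.05)) < 0))
  expect_error(fwe_threshold(0, 10), "alpha")
  expect_error(fwe_threshold(0.05, 0), "n_links")
})

test_that("voxel_fc_fisher computes atanh of pairwise Pearson r with i < j", {
  # constructed pair with exact sample correlation 0.5
  set.seed(2)
  T <- 100
  x <- as.numeric(scale(rnorm(T)))
  e <- residuals(lm(rnorm(T) ~ x)); e <- as.numeric(scale(e))
  y <- 0.5 * x + sqrt(0.75) * e
  co <- mat_cohort(list(rbind(x, y)), c(2, 1, 1))
  fc <- voxel_fc_fisher(co)
  expect_equal(dim(fc$z), c(1, 1))
  expect_equal(fc$pairs, cbind(i = 1L, j = 2L), ignore_attr = TRUE)
  expect_equal(fc$z[1, 1], atanh(0.5), tolerance = 1e-10)
  # no self-links: 4 voxels -> 6 pairs, all i < j
  co4 <- mat_cohort(list(matrix(rnorm(4 * 30), 4, 30)), c(4, 1, 1))
  fc4 <- voxel_fc_fisher(co4)
  expect_equal(nrow(fc4$pairs), 6)
  expect_true(all(fc4$pairs[, 1] < fc4$pairs[, 2]))
  # independent white noise at T = 500 gives small |z|
  set.seed(3)
  zs <- replicate(20, {
    cw <- mat_cohort(list(matrix(rnorm(2 * 500), 2, 500)), c(2, 1, 1))
    voxel_fc_fisher(cw)$z[1, 1]
  })
  expect_lt(stats::quantile(abs(zs), 0.9), 0.15)
  # degenerate voxels are refused
  bad <- mat_cohort(list(rbind(rep(1, 50), rnorm(50))), c(2, 1, 1))
  expect_error(voxel_fc_fisher(bad), "zero-variance")
  sat <- mat_cohort(list(rbind(x, 2 * x)), c(2, 1, 1))
  expect_error(voxel_fc_fisher(sat), "saturation")
})

test_that("link_group_test with no covariates equals the pooled two-sample t", {
  set.seed(4)
  sim <- generate_cohort(quick_config(seed = 21))
  fc <- voxel_fc_fisher(sim$cohort)
  lt <- link_group_test(fc, sim$phenotype, covariates = character(0))
  expect_equal(nrow(lt), nrow(fc$pairs))   # retain_p = 1 keeps everything
  g <- sim$phenotype$group
  for (k in sample(nrow(fc$pairs), 8)) {
    z <- fc$z[, k]
    oracle <- two_sample_t(z[g == "SCD"], z[g == "CN"])
    row <- lt[lt$i == fc$pairs[k, 1] & lt$j == fc$pairs[k, 2], ]
    expect_equal(row$t, oracle$t, tolerance = 1e-10)
    expect_equal(row$p, oracle$p, tolerance = 1e-10)
  }
  expect_equal(attr(lt, "df"), nrow(sim$phenotype) - 2L)
})

test_that("link_group_test adjusts covariates, checks design and sign convention", {
  sim <- generate_cohort(quick_config(seed = 22))
  fc <- voxel_fc_fisher(sim$cohort)
  ph <- sim$phenotype
  # covariate identical to the group indicator is collinear
  ph$bad <- as.integer(ph$group == "SCD")
  expect_error(link_group_test(fc, ph, covariates = "bad"),
               "degenerate-design")
  # GLM df accounts for the covariates
  lt <- link_group_test(fc, ph)
  expect_equal(attr(lt, "df"), nrow(ph) - 6L)
  # residualize-then-t variant has df = n - 2 and similar t values
  lt2 <- link_group_test(fc, ph, method = "residualize")
  expect_equal(attr(lt2, "df"), nrow(ph) - 2L)
  expect_gt(cor(lt$t, lt2$t), 0.98)
  # injected effect: smallest p-values concentrate on between-cluster links
  cfg <- recovery_config(seed = 23, n_per_group = c(CN = 20, SCD = 20))
  sim2 <- generate_cohort(cfg)
  res <- bwas_run(sim2$cohort, sim2$phenotype,
                  ma_min = TOY_MA_MIN, min_cluster_voxels = TOY_CLUSTER_MIN)
  ord <- order(res$links$p)[1:50]
  rows <- cluster_rows(cfg)
  cross <- (res$links$i[ord] %in% rows$A & res$links$j[ord] %in% rows$B) |
           (res$links$i[ord] %in% rows$B & res$links$j[ord] %in% rows$A)
  expect_gte(mean(cross), 0.95)
  # CN = 0, SCD = 1 coding: weakened FC in SCD shows negative t
  expect_true(all(res$links$t[ord] < 0))
})

test_that("compute_ma counts incident significant links", {
  # hand case: 5 voxels, significant set {(1,2),(1,3),(2,3)}
  p <- rep(0.9, 10)
  pairs <- bwasr:::link_pairs(5)
  sig <- (pairs[, 1] == 1 & pairs[, 2] == 2) |
         (pairs[, 1] == 1 & pairs[, 2] == 3) |
         (pairs[, 1] == 2 & pairs[, 2] == 3)
  p[sig] <- 1e-12
  lt <- structure(data.frame(i = pairs[, 1], j = pairs[, 2],
                             t = 0, p = p),
                  class = c("link_test_table", "data.frame"),
                  n_links = count_links(5), n_tests = 10,
                  alpha = 3.33e-2, cutoff = 3.33e-2 / count_links(5),
                  retain_p = 1, df = 10, n_voxels = 5L,
                  grid_shape = c(5L, 1L, 1L), mask_index = 1:5,
                  affine = diag(4))
  ma <- compute_ma(lt)
  expect_equal(ma$ma, c(2L, 2L, 2L, 0L, 0L))
  expect_equal(sum(ma$ma), 2 * ma$n_sig_links)
  # no significant links -> MA identically zero
  lt0 <- lt; lt0$p <- rep(0.5, 10); attributes(lt0) <- attributes(lt)
  expect_true(all(compute_ma(lt0)$ma == 0L))
  # retention below the FWE cutoff is an undercount error
  attr(lt, "retain_p") <- 1e-15
  expect_error(compute_ma(lt), "undercount")
})

test_that("compute_ma equals a brute-force double loop on a real instance", {
  # 30-voxel cohort with an effect, tested at a permissive alpha so that
  # many links are significant
  cfg <- sim_config(grid_shape = c(5, 3, 2), n_timepoints = 80,
                    n_subjects_per_group = c(CN = 12, SCD = 12),
                    signal_clusters = list(A = block_cluster(0:1, 0:1, 0:1),
                                           B = block_cluster(3:4, 1:2, 0:1)),
                    circuit_effects = list(list(pair = c("A", "B"),
                                                r_cn = 0.7, r_scd = 0)),
                    seed = 31)
  sim <- generate_cohort(cfg)
  fc <- voxel_fc_fisher(sim$cohort)
  lt <- link_group_test(fc, sim$phenotype, alpha = 0.5)
  ma <- compute_ma(lt)
  cutoff <- attr(lt, "cutoff")
  # oracle: double loop over all enumerated pairs
  ma_brute <- integer(30)
  for (r in seq_len(nrow(lt))) {
    if (lt$p[r] < cutoff) {
      ma_brute[lt$i[r]] <- ma_brute[lt$i[r]] + 1L
      ma_brute[lt$j[r]] <- ma_brute[lt$j[r]] + 1L
    }
  }
  expect_gt(ma$n_sig_links, 0)
  expect_identical(ma$ma, ma_brute)
  expect_equal(sum(ma$ma), 2 * ma$n_sig_links)
})

test_that("extract_clusters applies strict threshold, connectivity and size filter", {
  g <- c(8, 4, 4)
  # all-zero map -> empty set
  empty <- extract_clusters(make_ma_map(integer(prod(g)), g), 10, 5)
  expect_length(empty, 0)
  # one 3x3x3 block of MA 100 -> single 27-voxel cluster
  g2 <- c(6, 6, 6)
  ma_vals <- integer(216)
  block <- bwasr:::coords_to_linear(block_cluster(1:3, 1:3, 1:3), g2)
  ma_vals[block] <- 100L
  cs <- extract_clusters(make_ma_map(ma_vals, g2), 40, 20)
  expect_length(cs, 1)
  expect_equal(cs[[1]]$size, 27)
  expect_equal(cs[[1]]$peak_ma, 100L)
  # strictness: MA exactly at the threshold is excluded
  expect_length(extract_clusters(make_ma_map(ma_vals, g2), 100, 1), 0)
  # peak tie-break: lowest linear index among maxima
  expect_equal(cs[[1]]$peak_row, min(block))
  # diagonal-touching 12- and 10-voxel blocks: one 22-voxel cluster under
  # 26-connectivity, none at min size 20 under 6-connectivity
  ma2 <- integer(prod(g))
  b1 <- bwasr:::coords_to_linear(block_cluster(0:2, 0:1, 0:1), g)   # 12
  b2 <- bwasr:::coords_to_linear(block_cluster(3:7, 2:3, 2), g)    # 10
  ma2[c(b1, b2)] <- 50L
  cs26 <- extract_clusters(make_ma_map(ma2, g), 40, 20, connectivity = 26)
  expect_length(cs26, 1)
  expect_equal(cs26[[1]]$size, 22)
  cs6 <- extract_clusters(make_ma_map(ma2, g), 40, 20, connectivity = 6)
  expect_length(cs6, 0)
  cs6b <- extract_clusters(make_ma_map(ma2, g), 40, 5, connectivity = 6)
  expect_equal(sort(unname(vapply(cs6b, `[[`, integer(1), "size"))),
               c(10L, 12L))
})

test_that("subject order permutation leaves the link tests unchanged", {
  sim <- generate_cohort(quick_config(seed = 41))
  fc <- voxel_fc_fisher(sim$cohort)
  lt <- link_group_test(fc, sim$phenotype)
  set.seed(1)
  perm <- sample(length(sim$cohort$data))
  co_p <- voxel_cohort(sim$cohort$data[perm], sim$cohort$subject_ids[perm],
                       sim$cohort$grid_shape, sim$cohort$mask_index)
  lt_p <- link_group_test(voxel_fc_fisher(co_p), sim$phenotype[perm, ])
  expect_equal(lt$t, lt_p$t, tolerance = 1e-10)
})
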