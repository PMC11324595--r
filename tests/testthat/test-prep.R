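test_that("friston24 expansion has the declared structure", {
  set.seed(1)
  m <- matrix(rnorm(60), 10, 6)
  X <- friston24(m)
  expect_equal(ncol(X), 24)
  expect_equal(X[, 1:6], m, ignore_attr = TRUE)
  expect_equal(X[, 7:12], m^2, ignore_attr = TRUE)
  expect_equal(X[, 13:18], rbind(0, m[-10, ]), ignore_attr = TRUE)
  expect_equal(X[, 19:24], rbind(0, m[-10, ])^2, ignore_attr = TRUE)
  expect_true(all(friston24(matrix(0, 5, 6)) == 0))
  # single step at t = 3 appears in the lag column at t = 4
  m1 <- matrix(0, 5, 6); m1[3, 1] <- 2
  X1 <- friston24(m1)
  expect_equal(which(X1[, "p1"] != 0), 3L)
  expect_equal(which(X1[, "p1_lag"] != 0), 4L)
  expect_equal(unname(X1[4, "p1_lag_sq"]), 4)
  expect_error(friston24(matrix(0, 5, 5)), "6 columns")
})

test_that("fd_power follows the backward-difference sphere convention", {
  expect_equal(fd_power(matrix(0, 10, 6))$fd, rep(0, 10))
  # 1 mm x-translation step at t = 4
  m <- matrix(0, 6, 6); m[4:6, 1] <- 1
  fd <- fd_power(m)
  expect_equal(fd$fd, c(0, 0, 0, 1, 0, 0))
  expect_equal(fd$mean_fd, 1 / 6)
  # 0.02 rad rotation step -> 50 * 0.02 = 1 mm
  mr <- matrix(0, 5, 6); mr[3:5, 5] <- 0.02
  expect_equal(fd_power(mr)$fd[3], 1.0)
  expect_equal(fd_power(mr, head_radius_mm = 100)$fd[3], 2.0)
  m[2, 2] <- NA
  expect_error(fd_power(m), "non-finite")
})

test_that("regress_nuisance residuals match the normal-equations oracle", {
  set.seed(42)
  T <- 50
  X <- nuisance_design(matrix(rnorm(T * 6, sd = 0.1), T, 6),
                       wm = rnorm(T), csf = rnorm(T))
  Y <- matrix(rnorm(10 * T), 10, T)
  R <- regress_nuisance(Y, X)
  # oracle: explicit normal equations per voxel
  XtXi <- solve(t(X) %*% X)
  for (v in 1:10) {
    beta <- XtXi %*% t(X) %*% Y[v, ]
    expect_equal(R[v, ], as.numeric(Y[v, ] - X %*% beta), tolerance = 1e-8)
  }
  # residuals orthogonal to every design column
  expect_lt(max(abs(R %*% X)), 1e-8)
  # a voxel equal to a design column vanishes
  expect_lt(max(abs(regress_nuisance(rbind(X[, 3]), X))), 1e-10)
  # rank-deficient design is refused with the offending column named
  Xbad <- cbind(X, wm_copy = X[, "wm"])
  expect_error(regress_nuisance(Y, Xbad), "wm")
})

test_that("bandpass keeps passband and removes DC and stopband", {
  T <- 200; tr <- 2
  t_sec <- (0:(T - 1)) * tr
  amp_at <- function(x, f) {
    sp <- abs(fft(x)); sp[1 + round(f * T * tr)]
  }
  # constant series -> zero
  expect_lt(max(abs(bandpass(matrix(5, 1, T), tr))), 1e-10)
  # 0.05 Hz sinusoid retained >= 90%
  s_pass <- sin(2 * pi * 0.05 * t_sec)
  out <- bandpass(rbind(s_pass), tr)
  expect_gte(amp_at(out[1, ], 0.05) / amp_at(s_pass, 0.05), 0.9)
  # 0.2 Hz sinusoid attenuated <= 10%
  s_stop <- sin(2 * pi * 0.2 * t_sec)
  out2 <- bandpass(rbind(s_stop), tr)
  expect_lte(amp_at(out2[1, ], 0.2) / amp_at(s_stop, 0.2), 0.1)
  # linearity
  set.seed(1); a <- rnorm(T); b <- rnorm(T)
  expect_equal(bandpass(rbind(a + 2 * b), tr),
               bandpass(rbind(a), tr) + 2 * bandpass(rbind(b), tr),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(bandpass(rbind(a), tr, high_hz = 0.3), "Nyquist")
})

test_that("gaussian_smooth matches the sampled separable kernel", {
  g <- c(11, 11, 11)
  vol <- array(0, g); vol[6, 6, 6] <- 1
  fwhm <- 8; vs <- 4
  out <- gaussian_smooth(vol, fwhm, vs)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / vs
  r <- ceiling(4 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  for (dx in -2:2) for (dy in -2:2) for (dz in -2:2) {
    expect_equal(out[6 + dx, 6 + dy, 6 + dz],
                 k[r + 1 + dx] * k[r + 1 + dy] * k[r + 1 + dz],
                 tolerance = 1e-10)
  }
  expect_equal(sum(out), 1, tolerance = 1e-10)   # kernel mass conserved
  # identity and constancy
  expect_identical(gaussian_smooth(vol, 0, vs), vol)
  const <- array(3, c(5, 5, 5))
  expect_equal(gaussian_smooth(const, 8, 4), const, tolerance = 1e-10)
  expect_error(gaussian_smooth(vol, -1, vs), "fwhm")
})

test_that("intracranial volume is the plain tissue sum", {
  expect_equal(intracranial_volume(700, 500, 216.22), 1416.22)
  expect_equal(intracranial_volume(0, 0, 0), 0)
  set.seed(3)
  for (i in 1:5) {
    v <- runif(3, 0, 900)
    expect_equal(intracranial_volume(v[1], v[2], v[3]), sum(v))
  }
  expect_error(intracranial_volume(-1, 0, 0), "nonnegative")
})

test_that("prep_subject runs the fixed chain and is deterministic", {
  set.seed(9)
  g <- c(4, 4, 3); T <- 80
  Y <- matrix(rnorm(prod(g) * T), prod(g), T)
  motion <- apply(matrix(rnorm(T * 6, sd = 0.02), T, 6), 2, cumsum)
  out1 <- prep_subject(Y, motion, tr_seconds = 2, fwhm_mm = 8,
                       voxel_size_mm = 4, grid_shape = g)
  out2 <- prep_subject(Y, motion, tr_seconds = 2, fwhm_mm = 8,
                       voxel_size_mm = 4, grid_shape = g)
  expect_identical(out1, out2)
  expect_equal(dim(out1), dim(Y))
  # band-pass output has no DC component
  expect_lt(max(abs(rowMeans(out1))), 1e-10)
})
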