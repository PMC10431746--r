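test_that("data covariance: white noise gives ~identity, degenerate channels show rank structure", {
  set.seed(2)
  ep <- segment_rest(sensor_recording(matrix(rnorm(6 * 60000), 6), 1000), 2000)
  C <- compute_data_covariance(ep)
  expect_equal(max(abs(C - t(C))), 0)
  expect_true(all(abs(diag(C) - 1) < 0.05))
  expect_true(all(abs(C[upper.tri(C)]) < 0.05))
  ## duplicated channel pair: singular 2x2 block
  x <- matrix(rnorm(3 * 4000), 3)
  x <- rbind(x, x[3, ])
  Cd <- compute_data_covariance(segment_rest(sensor_recording(x, 1000), 2000))
  expect_lt(abs(det(Cd[3:4, 3:4])), 1e-12 * Cd[3, 3]^2)
  ## single nonzero channel: rank 1
  y <- matrix(0, 3, 4000)
  y[2, ] <- rnorm(4000)
  Cy <- compute_data_covariance(segment_rest(sensor_recording(y, 1000), 2000))
  expect_equal(sum(eigen(Cy)$values > 1e-12 * max(Cy)), 1L)
  expect_error(compute_data_covariance(segment_rest(
    sensor_recording(matrix(rnorm(8000), 2), 1000), 2000), c(5000, 6000)),
    "empty")
})

test_that("median-eigenvalue regularization floors the spectrum at the median", {
  ## constructed spectrum {1..5} -> {3,3,3,4,5}
  set.seed(5)
  Q <- qr.Q(qr(matrix(rnorm(25), 5)))
  C <- Q %*% diag(c(1, 2, 3, 4, 5)) %*% t(Q)
  R <- regularize_median_eig(C)
  expect_equal(sort(eigen(R)$values), c(3, 3, 3, 4, 5), tolerance = 1e-9)
  ## eigenvectors unchanged: R and C commute on the upper eigenspace
  expect_equal(R %*% Q[, 5], C %*% Q[, 5], tolerance = 1e-9)
  ## all-equal spectrum: identity transformation
  C2 <- Q %*% diag(rep(2, 5)) %*% t(Q)
  expect_equal(unclass(regularize_median_eig(C2)), C2, tolerance = 1e-10,
               ignore_attr = TRUE)
  ## random SPD matrices against an independent eigen-solve oracle
  for (s in 1:20) {
    M <- random_spd(7, 100 + s)
    ev <- eigen(M, symmetric = TRUE)$values      # oracle spectrum
    want <- sort(pmax(ev, median(ev)))
    got <- sort(eigen(regularize_median_eig(M), symmetric = TRUE)$values)
    expect_equal(got, want, tolerance = 1e-9)
  }
  ## never decreases an eigenvalue; condition number bounded by max/median
  M <- random_spd(10, 77)
  ev <- eigen(M, symmetric = TRUE)$values
  rv <- eigen(regularize_median_eig(M), symmetric = TRUE)$values
  expect_true(all(sort(rv) >= sort(ev) - 1e-10))
  expect_lte(max(rv) / min(rv), max(ev) / median(ev) + 1e-9)
  ## non-symmetric input rejected
  expect_error(regularize_median_eig(matrix(1:9, 3)), "symmetric")
})

test_that("LCMV weights have unit gain, the closed form under C = I, and covariance-scale invariance", {
  geo <- tiny_geometry()
  src <- geo$src
  ## closed form: C = I and the constrained lead field l gives w = l / (l'l)
  lf <- geo$lf_free
  C <- diag(nrow(lf))
  w_lf <- lcmv_weights(lf, C, src$normals, orientation = "leadfield")
  v <- 60L
  l <- unclass(geo$lf_con)[, v]
  expect_equal(unclass(w_lf)[v, ], l / sum(l^2), tolerance = 1e-9)
  ## unit gain for both projection conventions
  w_w <- lcmv_weights(lf, C, src$normals, orientation = "weights")
  gains_lf <- rowSums(unclass(w_lf) * t(unclass(geo$lf_con)))
  gains_w <- rowSums(unclass(w_w) * t(unclass(geo$lf_con)))
  expect_true(all(abs(gains_lf - 1) < 1e-6))
  expect_true(all(abs(gains_w - 1) < 1e-6))
  ## scaling the covariance leaves the weights unchanged
  M <- random_spd(nrow(lf), 42) * 1e-26
  w1 <- lcmv_weights(lf, M, src$normals)
  w2 <- lcmv_weights(lf, 7.3 * M, src$normals)
  expect_equal(unclass(w1), unclass(w2), tolerance = 1e-8)
})

test_that("apply_inverse is linear and zero maps to zero", {
  geo <- tiny_geometry()
  W <- lcmv_weights(geo$lf_free, diag(48), geo$src$normals)
  z <- matrix(0, 48, 100)
  expect_true(all(apply_inverse(W, z) == 0))
  set.seed(1)
  a <- matrix(rnorm(4800), 48)
  b <- matrix(rnorm(4800), 48)
  expect_equal(apply_inverse(W, a + b),
               apply_inverse(W, a) + apply_inverse(W, b), tolerance = 1e-9)
  expect_error(apply_inverse(W, matrix(0, 5, 10)), "dimensions")
})

test_that("a planted source is localized and its time course reconstructed", {
  cfg <- tiny_cfg()
  geo <- tiny_geometry(cfg)
  set.seed(33)
  v <- 111L
  n <- 20000
  sig <- matrix(5e-8 * somameg:::.band_carrier(n, band_spec("beta"), 1000), 1)
  stc <- structure(list(data = sig, vertices = v,
                        n_vertices = geo$src$n_vertices, sfreq = 1000),
                   class = "source_tc")
  clean <- unclass(geo$lf_con)[, v, drop = FALSE] %*% sig
  rec <- mix_to_sensors(stc, geo$lf_con, sqrt(mean(clean^2)) / 5, sfreq = 1000,
                        sensors = geo$sensors)
  ep <- segment_rest(rec, 2000)
  C <- compute_data_covariance(ep)
  w <- lcmv_weights(geo$lf_free, regularize_median_eig(C), geo$src$normals)
  est_v <- which.max(beamformer_nai(w, C))
  expect_lte(mesh_edge_distance(geo$src, v, est_v), 1)
  ## reconstructed time course at the true vertex matches the planted source
  est <- unclass(w)[v, , drop = FALSE] %*% rec$data
  expect_gt(abs(cor(as.vector(est), sig[1, ])), 0.9)
})
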