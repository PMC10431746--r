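test_that("average_evoked is the per-condition mean and permutation-invariant", {
  set.seed(3)
  d <- array(rnorm(6 * 4 * 50), c(6, 4, 50))
  ep <- somameg:::.epoch_set(d, seq_len(50), 1000, "evoked",
                             condition = rep(c("SP", "PP"), each = 3))
  m <- average_evoked(ep, "SP")
  expect_equal(unclass(m), apply(d[1:3, , ], c(2, 3), mean), tolerance = 1e-12,
               ignore_attr = TRUE)
  ## identical epochs: the average is any one epoch
  d2 <- d
  for (e in 1:6) d2[e, , ] <- d[1, , ]
  ep2 <- somameg:::.epoch_set(d2, seq_len(50), 1000, "evoked",
                              condition = rep("SP", 6))
  expect_equal(unclass(average_evoked(ep2, "SP")), d[1, , ],
               tolerance = 1e-12, ignore_attr = TRUE)
  ## permuting epochs leaves the mean unchanged
  ep3 <- somameg:::.epoch_set(d[c(3, 1, 2, 6, 4, 5), , ], seq_len(50), 1000,
                              "evoked", rep(c("SP", "PP"), each = 3)[c(3, 1, 2, 6, 4, 5)])
  expect_equal(average_evoked(ep3, "SP"), m, tolerance = 1e-12)
  ## noise-only amplitude shrinks like 1/sqrt(n)
  set.seed(9)
  big <- array(rnorm(400 * 2 * 100), c(400, 2, 100))
  epb <- somameg:::.epoch_set(big, 1:100, 1000, "evoked", rep("SP", 400))
  expect_equal(sd(average_evoked(epb, "SP")), 1 / sqrt(400), tolerance = 0.15)
})

test_that("ROI scouts centre on the activation peak with fixed size and scale invariance", {
  src <- small_mesh(2)
  times <- seq(-100, 150)
  map <- matrix(0, src$n_vertices, length(times))
  map[77, times >= 20 & times <= 26] <- 5
  sc <- define_roi_scout(map, times, c(20, 26), src)
  expect_equal(sc$center, 77L)
  expect_length(sc$vertices, 10L)
  sc2 <- define_roi_scout(2 * map, times, c(20, 26), src)
  expect_identical(sc$vertices, sc2$vertices)
  ## negative deflections count through the absolute value
  sc3 <- define_roi_scout(-map, times, c(20, 26), src)
  expect_equal(sc3$center, 77L)
  expect_error(define_roi_scout(matrix(1, src$n_vertices, length(times)),
                                times, c(20, 26), src), "flat")
  ## candidate restriction wins over a larger out-of-region peak
  map[5, times >= 20 & times <= 26] <- 50
  sc4 <- define_roi_scout(map, times, c(20, 26), src,
                          candidates = mesh_neighborhood(src, 77, 30))
  expect_equal(sc4$center, 77L)
})

test_that("subtraction, realignment, and rectification behave as stated", {
  times <- seq(-150, 250)
  sp <- matrix(rnorm(3 * length(times), sd = 0.01), 3)
  pp <- sp + 1
  expect_equal(subtract_sp_from_pp(pp, sp), pp - sp, ignore_attr = TRUE)
  expect_equal(subtract_sp_from_pp(sp, pp), -(pp - sp), ignore_attr = TRUE)
  expect_error(subtract_sp_from_pp(pp[, 1:10], sp), "shapes")
  ## a peak at 122 ms lands at 22 ms after the -100 ms shift
  wave <- matrix(0, 1, length(times))
  wave[1, times == 122] <- 4
  sh <- shift_rectify_baseline(wave, times, shift_ms = 100)
  expect_equal(sh$times[which.max(sh$map[1, ])], 22)
  expect_true(all(sh$map >= 0))
  expect_error(shift_rectify_baseline(wave, times, shift_ms = 1000), "baseline")
})

test_that("peak_in_window matches a brute-force scan and resolves ties to the earliest latency", {
  times <- seq(0, 100)
  w <- sin(times / 7) + 0.001 * times
  pk <- peak_in_window(w, times, c(20, 60))
  sel <- which(times >= 20 & times <= 60)
  expect_equal(pk$amplitude, max(w[sel]))
  expect_equal(pk$latency_ms, times[sel][which.max(w[sel])])
  ## constructed peak
  w2 <- numeric(101); w2[times == 22] <- 5
  expect_equal(peak_in_window(w2, times, c(20, 26)),
               list(amplitude = 5, latency_ms = 22))
  ## monotone segment peaks at the right edge
  expect_equal(peak_in_window(times / 10, times, c(30, 50))$latency_ms, 50)
  ## ties -> earliest
  w3 <- rep(1, 101)
  expect_equal(peak_in_window(w3, times, c(40, 60))$latency_ms, 40)
  expect_error(peak_in_window(w, times, c(300, 400)), "empty")
})

test_that("gating ratio handles trivial and degenerate peaks", {
  expect_equal(gating_ratio(3, 3), 1)
  expect_equal(gating_ratio(0, 3), 0)
  expect_warning(r <- gating_ratio(1, 0), "undefined")
  expect_true(is.na(r))
})

test_that("gating ratios are invariant to a global amplitude rescaling", {
  src <- small_mesh(2)
  times <- seq(-150, 250)
  set.seed(21)
  sp <- matrix(rnorm(src$n_vertices * length(times), sd = 0.05), src$n_vertices)
  resp <- exp(-0.5 * ((times - 22) / 3)^2)
  sp[25, ] <- sp[25, ] + 3 * resp
  pp <- sp + matrix(rnorm(length(sp), sd = 0.05), nrow(sp))
  pp[25, ] <- pp[25, ] + 1.5 * exp(-0.5 * ((times - 122) / 3)^2)
  g1 <- compute_gating(sp, pp, times, src)
  g2 <- compute_gating(10 * sp, 10 * pp, times, src)
  expect_equal(g1$ratio, g2$ratio, tolerance = 1e-12)
  expect_equal(g1$center_vertex, g2$center_vertex)
  expect_equal(g1$sp_amp * 10, g2$sp_amp, tolerance = 1e-12)
})
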