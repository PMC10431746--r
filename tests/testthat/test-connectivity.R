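test_that("FIR band filter: in-band gain ~1, stop-band suppressed, even order enforced", {
  fs <- 1000
  t <- seq_len(8000) / fs
  beta <- band_spec("beta")
  y20 <- fir_band_filter(sin(2 * pi * 20 * t), beta, fs)
  y5 <- fir_band_filter(sin(2 * pi * 5 * t), beta, fs)
  mid <- 2000:6000
  expect_equal(sqrt(2 * mean(y20[mid]^2)), 1, tolerance = 0.05)
  expect_lt(sqrt(2 * mean(y5[mid]^2)), 0.05)
  expect_error(fir_band_filter(rnorm(1000), beta, fs, order = 201), "even")
  expect_error(fir_band_filter(rnorm(100), beta, fs, order = 200), "shorter")
  expect_error(fir_band_filter(rnorm(1000), band_spec(c(100, 600)), 1000),
               "Nyquist")
  ## canonical bands resolve to the study values
  expect_equal(c(band_spec("alpha")$low_hz, band_spec("alpha")$high_hz), c(8, 12))
  expect_equal(c(beta$low_hz, beta$high_hz), c(15, 29))
})

test_that("analytic envelope recovers amplitude structure", {
  fs <- 1000
  t <- seq_len(4000) / fs
  x <- sin(2 * pi * 21 * t)
  env <- analytic_envelope(x)
  interior <- 200:3800
  expect_true(all(abs(env[interior] - 1) < 0.02))
  ## slow AM: envelope tracks the modulator
  a <- 1 + 0.5 * sin(2 * pi * 1.5 * t)
  env_am <- analytic_envelope(a * sin(2 * pi * 25 * t))
  expect_lt(max(abs(env_am[interior] - a[interior])), 0.05)
  ## absolute homogeneity
  expect_equal(analytic_envelope(-3 * x), 3 * analytic_envelope(x),
               tolerance = 1e-10)
})

test_that("orthogonalization removes zero-lag leakage and preserves quadrature signal", {
  fs <- 1000
  t <- seq_len(6000) / fs
  set.seed(6)
  sm <- somameg:::.smooth_gp
  env1 <- exp(0.5 * sm(6000, 100))
  env2 <- exp(0.5 * sm(6000, 100))
  s <- analytic_signal(env1 * cos(2 * pi * 22 * t))
  ## pure leakage: a real multiple of the seed orthogonalizes to ~0
  o <- orthogonalize_pair(s, 3.7 * s)
  expect_lt(max(abs(o)), 1e-8 * max(Mod(s)))
  ## quadrature signal with independent envelope: AEC essentially unchanged
  q <- analytic_signal(env2 * sin(2 * pi * 22 * t))
  trim <- 500:5500
  r_naive <- aec(Mod(s)[trim], Mod(q)[trim])
  r_orth <- aec(Mod(s)[trim], abs(orthogonalize_pair(s, q))[trim])
  expect_lt(abs(r_orth - r_naive), 0.1)
  expect_error(orthogonalize_pair(complex(real = numeric(5)), s[1:5]), "zero")
})

test_that("one mixed source gives naive AEC ~1 but orthogonalized AEC ~0", {
  fs <- 1000
  t <- seq_len(6000) / fs
  set.seed(8)
  env <- exp(0.5 * somameg:::.smooth_gp(6000, 100))
  x <- env * cos(2 * pi * 20 * t + cumsum(rnorm(6000, sd = 0.02)))
  ## two channels see the same source with different real gains
  a1 <- analytic_signal(1.0 * x)
  a2 <- analytic_signal(0.6 * x)
  trim <- 500:5500
  naive <- aec(Mod(a1)[trim], Mod(a2)[trim])
  orth <- aec(Mod(a1)[trim], abs(orthogonalize_pair(a1, a2))[trim])
  expect_gt(naive, 0.99)
  expect_lt(abs(orth), 0.25)
})

test_that("aec handles trivial and degenerate envelope pairs", {
  e <- abs(rnorm(100)) + 0.1
  expect_equal(aec(e, e), 1)
  expect_equal(aec(e, -2 * e + 5), -1)
  expect_true(is.na(aec(e, rep(1, 100))))
  set.seed(1)
  expect_lt(abs(aec(abs(rnorm(20000)), abs(rnorm(20000)))), 0.03)
  expect_error(aec(e, e[1:50]), "lengths")
})

test_that("seed_fc_map has map semantics: length V, epoch-order invariance, bounded values", {
  set.seed(12)
  E <- 4; V <- 30; S <- 2000
  arr <- array(rnorm(E * V * S), c(E, V, S))
  m1 <- seed_fc_map(arr, seed_vertices = 1:3, band = "beta", sfreq = 1000)
  expect_length(m1, V)
  expect_true(all(abs(m1[is.finite(m1)]) <= 1))
  ## permuting the epoch order changes nothing (averaging commutes)
  m2 <- seed_fc_map(arr[c(3, 1, 4, 2), , ], 1:3, "beta", sfreq = 1000)
  expect_identical(as.numeric(m1), as.numeric(m2))
  expect_error(seed_fc_map(arr, c(1, 1, 2), "beta", sfreq = 1000), "distinct")
  expect_error(seed_fc_map(arr[1, , , drop = FALSE], 1:3, "beta", sfreq = 1000),
               "2 epochs")
})

test_that("bidirectional AEC is symmetric under role exchange", {
  set.seed(13)
  arr <- array(rnorm(3 * 2 * 2000), c(3, 2, 2000))
  m_a <- seed_fc_map(arr, 1L, "beta", sfreq = 1000)
  m_b <- seed_fc_map(arr[, c(2, 1), ], 1L, "beta", sfreq = 1000)
  ## value of vertex 2 seeded at 1 equals value of vertex 1 seeded at 2
  expect_equal(m_a[2], m_b[2], tolerance = 1e-12)
})
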