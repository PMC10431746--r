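make_rec <- function(x, fs = 1000) sensor_recording(matrix(x, 1), fs)

test_that("band-pass preserves in-band tones, kills DC, and notches line noise", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)[-1]
  tone20 <- sin(2 * pi * 20 * t)
  tone50 <- sin(2 * pi * 50 * t)
  f20 <- bandpass_notch(make_rec(tone20))$data[1, ]
  f50 <- bandpass_notch(make_rec(tone50))$data[1, ]
  fdc <- bandpass_notch(make_rec(rep(1, length(t))))$data[1, ]
  mid <- 2000:8000
  amp <- function(x) sqrt(2 * mean(x[mid]^2))
  expect_equal(amp(f20), 1, tolerance = 0.05)
  expect_lt(amp(f50), 0.03)
  expect_lt(max(abs(fdc[mid])), 1e-3)
})

test_that("filtering is linear and rejects invalid band edges", {
  fs <- 500
  set.seed(4)
  x <- matrix(rnorm(3 * 4000), 3)
  y <- matrix(rnorm(3 * 4000), 3)
  fx <- bandpass_notch(sensor_recording(x, fs), 1, 100, NULL)$data
  fy <- bandpass_notch(sensor_recording(y, fs), 1, 100, NULL)$data
  fxy <- bandpass_notch(sensor_recording(2 * x + y, fs), 1, 100, NULL)$data
  expect_equal(fxy, 2 * fx + fy, tolerance = 1e-9)
  expect_error(bandpass_notch(sensor_recording(x, fs), 1, 300, NULL), "Nyquist")
  expect_error(bandpass_notch(sensor_recording(x, fs), 0, 100, NULL), "Nyquist")
})

test_that("segment_rest cuts floor(duration/window) epochs and drops the remainder", {
  fs <- 1000
  rec <- make_rec(rnorm(10 * fs))
  ep <- segment_rest(rec, 2000)
  expect_equal(dim(ep$data), c(5L, 1L, 2000L))
  ## concatenation reproduces the leading samples
  expect_equal(as.vector(t(ep$data[, 1, ])), rec$data[1, 1:10000])
  ep2 <- segment_rest(make_rec(rnorm(2500)), 2000)
  expect_equal(dim(ep2$data)[1], 1L)
  expect_error(segment_rest(make_rec(rnorm(1900)), 2000), "shorter")
})

test_that("epoch_evoked makes one epoch per valid event and skips edge events", {
  fs <- 1000
  rec <- make_rec(rnorm(20 * fs))
  ev <- data.frame(sample = c(100L, 5000L, 9000L, 19900L),
                   condition = c("SP", "SP", "PP", "PP"))
  expect_warning(ep <- epoch_evoked(rec, ev), "skipped")
  expect_equal(dim(ep$data), c(2L, 1L, 4000L))   # (2500 - (-1500)) ms at 1 kHz
  expect_equal(ep$condition, c("SP", "PP"))
  expect_equal(range(ep$times), c(-1500, 2499))
})

test_that("baseline correction zeroes the window mean and is idempotent", {
  fs <- 1000
  ev <- data.frame(sample = 5000L, condition = "SP")
  rec <- make_rec(rnorm(10 * fs) + 5)
  ep <- suppressWarnings(epoch_evoked(rec, ev))
  bc <- baseline_correct(ep)
  sel <- bc$times >= -100 & bc$times <= -5
  expect_lt(abs(mean(bc$data[1, 1, sel])), 1e-10)
  bc2 <- baseline_correct(bc)
  expect_equal(bc2$data, bc$data, tolerance = 1e-12)
  ## constant signal becomes identically zero
  cep <- segment_rest(make_rec(rep(3, 4000)), 2000)
  cep$times <- cep$times - 200   # give it a pre-zero baseline window
  expect_true(all(abs(baseline_correct(cep, -100, -5)$data) < 1e-12))
  expect_error(baseline_correct(ep, -3000, -2900), "outside")
})

test_that("peak-to-peak rejection removes exactly the injected artifact", {
  set.seed(9)
  rec <- sensor_recording(matrix(rnorm(2 * 8000), 2), 1000)
  ep <- segment_rest(rec, 2000)
  ep$data[3, 2, 100] <- 50   # 10x-amplitude spike in epoch 3
  lim <- 10
  kept <- reject_trials(ep, lim)
  rej <- attr(kept, "rejection")
  expect_equal(rej$rejected, 3L)
  expect_equal(rej$n_rejected, 1L)
  expect_equal(dim(kept$data)[1], 3L)
  ## infinite limit is the identity
  all_kept <- reject_trials(ep, Inf)
  expect_equal(all_kept$data, ep$data)
  expect_error(reject_trials(ep, 1e-6), "all trials rejected")
})
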