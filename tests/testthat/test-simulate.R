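test_that("identical seeds reproduce bit-identical simulations; different seeds decorrelate", {
  cfg <- tiny_cfg(rest_duration = 4, rng_seed = 11)
  geo <- tiny_geometry(cfg)
  a <- simulate_source_rest(cfg, 1, geo)
  b <- simulate_source_rest(cfg, 1, geo)
  expect_identical(a$data, b$data)
  cfg2 <- tiny_cfg(rest_duration = 4, rng_seed = 12)
  c3 <- simulate_source_rest(cfg2, 1, geo)
  expect_lt(abs(cor(a$data[1, ], c3$data[1, ])), 0.2)
  ## subjects are independent streams of the same master seed
  d <- simulate_source_rest(cfg, 2, geo)
  expect_lt(abs(cor(a$data[1, ], d$data[1, ])), 0.2)
  ## ground truth records the planted values
  expect_equal(a$ground_truth$planted_env_corr, cfg$planted_env_corr)
  expect_equal(a$ground_truth$seed_vertex, geo$seed_vertex)
})

test_that("mixing is linear, additive, and validated", {
  cfg <- tiny_cfg(rest_duration = 2)
  geo <- tiny_geometry(cfg)
  V <- geo$src$n_vertices
  n <- 500
  s1 <- structure(list(data = matrix(sin(1:n / 5), 1), vertices = 10L,
                       n_vertices = V, sfreq = 1000), class = "source_tc")
  s2 <- structure(list(data = matrix(cos(1:n / 7), 1), vertices = 40L,
                       n_vertices = V, sfreq = 1000), class = "source_tc")
  r1 <- mix_to_sensors(s1, geo$lf_con, 0)
  ## noiseless single source: sensors proportional to that lead field column
  expect_equal(r1$data, unclass(geo$lf_con)[, 10] %o% s1$data[1, ],
               tolerance = 1e-12)
  ## superposition
  s12 <- structure(list(data = rbind(s1$data, s2$data),
                        vertices = c(10L, 40L), n_vertices = V, sfreq = 1000),
                   class = "source_tc")
  r2 <- mix_to_sensors(s2, geo$lf_con, 0)
  r12 <- mix_to_sensors(s12, geo$lf_con, 0)
  expect_equal(r12$data, r1$data + r2$data, tolerance = 1e-12)
  ## zero sources: sensor variance matches the noise variance
  z <- structure(list(data = matrix(0, 1, 20000), vertices = 1L,
                      n_vertices = V, sfreq = 1000), class = "source_tc")
  rn <- with_rng_seed(5, mix_to_sensors(z, geo$lf_con, 2.5))
  expect_equal(sd(rn$data), 2.5, tolerance = 0.02)
  ## dimension mismatch rejected
  expect_error(mix_to_sensors(s1, unclass(geo$lf_con)[, 1:50], 0), "match")
})

test_that("planted envelope correlations are recovered at the source level", {
  geo <- tiny_geometry()
  band <- band_spec("beta")
  env_corr <- function(stc, trim = 500) {
    e1 <- analytic_envelope(fir_band_filter(stc$data[1, ], band, 1000))
    e2 <- analytic_envelope(fir_band_filter(stc$data[2, ], band, 1000))
    n <- length(e1)
    cor(e1[trim:(n - trim)], e2[trim:(n - trim)])
  }
  ## shared envelope only: correlation essentially 1
  c1 <- env_corr(simulate_source_rest(tiny_cfg(rest_duration = 20,
                                               planted_env_corr = 1,
                                               n_background = 0,
                                               rng_seed = 3), 1, geo))
  expect_gte(c1, 0.99)
  ## independent envelopes: within 3 SE of zero (envelope processes are
  ## smoothed over 100 ms, so the effective sample count is duration / ~0.2 s)
  cfg0 <- tiny_cfg(rest_duration = 40, planted_env_corr = 0, n_background = 0,
                   rng_seed = 4)
  c0 <- env_corr(simulate_source_rest(cfg0, 1, geo))
  se <- 1 / sqrt(40 / 0.2)
  expect_lt(abs(c0), 3 * se)
  ## intermediate value: Monte-Carlo mean within the calibrated tolerance
  cs <- vapply(1:5, function(s) {
    env_corr(simulate_source_rest(tiny_cfg(rest_duration = 30,
                                           planted_env_corr = 0.6,
                                           n_background = 0,
                                           rng_seed = 20 + s), 1, geo))
  }, 0)
  expect_lt(abs(mean(cs) - 0.6), 0.1)
  ## degenerate request rejected
  bad <- tiny_cfg(rest_duration = 2)
  bad$target_vertices <- geo$seed_vertex
  expect_error(simulate_source_rest(bad, 1,
                                    modifyList(geo, list(target_vertices = geo$seed_vertex))),
               "degenerate")
})

test_that("evoked trials superpose: unit gating duplicates the response, zero gating cancels it", {
  cfg <- tiny_cfg(n_sp_trials = 3, n_pp_trials = 3, isi_range = c(1, 1.2),
                  noise_sd = 0, rng_seed = 8,
                  planted_gating = c(N20m = 1, P35m = 1, P60m = 1))
  geo <- tiny_geometry(cfg)
  ev <- simulate_evoked_trials(cfg, 1, geo)
  sp_ev <- ev$events[ev$events$condition == "SP", ]
  pp_ev <- ev$events[ev$events$condition == "PP", ]
  shift <- 100
  win <- 0:119
  sp_resp <- ev$recording$data[, sp_ev$sample[1] + win]
  pp_first <- ev$recording$data[, pp_ev$sample[1] + win]
  pp_second <- ev$recording$data[, pp_ev$sample[1] + shift + win]
  ## gating 1: second response identical to the first, shifted 100 ms
  expect_equal(pp_second, pp_first, tolerance = 1e-12)
  expect_equal(sp_resp, pp_first, tolerance = 1e-12)
  ## gating 0: PP trials identical to SP trials
  cfg0 <- cfg
  cfg0$planted_gating <- c(N20m = 0, P35m = 0, P60m = 0)
  ev0 <- simulate_evoked_trials(cfg0, 1, geo)
  pp0 <- ev0$events[ev0$events$condition == "PP", ]
  sp0 <- ev0$events[ev0$events$condition == "SP", ]
  expect_equal(ev0$recording$data[, pp0$sample[1] + c(win, shift + win)],
               ev0$recording$data[, sp0$sample[1] + c(win, shift + win)],
               tolerance = 1e-12)
  ## negative gating rejected
  expect_error(sim_config(planted_gating = c(N20m = -0.1, P35m = 1, P60m = 1)),
               ">= 0")
})

test_that("behavioral responses follow the logistic psychometric model", {
  ## at the threshold distance the two-point rate converges to 0.5
  tab <- simulate_behavior(2.5, 3, distances = 2.5, trials_per_distance = 4000,
                           rng_seed = 2)
  expect_equal(mean(tab$response == "two_point"), 0.5, tolerance = 0.03)
  ## a steep slope is a step function around the threshold
  tab2 <- simulate_behavior(2.5, 1e4, trials_per_distance = 20, rng_seed = 3)
  p <- tapply(tab2$response == "two_point", tab2$distance, mean)
  d <- as.numeric(names(p))
  expect_true(all(p[d < 2.5] == 0))
  expect_true(all(p[d > 2.5] == 1))
  expect_error(simulate_behavior(2.5, 3, distances = numeric(0)), "empty")
  expect_error(simulate_behavior(2.5, -1), "positive")
})

test_that("cohort ground truth couples connectivity to thresholds with the planted slope", {
  cfg <- tiny_cfg(n_subjects = 40, coupling_slope = -2, rng_seed = 6)
  geo <- tiny_geometry(cfg)
  co <- simulate_cohort(cfg, geo)
  expect_equal(nrow(co$truth), 40L)
  ## noiseless coupling: strictly monotone map, Spearman R exactly -1
  cfg2 <- tiny_cfg(n_subjects = 20, coupling_slope = -2,
                   coupling_noise_sd = 1e-9, rng_seed = 7)
  co2 <- simulate_cohort(cfg2, geo)
  expect_equal(cor(co2$truth$planted_env_corr, co2$truth$true_threshold,
                   method = "spearman"), -1)
  ## zero coupling: correlation scattered around zero
  cfg3 <- tiny_cfg(n_subjects = 40, coupling_slope = 0, rng_seed = 8)
  co3 <- simulate_cohort(cfg3, geo)
  r0 <- cor(co3$truth$planted_env_corr, co3$truth$true_threshold)
  expect_lt(abs(r0), 0.45)
  ## per-subject behavioral tables reflect each subject's true threshold
  s_thr <- co$truth$true_threshold[5]
  fit <- fit_psychometric(co$behavior[co$behavior$subject == 5, ])
  expect_lt(abs(fit$threshold - s_thr), 0.5)
})
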