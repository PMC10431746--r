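## Synthetic-cohort generator. Plants known ground truth at every level the
## analysis chain later estimates: band-limited cortical oscillators whose
## amplitude envelopes have a prescribed correlation with the seed (rest),
## stereotyped three-component evoked responses with a prescribed paired-pulse
## attenuation per component (evoked), Bernoulli responses from a logistic
## psychometric function (behavior), and a cohort in which per-subject
## envelope correlation linearly drives the discrimination threshold.
##
## Envelope construction: each active vertex carries, per band, a
## constant-modulus band-limited carrier multiplied by a log-normal envelope
## exp(sigma * z) where z is a smoothed unit-variance Gaussian process. The
## target's z mixes the seed's process with an independent one,
## z = a * z_seed + sqrt(1 - a^2) * z_own, and the lognormal correlation
## identity corr(exp(s z1), exp(s z2)) = (exp(rho s^2)-1)/(exp(s^2)-1)
## gives the closed-form calibration a = log(1 + rho_env (e^{s^2}-1)) / s^2
## that makes the planted envelope correlation exact.

#' Simulation configuration
#'
#' Collects every generator parameter with the study's acquisition values as
#' defaults: 1000 Hz sampling, 5 min of rest, ~300 single-pulse and ~300
#' paired-pulse stimulations with 3.5-4.5 s between trials and 100 ms within
#' a pair, and the 10-distance x 16-trial two-point discrimination design.
#'
#' @param n_subjects cohort size (>= 8 for a cohort run).
#' @param rng_seed master seed; per-subject streams are derived with
#'   [subject_seed()].
#' @param sfreq sampling rate, Hz.
#' @param rest_duration rest recording length, s.
#' @param n_sp_trials,n_pp_trials evoked trial counts per condition.
#' @param bands character vector of carrier bands for the rest oscillators
#'   (`"alpha"`, `"beta"`).
#' @param seed_vertex,target_vertices vertex indices of the seed ("S1") and
#'   the connected targets; `NULL` resolves them from the geometry (seed at a
#'   left-central direction, targets spread over the surface).
#' @param planted_env_corr envelope correlation in `[0, 1]` between seed and
#'   each target.
#' @param planted_gating named per-component paired-pulse attenuation factors
#'   (N20m, P35m, P60m), each >= 0.
#' @param threshold_mm,psy_slope psychometric truth for a single subject
#'   (50% point in mm; slope in 1/mm).
#' @param distances stimulus pin distances, mm.
#' @param trials_per_distance trials per distance.
#' @param coupling_intercept,coupling_slope,coupling_noise_sd cohort-level
#'   linear model `threshold = intercept + slope * env_corr + noise`;
#'   negative slope makes strong connectivity predict lower (better)
#'   thresholds.
#' @param env_corr_range per-subject planted envelope correlations are drawn
#'   uniformly from this interval in cohort mode.
#' @param snr rest-recording sensor SNR (rms of the clean sensor signal over
#'   the noise SD) used when `noise_sd` is `NULL`.
#' @param evoked_snr evoked single-trial SNR (peak clean sensor amplitude
#'   over noise SD) used when `noise_sd` is `NULL`.
#' @param noise_sd explicit sensor noise SD (overrides the SNR rules).
#' @param source_amp oscillator amplitude, A m.
#' @param evoked_amp,evoked_latency_ms,evoked_width_ms amplitudes (A m),
#'   latencies and Gaussian widths (ms) of the three evoked deflections
#'   (nominal 22/33/58 ms, inside the component analysis windows).
#' @param env_log_sd log-envelope SD (modulation depth).
#' @param env_smooth_ms Gaussian smoothing SD of the envelope process, ms.
#' @param source_patch_size number of mesh vertices over which each active
#'   source (seed, targets, evoked response) extends coherently. The default
#'   of 1 (point sources) reflects the coarse synthetic meshes, on which an
#'   extended perfectly coherent patch has a topography distinguishable from
#'   the centre lead field and is partially cancelled by the minimum-variance
#'   filter; the 10-vertex analysis scouts still capture point sources
#'   through the inverse operator's point spread.
#' @param n_background number of inactive vertices that carry independent
#'   band-limited background activity.
#' @param background_scale amplitude of background sources relative to the
#'   active oscillators.
#' @param isi_range inter-trial interval range, s.
#' @param pp_isi_ms interval between the two pulses of a pair, ms.
#' @param mesh_subdivisions,n_sensors geometry used when none is supplied.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 8,
                       rng_seed = 1,
                       sfreq = 1000,
                       rest_duration = 300,
                       n_sp_trials = 300,
                       n_pp_trials = 300,
                       bands = "beta",
                       seed_vertex = NULL,
                       target_vertices = NULL,
                       planted_env_corr = 0.6,
                       planted_gating = c(N20m = 0.5, P35m = 0.6, P60m = 0.7),
                       threshold_mm = 2.5,
                       psy_slope = 3,
                       distances = c(0, 1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5),
                       trials_per_distance = 16,
                       coupling_intercept = 3.58,
                       coupling_slope = -2,
                       coupling_noise_sd = 0.3,
                       env_corr_range = c(0.15, 0.85),
                       snr = 5,
                       evoked_snr = 1,
                       noise_sd = NULL,
                       source_amp = 5e-8,
                       evoked_amp = c(35, 45, 40) * 1e-9,
                       evoked_latency_ms = c(22, 33, 58),
                       evoked_width_ms = c(2.5, 3.5, 8),
                       env_log_sd = 0.5,
                       env_smooth_ms = 100,
                       source_patch_size = 1,
                       n_background = 64,
                       background_scale = 1,
                       isi_range = c(3.5, 4.5),
                       pp_isi_ms = 100,
                       mesh_subdivisions = 3,
                       n_sensors = 102) {
  cfg <- as.list(environment())
  .assert(sfreq > 0, "sfreq must be positive")
  .assert(rest_duration > 0, "rest_duration must be positive")
  .assert(.is_count(n_sp_trials) && .is_count(n_pp_trials), "trial counts must be positive integers")
  .assert(planted_env_corr >= 0 && planted_env_corr <= 1,
          "planted_env_corr must be in [0, 1]")
  .assert(all(planted_gating >= 0), "planted_gating must be >= 0")
  .assert(psy_slope > 0, "psychometric slope must be positive")
  .assert(length(distances) >= 1 && all(distances >= 0),
          "distances must be non-negative")
  .assert(all(is.finite(rng_seed)) && rng_seed == round(rng_seed),
          "rng_seed must be an integer")
  .assert(env_log_sd > 0, "env_log_sd must be positive")
  .assert(isi_range[1] > 0 && isi_range[1] <= isi_range[2], "bad isi_range")
  structure(cfg, class = "sim_config")
}

#' Build the shared geometry for a simulation
#'
#' Constructs the source space, the sensor array, the free-orientation lead
#' field, and its normal-constrained form, and resolves default seed/target
#' vertices. Built once per cohort and shared by all subjects.
#'
#' @param config a `sim_config`.
#' @return list with `src`, `sensors`, `lf_free`, `lf_con`, `seed_vertex`,
#'   `target_vertices`.
#' @export
sim_geometry <- function(config) {
  .assert(inherits(config, "sim_config"), "need a sim_config")
  src <- cortical_mesh(subdivisions = config$mesh_subdivisions)
  sensors <- sensor_array(n_sites = config$n_sensors)
  lf_free <- sphere_forward(src, sensors, mode = "free")
  lf_con <- constrain_leadfield(lf_free, src$normals)
  seedv <- config$seed_vertex %||% nearest_vertex(src, c(-0.45, -0.3, 0.85))
  targets <- config$target_vertices %||% vapply(
    list(c(-0.3, -0.9, -0.2),   # posterior parietal-ish
         c(-0.85, 0.2, -0.4),   # temporal-ish
         c(0.55, 0.55, 0.6)),   # contralateral parietal-ish
    function(d) nearest_vertex(src, d), 0L)
  .assert(!(seedv %in% targets), "seed vertex coincides with a target")
  list(src = src, sensors = sensors, lf_free = lf_free, lf_con = lf_con,
       seed_vertex = as.integer(seedv), target_vertices = as.integer(targets))
}

## smoothed, standardized Gaussian process of length n (FFT convolution with
## a Gaussian kernel of SD smooth_samples)
.smooth_gp <- function(n, smooth_samples) {
  z <- rnorm(n)
  if (smooth_samples <= 0) return(as.vector(scale(z)))
  half <- ceiling(4 * smooth_samples)
  k <- exp(-0.5 * ((-half):half / smooth_samples)^2)
  k <- k / sum(k)
  nfft <- stats::nextn(n + length(k) - 1L, 2L)
  Z <- fft(c(z, rep(0, nfft - n)))
  K <- fft(c(k, rep(0, nfft - length(k))))
  y <- Re(fft(Z * K, inverse = TRUE)) / nfft
  y <- y[(half + 1):(half + n)]
  as.vector(scale(y))
}

## constant-modulus band-limited carrier: a frequency-wandering oscillator
## whose instantaneous frequency is a smoothed Gaussian process centred on
## the band and confined within it. The unit Hilbert envelope makes the
## planted amplitude envelope exactly recoverable downstream (see vignette).
.band_carrier <- function(n, band, sfreq, freq_smooth_ms = 40) {
  f0 <- (band$low_hz + band$high_hz) / 2
  dev <- 0.15 * (band$high_hz - band$low_hz) / 2
  f <- f0 + dev * .smooth_gp(n, freq_smooth_ms * sfreq / 1000)
  cos(2 * pi * cumsum(f) / sfreq + runif(1, 0, 2 * pi))
}

## closed-form mixing weight for the planted lognormal envelope correlation
.env_mix_weight <- function(rho, sigma) {
  .assert(rho >= 0 && rho <= 1, "rho must be in [0, 1]")
  if (rho == 0) return(0)
  log(1 + rho * (exp(sigma^2) - 1)) / sigma^2
}

#' Simulate resting source activity with a planted envelope correlation
#'
#' Active vertices (seed + targets) carry, per band, a band-limited
#' constant-modulus carrier modulated by a log-normal envelope; the
#' target envelopes share a latent Gaussian process with the seed, mixed so
#' that the envelope Pearson correlation equals `planted_env_corr` exactly
#' (closed-form calibration, see the package vignette). A configurable set of
#' inactive vertices carries independent band-limited background activity;
#' all remaining vertices are silent. The result is stored sparsely (only
#' nonzero rows).
#'
#' @param config a `sim_config`.
#' @param subject_id subject index; combined with the master seed via
#'   [subject_seed()] so subjects are independent but reproducible.
#' @param geometry optional [sim_geometry()] result (built if missing).
#' @return object of class `source_tc`: list with `data` (rows x samples),
#'   `vertices` (row vertex indices), `n_vertices`, `sfreq`, and
#'   `ground_truth` (planted values, recorded before any noise is added).
#' @export
simulate_source_rest <- function(config, subject_id = 1, geometry = NULL) {
  .assert(inherits(config, "sim_config"), "need a sim_config")
  geometry <- geometry %||% sim_geometry(config)
  seedv <- geometry$seed_vertex
  targets <- geometry$target_vertices
  .assert(!(seedv %in% targets),
          "seed vertex equals a target: degenerate correlation")
  src <- geometry$src
  V <- src$n_vertices
  .assert(all(c(seedv, targets) <= V), "vertex index out of range")
  fs <- config$sfreq
  n <- round(config$rest_duration * fs)
  sm <- config$env_smooth_ms * fs / 1000
  sigma <- config$env_log_sd
  a <- .env_mix_weight(config$planted_env_corr, sigma)
  ## every active source extends coherently over a mesh patch
  patches <- lapply(c(seedv, targets), function(v)
    mesh_neighborhood(src, v, config$source_patch_size))
  .assert(!anyDuplicated(unlist(patches)),
          "seed/target patches overlap: choose more separated vertices or a smaller source_patch_size")
  active <- unlist(patches)
  with_rng_seed(subject_seed(config$rng_seed, subject_id, 1L), {
    n_bg <- min(config$n_background, V - length(active))
    bg <- if (n_bg > 0) sample(setdiff(seq_len(V), active), n_bg) else integer(0)
    rows <- c(active, bg)
    data <- matrix(0, length(rows), n)
    row_of <- function(p) match(patches[[p]], rows)
    for (band_name in config$bands) {
      band <- band_spec(band_name)
      z_seed <- .smooth_gp(n, sm)
      sig_seed <- config$source_amp * exp(sigma * z_seed) *
        .band_carrier(n, band, fs)
      data[row_of(1), ] <- data[row_of(1), , drop = FALSE] +
        matrix(sig_seed, length(patches[[1]]), n, byrow = TRUE)
      for (j in seq_along(targets)) {
        z <- a * z_seed + sqrt(max(0, 1 - a^2)) * .smooth_gp(n, sm)
        sig <- config$source_amp * exp(sigma * z) * .band_carrier(n, band, fs)
        data[row_of(1 + j), ] <- data[row_of(1 + j), , drop = FALSE] +
          matrix(sig, length(patches[[1 + j]]), n, byrow = TRUE)
      }
      if (n_bg > 0) {
        amp_bg <- config$source_amp * config$background_scale
        for (j in seq_len(n_bg)) {
          zb <- .smooth_gp(n, sm)
          data[length(active) + j, ] <- data[length(active) + j, ] +
            amp_bg * exp(sigma * zb) * .band_carrier(n, band, fs)
        }
      }
    }
    gt <- list(subject_id = subject_id,
               planted_env_corr = config$planted_env_corr,
               seed_vertex = seedv, target_vertices = targets,
               seed_patch = patches[[1]],
               target_patches = patches[-1],
               bands = config$bands, background_vertices = bg)
    structure(list(data = data, vertices = rows, n_vertices = V, sfreq = fs,
                   ground_truth = gt),
              class = "source_tc")
  })
}

#' Mix source time courses to the sensors
#'
#' `sensors = leadfield %*% sources + white Gaussian noise(0, noise_sd)`.
#' Linear and additive; uses the caller's RNG state for the noise (wrap in
#' [with_rng_seed()] for reproducibility).
#'
#' @param source_tc a `source_tc` (sparse rows) or a full V x samples matrix.
#' @param leadfield constrained lead field, channels x V.
#' @param noise_sd sensor noise SD (0 gives the noiseless projection).
#' @param sfreq sampling rate; taken from `source_tc` when available.
#' @param sensors optional `sensor_array` carried into the recording.
#' @return a `sensor_recording`.
#' @export
mix_to_sensors <- function(source_tc, leadfield, noise_sd, sfreq = NULL,
                           sensors = NULL) {
  lf <- unclass(leadfield)
  if (inherits(source_tc, "source_tc")) {
    .assert(ncol(lf) == source_tc$n_vertices,
            "lead field does not match the number of modeled vertices")
    clean <- lf[, source_tc$vertices, drop = FALSE] %*% source_tc$data
    sfreq <- sfreq %||% source_tc$sfreq
  } else {
    .assert(is.matrix(source_tc) && ncol(lf) == nrow(source_tc),
            "lead field does not match the number of modeled vertices")
    clean <- lf %*% source_tc
    .assert(!is.null(sfreq), "sfreq required for matrix input")
  }
  .assert(noise_sd >= 0, "noise_sd must be >= 0")
  if (noise_sd > 0) {
    clean <- clean + matrix(rnorm(length(clean), sd = noise_sd),
                            nrow(clean), ncol(clean))
  }
  sensor_recording(clean, sfreq, sensors = sensors)
}

#' Simulate a subject's resting sensor recording
#'
#' Convenience wrapper: [simulate_source_rest()] then [mix_to_sensors()],
#' with the noise SD derived from the configured rest SNR
#' (`noise_sd = rms(clean) / snr`) unless given explicitly.
#'
#' @inheritParams simulate_source_rest
#' @return list with `recording` (a `sensor_recording`), `ground_truth`, and
#'   `noise_sd`.
#' @export
simulate_rest_recording <- function(config, subject_id = 1, geometry = NULL) {
  geometry <- geometry %||% sim_geometry(config)
  stc <- simulate_source_rest(config, subject_id, geometry)
  clean <- unclass(geometry$lf_con)[, stc$vertices, drop = FALSE] %*% stc$data
  nsd <- config$noise_sd %||% (sqrt(mean(clean^2)) / config$snr)
  rec <- with_rng_seed(subject_seed(config$rng_seed, subject_id, 2L), {
    sensor_recording(clean + matrix(rnorm(length(clean), sd = nsd),
                                    nrow(clean), ncol(clean)),
                     stc$sfreq, sensors = geometry$sensors)
  })
  list(recording = rec, ground_truth = stc$ground_truth, noise_sd = nsd)
}

## stereotyped S1 waveform: three signed Gaussian deflections; returns the
## per-component matrix (3 x samples) so paired-pulse attenuation can scale
## each component separately
.evoked_components <- function(config, n_samples) {
  t_ms <- (seq_len(n_samples) - 1) / config$sfreq * 1000
  signs <- c(-1, 1, -1)
  out <- matrix(0, 3, n_samples)
  for (k in 1:3) {
    out[k, ] <- signs[k] * config$evoked_amp[k] *
      exp(-0.5 * ((t_ms - config$evoked_latency_ms[k]) /
                    config$evoked_width_ms[k])^2)
  }
  out
}

#' Simulate an evoked (SP/PP) sensor recording with planted gating
#'
#' Builds a continuous recording containing randomly interleaved single-pulse
#' (SP) and paired-pulse (PP) trials. Every stimulus evokes a stereotyped S1
#' waveform of three deflections (nominal 22/33/58 ms, inside the component
#' analysis windows 20-26 / 27-40 / 45-71 ms) at the seed vertex. PP trials
#' add a second response at +`pp_isi_ms` ms whose components are scaled by
#' `planted_gating`. Trial spacing is uniform in `isi_range`. Sensor noise is
#' white with SD `peak(clean) / evoked_snr` unless `noise_sd` is set.
#'
#' @inheritParams simulate_source_rest
#' @return list with `recording` (a `sensor_recording`), `events` (data
#'   frame: sample, condition), `ground_truth`, and `noise_sd`.
#' @export
simulate_evoked_trials <- function(config, subject_id = 1, geometry = NULL) {
  .assert(inherits(config, "sim_config"), "need a sim_config")
  .assert(all(config$planted_gating >= 0), "planted_gating must be >= 0")
  geometry <- geometry %||% sim_geometry(config)
  fs <- config$sfreq
  with_rng_seed(subject_seed(config$rng_seed, subject_id, 3L), {
    n_ev <- config$n_sp_trials + config$n_pp_trials
    cond <- sample(rep(c("SP", "PP"), c(config$n_sp_trials, config$n_pp_trials)))
    isi <- runif(n_ev, config$isi_range[1], config$isi_range[2])
    onsets <- round(2 * fs + cumsum(c(0, isi[-1])) * fs)
    n <- max(onsets) + round(3 * fs)
    comp <- .evoked_components(config, round(0.12 * fs))
    wf_sp <- colSums(comp)
    wf_pp2 <- as.vector(config$planted_gating %*% comp)
    shift <- round(config$pp_isi_ms * fs / 1000)
    patch <- mesh_neighborhood(geometry$src, geometry$seed_vertex,
                               config$source_patch_size)
    topo <- rowSums(unclass(geometry$lf_con)[, patch, drop = FALSE])
    ## source-level trigger train, then one outer product per channel block
    drive <- numeric(n)
    for (i in seq_len(n_ev)) {
      ix <- onsets[i]:(onsets[i] + length(wf_sp) - 1L)
      drive[ix] <- drive[ix] + wf_sp
      if (cond[i] == "PP") {
        ix2 <- ix + shift
        drive[ix2] <- drive[ix2] + wf_pp2
      }
    }
    clean <- topo %o% drive
    nsd <- config$noise_sd %||% (max(abs(clean)) / config$evoked_snr)
    data <- clean + matrix(rnorm(length(clean), sd = nsd),
                           nrow(clean), ncol(clean))
    gt <- list(subject_id = subject_id,
               planted_gating = config$planted_gating,
               latencies_ms = config$evoked_latency_ms,
               seed_vertex = geometry$seed_vertex,
               seed_patch = patch)
    list(recording = sensor_recording(data, fs, sensors = geometry$sensors),
         events = data.frame(sample = onsets, condition = cond),
         ground_truth = gt, noise_sd = nsd)
  })
}

#' Simulate two-point discrimination responses
#'
#' Per trial at pin distance d, the "two points" response is Bernoulli with
#' `p = logistic(slope * (d - threshold_mm))`, so p = 0.5 exactly at the
#' planted threshold.
#'
#' @param threshold_mm planted 50% threshold, mm.
#' @param slope psychometric slope, 1/mm (> 0).
#' @param distances pin distances, mm.
#' @param trials_per_distance trials at each distance.
#' @param rng_seed integer seed.
#' @param subject_id label written into the table.
#' @return data frame (`behavioral_table`): subject, distance, trial,
#'   response (`"two_point"` / `"one_or_uncertain"`).
#' @export
simulate_behavior <- function(threshold_mm, slope, distances = c(0, 1, 1.5, 2,
                              2.5, 3, 3.5, 4, 4.5, 5), trials_per_distance = 16,
                              rng_seed = 1, subject_id = 1) {
  .assert(slope > 0, "slope must be positive")
  .assert(length(distances) >= 1, "empty distance list")
  .assert(all(distances >= 0), "distances must be non-negative")
  with_rng_seed(rng_seed, {
    d <- rep(distances, each = trials_per_distance)
    p <- 1 / (1 + exp(-slope * (d - threshold_mm)))
    y <- rbinom(length(d), 1, p)
    data.frame(subject = subject_id,
               distance = d,
               trial = as.vector(sapply(seq_along(distances),
                                        function(i) seq_len(trials_per_distance))),
               response = ifelse(y == 1, "two_point", "one_or_uncertain"))
  })
}

#' Simulate a multi-subject cohort with a planted brain-behavior coupling
#'
#' Draws per-subject ground truth: planted envelope correlation uniform in
#' `env_corr_range`, discrimination threshold
#' `intercept + coupling_slope * env_corr + N(0, coupling_noise_sd)`
#' (negative slope: stronger connectivity, better performance), and the
#' per-component gating factors from the configuration. Ground truth is
#' recorded before any recording is synthesized and never recomputed from
#' data. With `materialize = TRUE` the rest and evoked recordings are
#' generated for every subject (memory-heavy at study scale); otherwise the
#' bundle carries per-subject configurations from which [run_pipeline()] (or
#' the caller) generates recordings one subject at a time.
#'
#' @param config a `sim_config` (`n_subjects >= 8`).
#' @param geometry optional shared [sim_geometry()].
#' @param materialize also generate all recordings now.
#' @return list of class `cohort`: `truth` (data frame: subject,
#'   planted_env_corr, true_threshold, gating factors), `behavior` (stacked
#'   behavioral tables), `subject_configs`, `geometry`, and (if materialized)
#'   `subjects` with recordings.
#' @export
simulate_cohort <- function(config, geometry = NULL, materialize = FALSE) {
  .assert(inherits(config, "sim_config"), "need a sim_config")
  .assert(config$n_subjects >= 8, "cohort needs at least 8 subjects")
  geometry <- geometry %||% sim_geometry(config)
  ns <- config$n_subjects
  truth <- with_rng_seed(subject_seed(config$rng_seed, 0L, 9L), {
    corr <- runif(ns, config$env_corr_range[1], config$env_corr_range[2])
    thr <- config$coupling_intercept + config$coupling_slope * corr +
      rnorm(ns, sd = config$coupling_noise_sd)
    thr <- pmin(pmax(thr, 0.4), 4.6)  # keep the 50% point inside the pin range
    data.frame(subject = seq_len(ns), planted_env_corr = corr,
               true_threshold = thr,
               gating_N20m = config$planted_gating[["N20m"]],
               gating_P35m = config$planted_gating[["P35m"]],
               gating_P60m = config$planted_gating[["P60m"]])
  })
  subject_configs <- lapply(seq_len(ns), function(s) {
    cs <- config
    cs$planted_env_corr <- truth$planted_env_corr[s]
    cs$threshold_mm <- truth$true_threshold[s]
    cs
  })
  behavior <- do.call(rbind, lapply(seq_len(ns), function(s) {
    simulate_behavior(truth$true_threshold[s], config$psy_slope,
                      config$distances, config$trials_per_distance,
                      rng_seed = subject_seed(config$rng_seed, s, 4L),
                      subject_id = s)
  }))
  out <- list(truth = truth, behavior = behavior,
              subject_configs = subject_configs, geometry = geometry,
              config = config)
  if (materialize) {
    out$subjects <- lapply(seq_len(ns), function(s) {
      list(rest = simulate_rest_recording(subject_configs[[s]], s, geometry),
           evoked = simulate_evoked_trials(subject_configs[[s]], s, geometry))
    })
  }
  structure(out, class = "cohort")
}

#' Map-level cohort generator for group-statistics calibration
#'
#' Generates per-subject connectivity maps directly (bypassing the expensive
#' sensor-level chain) with a planted linear coupling between the map values
#' in a mesh patch and the behavioral covariate: subject s has a latent
#' strength `u_s ~ U(env_corr_range)`, map values `base + profile * u_s +
#' N(0, map_noise_sd)` where the profile tapers over `effect_rings` mesh
#' rings around `target_vertex` (zero elsewhere), and covariate
#' `intercept + coupling_slope * u_s + N(0, coupling_noise_sd)`. With
#' `coupling_slope = 0` the covariate is independent of the maps — the null
#' used to calibrate family-wise error.
#'
#' @param src a `source_space`.
#' @param n_subjects cohort size.
#' @param target_vertex centre of the effect patch (default: mesh vertex 1).
#' @param effect_rings hop radius of the patch.
#' @param coupling_slope covariate units per unit latent strength.
#' @param map_noise_sd,base_fc,map_scale map noise SD, baseline level, and
#'   effect amplitude.
#' @param intercept,coupling_noise_sd covariate model parameters.
#' @param env_corr_range latent strength range.
#' @param rng_seed integer seed.
#' @return list: `maps` (subjects x V), `covariate`, `latent`,
#'   `effect_vertices`.
#' @export
simulate_fc_cohort <- function(src, n_subjects = 20, target_vertex = 1,
                               effect_rings = 3, coupling_slope = -2,
                               map_noise_sd = 0.03, base_fc = 0.1,
                               map_scale = 0.35, intercept = 3.58,
                               coupling_noise_sd = 0.3,
                               env_corr_range = c(0.15, 0.85), rng_seed = 1) {
  .assert(inherits(src, "source_space"), "need a source_space")
  V <- src$n_vertices
  ## tapered patch profile by hop distance
  ring <- rep(NA_integer_, V)
  frontier <- target_vertex
  ring[frontier] <- 0L
  d <- 0L
  while (length(frontier) && d < effect_rings) {
    d <- d + 1L
    nxt <- unique(unlist(src$adjacency[frontier]))
    nxt <- nxt[is.na(ring[nxt])]
    ring[nxt] <- d
    frontier <- nxt
  }
  profile <- ifelse(is.na(ring), 0, map_scale * (1 - ring / (effect_rings + 1)))
  with_rng_seed(rng_seed, {
    u <- runif(n_subjects, env_corr_range[1], env_corr_range[2])
    maps <- matrix(rnorm(n_subjects * V, sd = map_noise_sd), n_subjects, V)
    maps <- maps + base_fc + u %o% profile
    cov <- intercept + coupling_slope * u + rnorm(n_subjects,
                                                  sd = coupling_noise_sd)
    list(maps = maps, covariate = cov, latent = u,
         effect_vertices = which(profile > 0))
  })
}
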