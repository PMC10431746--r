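## End-to-end orchestration: synthetic cohort -> preprocessing -> forward /
## LCMV inverse -> seed AEC connectivity + paired-pulse gating + psychometric
## thresholds -> group statistics (vertex-wise regression with TFCE
## permutation FWE, peak-vertex Spearman, SP-vs-PP Wilcoxon). Fully
## deterministic under the master seed.

.default_config <- function() {
  list(
    rng_seed = 1,
    simulate = list(),                     # sim_config() overrides
    preprocess = list(
      low_hz = 0.5, high_hz = 100, notch_hz = 50,
      window_ms = 2000, tmin = -1500, tmax = 2500,
      baseline = c(-100, -5),
      reject_ptp = NULL                    # NULL: 7 x median peak-to-peak
    ),
    beamformer = list(
      orientation = "weights",
      rest_cov_window = NULL,              # whole 0-2000 ms segment
      evoked_cov_window = NULL             # whole -1500..2500 ms epoch
    ),
    connectivity = list(band = "beta", trim_ms = 200, fisher = FALSE,
                        seed_from = "N20m"),
    gating = list(shift_ms = 100, n_scout = 10),
    stats = list(E = 0.5, H = 2, n_steps = 100, n_permutations = 1000,
                 alpha = 0.05, k_min = 50, n_comparisons = 3)
  )
}

.merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- .merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Validate and resolve a pipeline configuration
#'
#' Merges the user configuration (an R list, or a path to a YAML file) into
#' the defaults — the study's analysis parameters: 0.5-100 Hz band-pass with
#' a 50 Hz notch, 2000 ms rest segments, -1500..2500 ms evoked epochs with
#' -100..-5 ms baseline, alpha (8-12 Hz) / beta (15-29 Hz) bands, TFCE
#' E = 0.5, H = 2, cluster extent floor k > 50, alpha = 0.05, and a
#' three-way Bonferroni family — checks every parameter range, and reports
#' every resolved value.
#'
#' @param config named list of overrides (possibly nested), or a YAML file
#'   path, or `NULL` for pure defaults.
#' @return list of class `pipeline_config_report`: `ok`, `errors`
#'   (character), `config` (fully resolved), `resolved` (flat summary of key
#'   values).
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- config %||% list()
  .assert(is.list(config), "config must be a list or YAML path")
  cfg <- .merge_config(.default_config(), config)
  errors <- character(0)
  note <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)

  p <- cfg$preprocess
  note(p$low_hz > 0 && p$low_hz < p$high_hz, "preprocess: need 0 < low_hz < high_hz")
  note(p$tmin < p$tmax, "preprocess: need tmin < tmax")
  note(p$baseline[1] < p$baseline[2] && p$baseline[1] >= p$tmin,
       "preprocess: baseline window must lie inside the epoch")
  note(p$window_ms > 0, "preprocess: window_ms must be positive")
  s <- cfg$stats
  note(s$E > 0, "stats: TFCE E must be positive")
  note(s$H > 0, "stats: TFCE H must be positive")
  note(s$n_steps >= 1, "stats: TFCE dh step count must be >= 1")
  note(s$n_permutations >= 100, "stats: need at least 100 permutations")
  note(s$alpha > 0 && s$alpha < 1, "stats: alpha must be in (0, 1)")
  note(s$k_min >= 0, "stats: k_min must be >= 0")
  note(s$n_comparisons >= 1, "stats: n_comparisons must be >= 1")
  bd <- tryCatch(band_spec(cfg$connectivity$band), error = function(e) NULL)
  note(!is.null(bd), "connectivity: unknown band")
  note(cfg$connectivity$trim_ms >= 0, "connectivity: trim_ms must be >= 0")
  note(cfg$beamformer$orientation %in% c("weights", "leadfield"),
       "beamformer: orientation must be 'weights' or 'leadfield'")
  simcfg <- tryCatch(
    do.call(sim_config, c(cfg$simulate,
                          list(rng_seed = cfg$simulate$rng_seed %||% cfg$rng_seed))),
    error = function(e) {
      errors <<- c(errors, paste("simulate:", conditionMessage(e)))
      NULL
    })
  resolved <- list(
    rng_seed = cfg$rng_seed,
    band = if (!is.null(bd)) c(bd$low_hz, bd$high_hz) else NULL,
    bandpass_hz = c(p$low_hz, p$high_hz), notch_hz = p$notch_hz,
    rest_window_ms = p$window_ms,
    epoch_ms = c(p$tmin, p$tmax), baseline_ms = p$baseline,
    tfce = c(E = s$E, H = s$H), n_permutations = s$n_permutations,
    alpha = s$alpha, k_min = s$k_min,
    bonferroni_alpha = s$alpha / s$n_comparisons,
    gating_windows = gating_windows(),
    n_subjects = if (!is.null(simcfg)) simcfg$n_subjects else NULL
  )
  structure(list(ok = length(errors) == 0, errors = errors, config = cfg,
                 sim_config = simcfg, resolved = resolved),
            class = "pipeline_config_report")
}

#' @export
print.pipeline_config_report <- function(x, ...) {
  cat(sprintf("<pipeline_config_report> %s\n",
              if (x$ok) "valid" else "INVALID"))
  for (e in x$errors) cat("  error:", e, "\n")
  invisible(x)
}

.resolve_reject <- function(epochs, spec) {
  if (is.numeric(spec)) return(spec)
  d <- epochs$data
  ptp <- apply(d, 1, function(m) max(apply(m, 1, function(x) diff(range(x)))))
  7 * median(ptp)
}

## analyze one subject end to end (evoked first: the N20m scout seeds the FC)
.run_subject <- function(s, simcfg_s, cfg, geometry, behavior_s) {
  p <- cfg$preprocess
  src <- geometry$src

  ## ----- evoked: epochs, covariance, inverse, gating
  ev <- simulate_evoked_trials(simcfg_s, s, geometry)
  rec <- bandpass_notch(ev$recording, p$low_hz, p$high_hz, p$notch_hz)
  epo <- epoch_evoked(rec, ev$events, p$tmin, p$tmax)
  epo <- baseline_correct(epo, p$baseline[1], p$baseline[2])
  epo <- reject_trials(epo, .resolve_reject(epo, p$reject_ptp))
  ev_rej <- attr(epo, "rejection")
  covE <- regularize_median_eig(
    compute_data_covariance(epo, cfg$beamformer$evoked_cov_window))
  wE <- lcmv_weights(geometry$lf_free, covE, src$normals,
                     orientation = cfg$beamformer$orientation)
  sp_src <- apply_inverse(wE, average_evoked(epo, "SP"))
  pp_src <- apply_inverse(wE, average_evoked(epo, "PP"))
  gating <- compute_gating(sp_src, pp_src, epo$times, src,
                           shift_ms = cfg$gating$shift_ms,
                           n_scout = cfg$gating$n_scout,
                           scout_norm = sqrt(rowSums(unclass(wE)^2)))

  ## ----- rest: segments, covariance, inverse, seed AEC map
  seed_scout <- if (identical(cfg$connectivity$seed_from, "N20m")) {
    attr(gating, "scouts")$N20m$vertices
  } else {
    mesh_neighborhood(src, geometry$seed_vertex, cfg$gating$n_scout)
  }
  rest <- simulate_rest_recording(simcfg_s, s, geometry)
  rrec <- bandpass_notch(rest$recording, p$low_hz, p$high_hz, p$notch_hz)
  rep_ <- segment_rest(rrec, p$window_ms)
  rep_ <- reject_trials(rep_, .resolve_reject(rep_, p$reject_ptp))
  rest_rej <- attr(rep_, "rejection")
  covR <- regularize_median_eig(
    compute_data_covariance(rep_, cfg$beamformer$rest_cov_window))
  wR <- lcmv_weights(geometry$lf_free, covR, src$normals,
                     orientation = cfg$beamformer$orientation)
  fc <- compute_fc_map(wR, rep_, seed_scout, cfg$connectivity$band,
                       trim_ms = cfg$connectivity$trim_ms,
                       fisher = cfg$connectivity$fisher)

  ## ----- behavior
  psy <- fit_psychometric(behavior_s)

  list(fc = fc, gating = gating, threshold = psy$threshold, psy = psy,
       seed_scout = seed_scout,
       qc = list(evoked_rejected = ev_rej$fraction,
                 rest_rejected = rest_rej$fraction))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes, per subject: evoked simulation, filtering, epoching, baseline,
#' trial rejection, LCMV inversion, and gating analysis; resting simulation,
#' filtering, segmentation, LCMV inversion, and the seed AEC map (seeded at
#' the subject's N20m scout); psychometric threshold fitting. Then, at the
#' group level: vertex-wise regression of the FC maps on the thresholds with
#' TFCE max-statistic permutation FWE correction and extent-filtered
#' clusters; Spearman tests of the gating ratios against the thresholds and
#' of FC at cluster peaks; Wilcoxon signed-rank tests of SP vs PP amplitudes
#' (all Bonferroni-corrected over the three components).
#'
#' @param config overrides for [validate_config()] (list or YAML path).
#' @param out_dir optional directory for CSV/JSON outputs.
#' @param verbose print per-stage progress.
#' @return list of class `pipeline_result`: `fc_maps` (subjects x V),
#'   `thresholds`, `gating` (long data frame), `group` (fwe result, cluster
#'   table, spearman/wilcoxon tests), `truth`, `qc`, `config`.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, verbose = TRUE) {
  vc <- validate_config(config)
  if (!vc$ok) {
    stop("invalid configuration:\n  ", paste(vc$errors, collapse = "\n  "),
         call. = FALSE)
  }
  cfg <- vc$config
  simcfg <- vc$sim_config
  say <- function(...) if (verbose) message(sprintf(...))
  say("[geometry] building mesh, sensors, lead field")
  geometry <- sim_geometry(simcfg)
  say("[cohort] drawing ground truth for %d subjects", simcfg$n_subjects)
  cohort <- simulate_cohort(simcfg, geometry)

  ns <- simcfg$n_subjects
  V <- geometry$src$n_vertices
  fc_maps <- matrix(NA_real_, ns, V)
  thresholds <- numeric(ns)
  gat_rows <- list()
  qc <- list()
  for (s in seq_len(ns)) {
    say("[subject %d/%d] evoked + rest + behavior", s, ns)
    res <- .run_subject(s, cohort$subject_configs[[s]], cfg, geometry,
                        cohort$behavior[cohort$behavior$subject == s, ])
    fc_maps[s, ] <- as.numeric(res$fc)
    thresholds[s] <- res$threshold
    g <- as.data.frame(res$gating)
    g$subject <- s
    gat_rows[[s]] <- g
    qc[[s]] <- res$qc
  }
  gating <- do.call(rbind, gat_rows)

  say("[group] TFCE permutation inference (%d permutations)",
      cfg$stats$n_permutations)
  maps0 <- fc_maps
  maps0[!is.finite(maps0)] <- 0
  st <- cfg$stats
  fwe <- permutation_fwe(maps0, thresholds, geometry$src$edges,
                         E = st$E, H = st$H, n_steps = st$n_steps,
                         n_permutations = st$n_permutations,
                         rng_seed = subject_seed(cfg$rng_seed, 0L, 7L))
  clusters <- cluster_filter(fwe$p, geometry$src$edges, st$alpha, st$k_min)

  comp_names <- unique(gating$component)
  sp_tests <- lapply(comp_names, function(cp) {
    g <- gating[gating$component == cp, ]
    spearman_test(g$ratio[order(g$subject)], thresholds,
                  n_comparisons = st$n_comparisons)
  })
  names(sp_tests) <- comp_names
  wx_tests <- lapply(comp_names, function(cp) {
    g <- gating[gating$component == cp, ]
    g <- g[order(g$subject), ]
    wilcoxon_signed_rank(g$sp_amp, g$pp_amp,
                         n_comparisons = st$n_comparisons)
  })
  names(wx_tests) <- comp_names
  peak_tests <- if (nrow(clusters)) {
    lapply(seq_len(nrow(clusters)), function(i) {
      v <- clusters$peak_vertex[i]
      c(list(cluster = i, vertex = v),
        spearman_test(maps0[, v], thresholds,
                      n_comparisons = max(1, nrow(clusters))))
    })
  } else list()

  out <- structure(list(
    fc_maps = fc_maps, thresholds = thresholds, gating = gating,
    group = list(fwe = fwe, clusters = clusters,
                 spearman_gating = sp_tests, wilcoxon_sp_pp = wx_tests,
                 spearman_peaks = peak_tests),
    truth = cohort$truth, qc = qc, geometry = geometry,
    config = cfg), class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' Write the pipeline result bundle to a directory
#'
#' Emits `cluster_table.csv`, `gating.csv`, `thresholds.csv`,
#' `fc_maps.csv` (subjects x vertices), `stat_maps.csv` (t / TFCE / FWE p
#' per vertex), `truth.csv`, and `provenance.json` (the resolved
#' configuration, verbatim, plus seeds and package version; no timestamps,
#' so identical runs produce identical files).
#'
#' @param result a `pipeline_result`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(out_dir, x)
  write.csv(result$group$clusters, f("cluster_table.csv"), row.names = FALSE)
  write.csv(result$gating, f("gating.csv"), row.names = FALSE)
  write.csv(data.frame(subject = seq_along(result$thresholds),
                       threshold_mm = result$thresholds),
            f("thresholds.csv"), row.names = FALSE)
  write.csv(as.data.frame(result$fc_maps), f("fc_maps.csv"), row.names = FALSE)
  write.csv(data.frame(vertex = seq_along(result$group$fwe$t),
                       t = result$group$fwe$t,
                       tfce = result$group$fwe$tfce,
                       p_fwe = result$group$fwe$p),
            f("stat_maps.csv"), row.names = FALSE)
  write.csv(result$truth, f("truth.csv"), row.names = FALSE)
  write_provenance(list(
    package = "somameg",
    version = as.character(utils::packageVersion("somameg")),
    rng_seed = result$config$rng_seed,
    config = result$config), f("provenance.json"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects, %d vertices\n",
              nrow(x$fc_maps), ncol(x$fc_maps)))
  cat(sprintf("  thresholds: %.2f +/- %.2f mm\n", mean(x$thresholds),
              sd(x$thresholds)))
  cat(sprintf("  clusters surviving FWE: %d\n", nrow(x$group$clusters)))
  invisible(x)
}
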