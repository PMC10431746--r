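## Shared small fixtures. Geometries are cached per (subdivision, sensors)
## because the lead field is deterministic and rebuilding it dominates the
## cost of small simulation tests.

.fixture_cache <- new.env(parent = emptyenv())

small_mesh <- function(subdivisions = 2) {
  key <- paste0("mesh", subdivisions)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- cortical_mesh(subdivisions)
  }
  .fixture_cache[[key]]
}

tiny_cfg <- function(...) {
  args <- modifyList(list(mesh_subdivisions = 2, n_sensors = 48,
                          rest_duration = 30, n_background = 16),
                     list(...))
  do.call(sim_config, args)
}

tiny_geometry <- function(cfg = tiny_cfg()) {
  key <- paste0("geo", cfg$mesh_subdivisions, "_", cfg$n_sensors)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- sim_geometry(cfg)
  }
  .fixture_cache[[key]]
}

## random symmetric positive-definite matrix
random_spd <- function(n, seed) {
  set.seed(seed)
  a <- matrix(rnorm(n * n), n)
  crossprod(a) + diag(n) * 0.1
}

## source-level rest chain up to a connectivity map (shared by connectivity
## and acceptance tests)
rest_chain_fc <- function(cfg, geometry = tiny_geometry(cfg)) {
  rr <- simulate_rest_recording(cfg, 1, geometry)
  ep <- segment_rest(bandpass_notch(rr$recording), 2000)
  Cr <- regularize_median_eig(compute_data_covariance(ep))
  w <- lcmv_weights(geometry$lf_free, Cr, geometry$src$normals)
  fc <- compute_fc_map(w, ep, mesh_neighborhood(geometry$src,
                                                geometry$seed_vertex, 10),
                       "beta")
  list(fc = fc, geometry = geometry, weights = w, epochs = ep)
}

## evoked chain up to the gating table (shared by gating and acceptance
## tests); short inter-trial intervals keep the recording small while the
## epoching and windows stay at their standard values
evoked_chain_gating <- function(n_trials, planted_n20, seed, n_sensors = 32) {
  cfg <- sim_config(mesh_subdivisions = 2, n_sensors = n_sensors,
                    rng_seed = seed, n_sp_trials = n_trials,
                    n_pp_trials = n_trials, isi_range = c(1, 1.5),
                    planted_gating = c(N20m = planted_n20, P35m = 0.6,
                                       P60m = 0.7))
  geo <- tiny_geometry(cfg)
  ev <- simulate_evoked_trials(cfg, 1, geo)
  rec <- bandpass_notch(ev$recording)
  epo <- baseline_correct(epoch_evoked(rec, ev$events))
  covE <- regularize_median_eig(compute_data_covariance(epo))
  w <- lcmv_weights(geo$lf_free, covE, geo$src$normals)
  sp <- apply_inverse(w, average_evoked(epo, "SP"))
  pp <- apply_inverse(w, average_evoked(epo, "PP"))
  compute_gating(sp, pp, epo$times, geo$src,
                 scout_norm = sqrt(rowSums(unclass(w)^2)))
}
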