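## Somatosensory-gating analysis of evoked source maps: condition averaging,
## activation-peak ROI scouts, paired-pulse minus single-pulse subtraction,
## time realignment + rectification, and per-component PP/SP peak ratios.

#' Component analysis windows
#'
#' The three successive evoked-field components and their peak-analysis
#' windows in ms: N20m 20-26, P35m 27-40, P60m 45-71.
#' @return named list of length-2 numeric vectors.
#' @export
gating_windows <- function() {
  list(N20m = c(20, 26), P35m = c(27, 40), P60m = c(45, 71))
}

#' Average epochs of one condition
#'
#' Arithmetic mean across epochs, optionally restricted to one condition
#' label.
#'
#' @param epochs an `epoch_set` (sensor or source level).
#' @param condition condition label to select (`NULL` for all epochs).
#' @return series x samples matrix with attribute `times`.
#' @export
average_evoked <- function(epochs, condition = NULL) {
  .assert(inherits(epochs, "epoch_set"), "need an epoch_set")
  keep <- if (is.null(condition)) rep(TRUE, dim(epochs$data)[1]) else
    epochs$condition == condition
  .assert(sum(keep) >= 2, "need at least 2 epochs of the condition")
  m <- apply(epochs$data[keep, , , drop = FALSE], c(2, 3), mean)
  structure(m, times = epochs$times, n_epochs = sum(keep))
}

#' Define an activation-peak ROI scout
#'
#' The scout centre is the vertex with maximal absolute amplitude anywhere in
#' the analysis window; the scout is the centre plus its nearest mesh
#' neighbors by edge (hop) distance, ties broken by lower vertex index, up to
#' `n_scout` vertices (10, the study's scout size). For beamformer maps the
#' amplitudes can be divided by a per-vertex normalizer (typically the
#' filter's noise gain `||w_v||`) before the argmax, since unit-gain
#' minimum-variance maps inflate vertices with weak lead fields; and the
#' search can be restricted to an anatomical candidate region, mirroring
#' scout placement "on S1".
#'
#' @param evoked_map vertices x samples source map.
#' @param times time axis, ms.
#' @param window_ms length-2 analysis window, ms.
#' @param src the `source_space` (for neighborhoods).
#' @param n_scout scout size.
#' @param norm optional per-vertex divisor applied before the argmax.
#' @param candidates optional vertex indices to which the centre search is
#'   restricted.
#' @return list of class `roi_scout`: `center`, `vertices`, `window_ms`.
#' @export
define_roi_scout <- function(evoked_map, times, window_ms, src, n_scout = 10,
                             norm = NULL, candidates = NULL) {
  sel <- times >= window_ms[1] & times <= window_ms[2]
  .assert(any(sel), "window outside the epoch time axis")
  amp <- apply(abs(evoked_map[, sel, drop = FALSE]), 1, max)
  .assert(diff(range(amp)) > 0, "flat map: no activation peak")
  if (!is.null(norm)) {
    .assert(length(norm) == length(amp) && all(norm > 0), "invalid norm")
    amp <- amp / norm
  }
  cand <- candidates %||% seq_along(amp)
  center <- cand[which.max(amp[cand])]
  verts <- mesh_neighborhood(src, center, n_scout)
  structure(list(center = center, vertices = verts, window_ms = window_ms),
            class = "roi_scout")
}

#' Subtract the single-pulse map from the paired-pulse map
#'
#' Removes the first-pulse response from the paired-pulse condition under the
#' linear-superposition assumption, leaving the (attenuated) second-pulse
#' response.
#'
#' @param pp_map,sp_map aligned vertices x samples maps.
#' @param times optional shared time axis (checked when both carry one).
#' @return `pp_map - sp_map` with the time axis preserved.
#' @export
subtract_sp_from_pp <- function(pp_map, sp_map, times = NULL) {
  .assert(all(dim(pp_map) == dim(sp_map)), "map shapes differ")
  tp <- attr(pp_map, "times"); ts <- attr(sp_map, "times")
  if (!is.null(tp) && !is.null(ts)) {
    .assert(isTRUE(all.equal(tp, ts)), "time axes differ")
  }
  structure(unclass(pp_map) - unclass(sp_map), times = times %||% tp)
}

#' Realign, baseline-correct, and rectify a subtracted map
#'
#' Shifts the time axis by `-shift_ms` so the second pulse sits at t = 0
#' (comparable to the single-pulse trigger), baseline-corrects over the
#' standard window on the new axis, and takes absolute values. Rectification
#' after baseline correction is applied identically to both conditions for
#' comparability.
#'
#' @param subtracted_map vertices x samples map (or vector).
#' @param times time axis, ms.
#' @param shift_ms realignment shift (the within-pair interval, 100 ms).
#' @param baseline length-2 baseline window on the shifted axis.
#' @return list: `map` (rectified), `times` (shifted axis).
#' @export
shift_rectify_baseline <- function(subtracted_map, times, shift_ms = 100,
                                   baseline = c(-100, -5)) {
  if (is.null(dim(subtracted_map))) {
    subtracted_map <- matrix(subtracted_map, 1)
  }
  t2 <- times - shift_ms
  .assert(any(t2 >= baseline[1] & t2 <= baseline[2]),
          "shift leaves no baseline window inside the epoch")
  m <- .baseline_mat(unclass(subtracted_map), t2, baseline[1], baseline[2])
  list(map = abs(m), times = t2)
}

#' Peak amplitude and latency in a window
#'
#' Maximum of the waveform over the window (inclusive in ms); ties resolve
#' to the earliest latency.
#'
#' @param waveform numeric vector.
#' @param times time axis, ms.
#' @param window_ms length-2 window.
#' @return list: `amplitude`, `latency_ms`.
#' @export
peak_in_window <- function(waveform, times, window_ms) {
  sel <- which(times >= window_ms[1] & times <= window_ms[2])
  .assert(length(sel) > 0, "empty analysis window")
  i <- sel[which.max(waveform[sel])]
  list(amplitude = waveform[i], latency_ms = times[i])
}

#' Paired-pulse / single-pulse gating ratio
#'
#' @param pp_peak,sp_peak peak amplitudes (same units).
#' @return `pp_peak / sp_peak`; `NA` (flagged by a warning) if the SP peak
#'   is not positive. Ratios below 1 indicate inhibition (gating).
#' @export
gating_ratio <- function(pp_peak, sp_peak) {
  if (!isTRUE(sp_peak > 0)) {
    warning("single-pulse peak is not positive; gating ratio undefined")
    return(NA_real_)
  }
  pp_peak / sp_peak
}

#' Full somatosensory-gating analysis of one subject
#'
#' Takes condition-averaged source maps (vertices x time, first-pulse-locked
#' for PP), baseline-corrects both, defines per-component activation scouts
#' from the SP map, subtracts SP from PP, realigns the residual by -100 ms,
#' re-baselines, rectifies, and extracts per-component SP and PP peaks and
#' their PP/SP ratio.
#'
#' @param sp_map,pp_map vertices x samples averaged source maps.
#' @param times time axis, ms.
#' @param src the `source_space`.
#' @param windows named list of component windows (default
#'   [gating_windows()]).
#' @param shift_ms within-pair interval (ms).
#' @param baseline baseline window (ms).
#' @param n_scout scout size.
#' @param scout_norm,scout_candidates passed to [define_roi_scout()] (noise
#'   gain normalization / anatomical restriction of the centre search).
#' @return data frame of class `gating_result`: component, center_vertex,
#'   sp_amp, sp_lat, pp_amp, pp_lat, ratio; attribute `scouts`.
#' @export
compute_gating <- function(sp_map, pp_map, times, src,
                           windows = gating_windows(), shift_ms = 100,
                           baseline = c(-100, -5), n_scout = 10,
                           scout_norm = NULL, scout_candidates = NULL) {
  sp_bc <- .baseline_mat(unclass(sp_map), times, baseline[1], baseline[2])
  pp_bc <- .baseline_mat(unclass(pp_map), times, baseline[1], baseline[2])
  sub <- pp_bc - sp_bc
  ## scout waveforms are extracted from the signed maps and rectified after
  ## averaging over the scout, so uncorrelated vertex noise averages out
  ## before the absolute value is taken
  t_shift <- times - shift_ms
  sub_bc <- .baseline_mat(sub, t_shift, baseline[1], baseline[2])
  scouts <- list()
  rows <- lapply(names(windows), function(comp) {
    w <- windows[[comp]]
    scout <- define_roi_scout(sp_bc, times, w, src, n_scout,
                              norm = scout_norm, candidates = scout_candidates)
    scouts[[comp]] <<- scout
    spw <- abs(colMeans(sp_bc[scout$vertices, , drop = FALSE]))
    ppw <- abs(colMeans(sub_bc[scout$vertices, , drop = FALSE]))
    sp_pk <- peak_in_window(spw, times, w)
    pp_pk <- peak_in_window(ppw, t_shift, w)
    data.frame(component = comp, center_vertex = scout$center,
               sp_amp = sp_pk$amplitude, sp_lat = sp_pk$latency_ms,
               pp_amp = pp_pk$amplitude, pp_lat = pp_pk$latency_ms,
               ratio = gating_ratio(pp_pk$amplitude, sp_pk$amplitude))
  })
  structure(do.call(rbind, rows), scouts = scouts, class = c("gating_result",
                                                             "data.frame"))
}
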