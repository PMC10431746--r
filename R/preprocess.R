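## Sensor-space preprocessing: zero-phase FIR band-pass + notch filtering,
## fixed-length segmentation of resting recordings, trigger-locked epoching of
## evoked recordings, baseline correction, and deterministic peak-to-peak
## trial rejection (the automated stand-in for visual artifact review).

#' Construct a sensor recording
#'
#' @param data channels x samples numeric matrix, sensor units.
#' @param sfreq sampling frequency in Hz.
#' @param sensors optional `sensor_array` describing the channels.
#' @param channel_names optional character vector.
#' @return An object of class `sensor_recording`.
#' @export
sensor_recording <- function(data, sfreq, sensors = NULL, channel_names = NULL) {
  .assert(is.matrix(data) && all(is.finite(data)), "data must be a finite matrix")
  .assert(sfreq > 0, "sfreq must be positive")
  if (!is.null(sensors)) {
    .assert(inherits(sensors, "sensor_array"), "sensors must be a sensor_array")
    .assert(sensors$n_channels == nrow(data), "channel meta does not match data")
  }
  structure(list(data = data, sfreq = sfreq, sensors = sensors,
                 channel_names = channel_names %||%
                   paste0("ch", seq_len(nrow(data)))),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq))
  invisible(x)
}

## ---- FIR machinery --------------------------------------------------------

## FFT-based linear convolution of filter b with each column of x
## (samples x channels), returning the delay-compensated "same" part.
## b must be linear phase with even order (odd length) so the group delay
## (length(b)-1)/2 is an integer number of samples.
.fir_apply <- function(b, x) {
  n <- nrow(x)
  nb <- length(b)
  delay <- (nb - 1L) %/% 2L
  nfft <- stats::nextn(n + nb - 1L, c(2L, 3L, 5L))
  B <- fft(c(b, rep(0, nfft - nb)))
  ## bound the complex workspace on long recordings by chunking channels
  chunk <- max(1L, floor(2^23 / nfft))
  out <- matrix(0, n, ncol(x))
  for (j0 in seq(1L, ncol(x), by = chunk)) {
    j <- j0:min(ncol(x), j0 + chunk - 1L)
    X <- mvfft(rbind(x[, j, drop = FALSE], matrix(0, nfft - n, length(j))))
    y <- Re(mvfft(X * B, inverse = TRUE)) / nfft
    out[, j] <- y[(delay + 1L):(delay + n), , drop = FALSE]
  }
  out
}

## reflect-pad each column by p samples, apply, trim
.fir_padded <- function(b, x, p = length(b) - 1L) {
  n <- nrow(x)
  p <- min(p, n - 1L)
  xp <- rbind(x[(p + 1L):2L, , drop = FALSE],
              x,
              x[(n - 1L):(n - p), , drop = FALSE])
  y <- .fir_apply(b, xp)
  y[(p + 1L):(p + n), , drop = FALSE]
}

## zero-phase: forward-backward application (magnitude response squared);
## channels are processed in blocks so temporaries stay bounded on long
## recordings
.fir_zero_phase <- function(b, x) {
  n <- nrow(x)
  block <- max(1L, floor(2^24 / n))
  out <- matrix(0, n, ncol(x))
  for (j0 in seq(1L, ncol(x), by = block)) {
    j <- j0:min(ncol(x), j0 + block - 1L)
    y <- .fir_padded(b, x[, j, drop = FALSE])
    y <- y[n:1L, , drop = FALSE]
    y <- .fir_padded(b, y)
    out[, j] <- y[n:1L, , drop = FALSE]
  }
  out
}

.even <- function(x) max(2L, 2L * floor(x / 2))

#' Band-pass and notch filter a recording
#'
#' Zero-phase filtering by forward-backward application of linear-phase
#' (even-order, Hamming-windowed) FIR filters: a band-pass from `low_hz` to
#' `high_hz` followed by a band-stop notch of width `2 * notch_width_hz`
#' centred on `notch_hz` (power-line suppression). Edges are reflect-padded.
#'
#' @param recording a `sensor_recording`.
#' @param low_hz,high_hz band-pass edges (Hz); defaults 0.5 and 100.
#' @param notch_hz notch centre frequency (Hz), or `NULL` to skip; default 50.
#' @param notch_width_hz half-width of the stop band.
#' @param order band-pass FIR order (even). Default scales with the low edge
#'   (transition width about `3.3 * sfreq / order` Hz) and is capped by the
#'   recording length.
#' @return filtered `sensor_recording`.
#' @export
bandpass_notch <- function(recording, low_hz = 0.5, high_hz = 100,
                           notch_hz = 50, notch_width_hz = 2, order = NULL) {
  .assert(inherits(recording, "sensor_recording"), "need a sensor_recording")
  fs <- recording$sfreq
  nyq <- fs / 2
  .assert(low_hz > 0 && low_hz < high_hz && high_hz < nyq,
          "require 0 < low < high < Nyquist")
  if (!is.null(notch_hz)) {
    .assert(notch_hz + notch_width_hz < nyq, "notch exceeds Nyquist")
  }
  n <- ncol(recording$data)
  if (is.null(order)) {
    order <- .even(min(3.3 * fs / low_hz, (n - 1) / 3))
  }
  .assert(order %% 2 == 0, "FIR order must be even")
  .assert(order < n, "recording shorter than filter order")
  x <- t(recording$data)
  b <- signal::fir1(order, c(low_hz, high_hz) / nyq, type = "pass")
  if (!is.null(notch_hz)) {
    ## fold the notch into the band-pass kernel: one zero-phase pass of the
    ## combined (still linear-phase, even-order) filter
    ord_n <- .even(min(fs, (n - 1) / 3))
    b_n <- signal::fir1(ord_n, c(notch_hz - notch_width_hz,
                                 notch_hz + notch_width_hz) / nyq,
                        type = "stop")
    b <- convolve(b, rev(b_n), type = "open")
  }
  .assert(length(b) < n, "recording shorter than the combined filter")
  out <- recording
  out$data <- t(.fir_zero_phase(b, x))
  out
}

## ---- Epoching -------------------------------------------------------------

.epoch_set <- function(data, times, sfreq, label, condition = NULL) {
  structure(list(data = data, times = times, sfreq = sfreq, label = label,
                 condition = condition %||% rep(label, dim(data)[1])),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set:%s> %d epochs x %d series x %d samples, t = [%g, %g] ms\n",
              x$label, d[1], d[2], d[3], min(x$times), max(x$times)))
  invisible(x)
}

#' Segment a resting recording into fixed windows
#'
#' Cuts the recording into consecutive non-overlapping windows of
#' `window_ms`; a trailing remainder shorter than one window is dropped.
#'
#' @param recording a `sensor_recording`.
#' @param window_ms window length in ms (default 2000).
#' @return an `epoch_set` with label `"rest"`; time axis starts at 0 ms.
#' @export
segment_rest <- function(recording, window_ms = 2000) {
  .assert(inherits(recording, "sensor_recording"), "need a sensor_recording")
  fs <- recording$sfreq
  w <- round(window_ms * fs / 1000)
  n <- ncol(recording$data)
  .assert(n >= w, "recording shorter than one window")
  n_ep <- n %/% w
  C <- nrow(recording$data)
  data <- array(0, c(n_ep, C, w))
  for (e in seq_len(n_ep)) {
    data[e, , ] <- recording$data[, ((e - 1) * w + 1):(e * w)]
  }
  .epoch_set(data, (seq_len(w) - 1) / fs * 1000, fs, "rest")
}

#' Epoch an evoked recording around stimulus triggers
#'
#' One epoch per event, from `tmin` to `tmax` ms around the trigger sample
#' (half-open in samples: `tmax` itself is excluded). Paired-pulse trials are
#' expected to be triggered on the first pulse. Events whose window falls
#' outside the recording are skipped with a warning.
#'
#' @param recording a `sensor_recording`.
#' @param events data frame with columns `sample` (trigger sample index,
#'   1-based) and `condition` (e.g. `"SP"`/`"PP"`).
#' @param tmin,tmax epoch window in ms relative to the trigger.
#' @return an `epoch_set` with per-epoch `condition`.
#' @export
epoch_evoked <- function(recording, events, tmin = -1500, tmax = 2500) {
  .assert(inherits(recording, "sensor_recording"), "need a sensor_recording")
  .assert(all(c("sample", "condition") %in% names(events)),
          "events needs columns sample, condition")
  fs <- recording$sfreq
  i0 <- round(tmin * fs / 1000)
  ns <- round((tmax - tmin) * fs / 1000)
  n <- ncol(recording$data)
  start <- events$sample + i0
  ok <- start >= 1 & (start + ns - 1) <= n
  if (any(!ok)) {
    warning(sprintf("%d event(s) too close to a recording edge were skipped",
                    sum(!ok)))
  }
  .assert(any(ok), "no events with a complete epoch window")
  start <- start[ok]
  C <- nrow(recording$data)
  data <- array(0, c(length(start), C, ns))
  for (e in seq_along(start)) {
    data[e, , ] <- recording$data[, start[e]:(start[e] + ns - 1)]
  }
  times <- tmin + (seq_len(ns) - 1) / fs * 1000
  .epoch_set(data, times, fs, "evoked", condition = events$condition[ok])
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per epoch and series, the mean over the baseline window. The
#' operation is idempotent.
#'
#' @param epochs an `epoch_set`.
#' @param from,to baseline window in ms (defaults -100 to -5).
#' @return corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, from = -100, to = -5) {
  .assert(inherits(epochs, "epoch_set"), "need an epoch_set")
  sel <- epochs$times >= from & epochs$times <= to
  .assert(any(sel), "baseline window outside the epoch time axis")
  d <- epochs$data
  bl <- apply(d[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- d - array(rep(bl, dim(d)[3]), dim(d))
  epochs
}

## matrix variant (series x samples) used on evoked source maps
.baseline_mat <- function(map, times, from = -100, to = -5) {
  sel <- times >= from & times <= to
  .assert(any(sel), "baseline window outside the time axis")
  map - rowMeans(map[, sel, drop = FALSE])
}

#' Reject epochs by peak-to-peak amplitude
#'
#' Removes epochs whose maximum channel peak-to-peak amplitude exceeds
#' `limit`. This deterministic criterion replaces visual trial review.
#'
#' @param epochs an `epoch_set`.
#' @param limit peak-to-peak threshold in sensor units (`Inf` keeps all).
#' @return the retained `epoch_set`, with attribute `rejection` — a list
#'   with `n_total`, `n_rejected`, `fraction` and the rejected indices.
#' @export
reject_trials <- function(epochs, limit) {
  .assert(inherits(epochs, "epoch_set"), "need an epoch_set")
  .assert(is.numeric(limit) && limit > 0, "limit must be positive")
  d <- epochs$data
  ptp <- apply(d, 1, function(m) max(apply(m, 1, function(x) diff(range(x)))))
  keep <- ptp <= limit
  .assert(any(keep), "all trials rejected; pipeline cannot proceed")
  out <- epochs
  out$data <- d[keep, , , drop = FALSE]
  out$condition <- epochs$condition[keep]
  attr(out, "rejection") <- list(n_total = length(keep),
                                 n_rejected = sum(!keep),
                                 fraction = mean(!keep),
                                 rejected = which(!keep))
  out
}
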