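## Seed-based amplitude-envelope correlation (AEC) with pairwise
## leakage-correcting orthogonalization. Band-limited source signals are
## obtained with an even-order linear-phase FIR band-pass; envelopes are the
## magnitude of the analytic signal (Hilbert transform); before correlating,
## each member of a pair is orthogonalized against the other's instantaneous
## phase-aligned component, removing the zero-lag contribution that spatial
## leakage of the inverse operator produces.

#' Canonical frequency bands
#'
#' @param name `"alpha"` (8-12 Hz) or `"beta"` (15-29 Hz), or a numeric
#'   length-2 vector taken as (low, high) in Hz.
#' @return list with `name`, `low_hz`, `high_hz`.
#' @export
band_spec <- function(name) {
  if (is.numeric(name)) {
    .assert(length(name) == 2 && name[1] > 0 && name[1] < name[2],
            "numeric band must be (low, high) with 0 < low < high")
    return(list(name = paste0(name[1], "-", name[2], "Hz"),
                low_hz = name[1], high_hz = name[2]))
  }
  switch(match.arg(name, c("alpha", "beta")),
         alpha = list(name = "alpha", low_hz = 8, high_hz = 12),
         beta = list(name = "beta", low_hz = 15, high_hz = 29))
}

#' Even-order linear-phase FIR band-pass, delay compensated
#'
#' Single-pass Hamming-window FIR filtering with the group delay (order/2
#' samples) removed and reflect-padded edges, for vectors or samples x series
#' matrices.
#'
#' @param x numeric vector or samples x series matrix.
#' @param band a [band_spec()] (or value accepted by it).
#' @param sfreq sampling frequency (Hz).
#' @param order even FIR order; default scales with `sfreq` and is capped by
#'   the series length (transition width about `3.3 * sfreq / order` Hz).
#' @return filtered data, same shape as `x`.
#' @export
fir_band_filter <- function(x, band, sfreq, order = NULL) {
  band <- if (is.list(band)) band else band_spec(band)
  nyq <- sfreq / 2
  .assert(band$high_hz < nyq, "band exceeds Nyquist")
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(xm)
  if (is.null(order)) order <- .even(min(sfreq, (n - 1) / 2.5))
  .assert(order %% 2 == 0, "FIR order must be even")
  .assert(n > order, "series shorter than the filter order")
  b <- signal::fir1(order, c(band$low_hz, band$high_hz) / nyq, type = "pass")
  y <- .fir_padded(b, xm)
  if (vec) as.vector(y) else y
}

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal (real part = input, imaginary part =
#' Hilbert transform) of each column.
#'
#' @param x numeric vector or samples x series matrix.
#' @return complex data, same shape.
#' @export
analytic_signal <- function(x) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  .assert(all(is.finite(xm)), "input must be finite")
  n <- nrow(xm)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  X <- mvfft(xm)
  a <- mvfft(X * h, inverse = TRUE) / n
  if (vec) as.vector(a) else a
}

#' Amplitude envelope (magnitude of the analytic signal)
#'
#' @inheritParams analytic_signal
#' @return non-negative envelope, same shape as `x`.
#' @export
analytic_envelope <- function(x) Mod(analytic_signal(x))

#' Orthogonalize a target analytic signal against a seed
#'
#' Time-resolved pairwise orthogonalization: per sample, the component of the
#' target analytic signal orthogonal to the seed's instantaneous phase,
#' `Im(target * Conj(seed) / |seed|)`. If the target is a real multiple of
#' the seed (pure zero-lag leakage) the result is identically zero; signal in
#' phase quadrature passes through with its envelope intact.
#'
#' @param seed_analytic,target_analytic equal-length complex vectors.
#' @return real vector; its absolute value is the leakage-corrected target
#'   envelope.
#' @export
orthogonalize_pair <- function(seed_analytic, target_analytic) {
  .assert(length(seed_analytic) == length(target_analytic),
          "series lengths differ")
  m <- Mod(seed_analytic)
  .assert(max(m) > 0, "seed is identically zero")
  Im(target_analytic * Conj(seed_analytic) / pmax(m, .Machine$double.xmin))
}

#' Amplitude envelope correlation
#'
#' Pearson correlation between two amplitude envelopes. A zero-variance
#' envelope makes the correlation undefined; `NA` is returned so callers can
#' exclude the epoch from averaging.
#'
#' @param env_a,env_b equal-length non-negative envelopes.
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
aec <- function(env_a, env_b) {
  .assert(length(env_a) == length(env_b), "envelope lengths differ")
  .assert(length(env_a) >= 3, "need at least 3 samples")
  if (sd(env_a) == 0 || sd(env_b) == 0) return(NA_real_)
  cor(env_a, env_b)
}

## column-wise Pearson correlation between paired columns of two matrices
.paired_col_cor <- function(A, B) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  num <- colSums(A * B)
  den <- sqrt(colSums(A^2) * colSums(B^2))
  ifelse(den > 0, num / den, NA_real_)
}

## orthogonalized bidirectional AEC of a seed series against every column of
## a source matrix, one epoch. X: samples x V (raw, unfiltered); returns
## per-vertex AEC (NA where undefined).
.aec_epoch <- function(X, seed_idx, band, sfreq, trim_ms, order = NULL) {
  seed_series <- rowMeans(X[, seed_idx, drop = FALSE])
  filt <- fir_band_filter(cbind(seed_series, X), band, sfreq, order)
  A <- analytic_signal(filt)
  n <- nrow(A)
  tr <- round(trim_ms * sfreq / 1000)
  .assert(n - 2 * tr >= 8, "epoch too short after edge trimming")
  A <- A[(tr + 1):(n - tr), , drop = FALSE]
  S <- A[, 1]
  Y <- A[, -1, drop = FALSE]
  envS <- Mod(S)
  envY <- Mod(Y)
  ## target orthogonalized to seed
  U <- S / pmax(envS, .Machine$double.xmin)
  env_t_orth <- abs(Im(Y * Conj(U)))
  r1 <- suppressWarnings(as.vector(cor(envS, env_t_orth)))
  ## seed orthogonalized to each target
  UY <- Y / pmax(envY, .Machine$double.xmin)
  env_s_orth <- abs(Im(S * Conj(UY)))
  r2 <- .paired_col_cor(env_s_orth, envY)
  r1[!is.finite(r1)] <- NA_real_
  (r1 + r2) / 2
}

#' Seed-based orthogonalized AEC connectivity map
#'
#' The seed series is the mean of the seed vertices' raw time courses
#' (averaged before any connectivity computation). Per epoch, seed and
#' targets are band-filtered, the analytic signal is taken, the first and
#' last `trim_ms` are discarded (Hilbert edge effects), and the
#' orthogonalized AEC is computed in both directions (target against seed and
#' seed against target) and averaged; per-epoch values are then averaged into
#' one map (Fisher-z averaging optional). Epochs where a vertex's value is
#' undefined (zero variance — including the seed vertices themselves, whose
#' orthogonalized residual is identically zero) are excluded for that vertex;
#' a vertex with no valid epoch gets `NA`.
#'
#' @param source_epochs a source-level `epoch_set`, or an epochs x V x
#'   samples array.
#' @param seed_vertices integer vertex indices (default scouts have 10).
#' @param band a [band_spec()] or its argument.
#' @param sfreq sampling frequency; taken from the epoch set when omitted.
#' @param trim_ms edge trim per epoch side in ms.
#' @param fisher average epochs on the Fisher-z scale.
#' @param order optional FIR order passed to [fir_band_filter()].
#' @return numeric vector of class `connectivity_map` (length V) with
#'   attributes `band`, `seed`, `n_epochs`, `n_valid`.
#' @export
seed_fc_map <- function(source_epochs, seed_vertices, band, sfreq = NULL,
                        trim_ms = 200, fisher = FALSE, order = NULL) {
  if (inherits(source_epochs, "epoch_set")) {
    sfreq <- sfreq %||% source_epochs$sfreq
    d <- source_epochs$data
  } else {
    d <- source_epochs
    .assert(!is.null(sfreq), "sfreq required for array input")
  }
  .assert(length(dim(d)) == 3, "source epochs must be epochs x V x samples")
  E <- dim(d)[1]; V <- dim(d)[2]
  .assert(E >= 2, "need at least 2 epochs")
  .assert(all(seed_vertices >= 1 & seed_vertices <= V), "seed vertex out of range")
  .assert(!anyDuplicated(seed_vertices), "seed vertices must be distinct")
  band <- if (is.list(band)) band else band_spec(band)
  rmat <- matrix(NA_real_, E, V)
  for (e in seq_len(E)) {
    rmat[e, ] <- .aec_epoch(t(d[e, , ]), seed_vertices, band, sfreq, trim_ms,
                            order)
  }
  out <- .avg_epoch_values(rmat, fisher)
  if (any(out$n_valid == 0)) {
    message(sprintf("seed_fc_map: %d vertex/vertices with no valid epoch (NA)",
                    sum(out$n_valid == 0)))
  }
  structure(out$map, band = band$name, seed = seed_vertices, n_epochs = E,
            n_valid = out$n_valid, fisher = fisher, class = "connectivity_map")
}

## average per-epoch values into one map; summation runs over values sorted
## within each vertex, so the result is invariant to epoch relabeling down to
## the last bit
.avg_epoch_values <- function(rmat, fisher) {
  map <- apply(rmat, 2, function(col) {
    ok <- is.finite(col)
    if (!any(ok)) return(NA_real_)
    v <- sort(col[ok])
    if (fisher) tanh(mean(atanh(pmin(pmax(v, -1 + 1e-12), 1 - 1e-12))))
    else mean(v)
  })
  list(map = map, n_valid = colSums(is.finite(rmat)))
}

#' Streamed seed AEC map from sensor epochs and beamformer weights
#'
#' Equivalent to `seed_fc_map(apply_inverse(weights, epochs), ...)` but
#' inverts one epoch at a time, so the full source-level epoch array is never
#' held in memory.
#'
#' @param weights `beamformer_weights` (V x channels).
#' @param sensor_epochs sensor-level `epoch_set`.
#' @inheritParams seed_fc_map
#' @return a `connectivity_map`.
#' @export
compute_fc_map <- function(weights, sensor_epochs, seed_vertices, band,
                           trim_ms = 200, fisher = FALSE, order = NULL) {
  .assert(inherits(sensor_epochs, "epoch_set"), "need an epoch_set")
  d <- sensor_epochs$data
  E <- dim(d)[1]
  .assert(E >= 2, "need at least 2 epochs")
  W <- unclass(weights)
  V <- nrow(W)
  band <- if (is.list(band)) band else band_spec(band)
  sfreq <- sensor_epochs$sfreq
  rmat <- matrix(NA_real_, E, V)
  for (e in seq_len(E)) {
    src <- W %*% d[e, , ]
    rmat[e, ] <- .aec_epoch(t(src), seed_vertices, band, sfreq, trim_ms, order)
  }
  out <- .avg_epoch_values(rmat, fisher)
  structure(out$map, band = band$name, seed = seed_vertices, n_epochs = E,
            n_valid = out$n_valid, fisher = fisher, class = "connectivity_map")
}
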