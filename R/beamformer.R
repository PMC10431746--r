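## LCMV beamformer inversion. The spatial filter for a source with (free)
## lead field L and data covariance C is W = (L' C^-1 L)^-1 L' C^-1 ; the 3D
## weights are then projected onto the cortical orientation (outward surface
## normal) to yield one constrained weight vector per vertex. The covariance
## is regularized by replacing every eigenvalue below its median with the
## median itself.

#' Average per-epoch data covariance
#'
#' Computes the channel covariance per epoch over a time window (samples
#' channel-centred within the window) and averages across epochs.
#'
#' @param epochs an `epoch_set` (sensor level).
#' @param window_ms length-2 vector of window bounds in ms on the epoch time
#'   axis, or `NULL` for the whole epoch.
#' @return channels x channels matrix of class `covariance_matrix`.
#' @export
compute_data_covariance <- function(epochs, window_ms = NULL) {
  .assert(inherits(epochs, "epoch_set"), "need an epoch_set")
  d <- epochs$data
  .assert(dim(d)[1] >= 2, "need at least 2 epochs")
  sel <- if (is.null(window_ms)) rep(TRUE, length(epochs$times)) else
    epochs$times >= window_ms[1] & epochs$times <= window_ms[2]
  .assert(sum(sel) >= 2, "covariance window is empty")
  C <- dim(d)[2]
  acc <- matrix(0, C, C)
  for (e in seq_len(dim(d)[1])) {
    x <- d[e, , sel, drop = TRUE]
    x <- x - rowMeans(x)
    acc <- acc + tcrossprod(x) / (ncol(x) - 1)
  }
  out <- acc / dim(d)[1]
  out <- (out + t(out)) / 2
  structure(out, window_ms = window_ms, n_epochs = dim(d)[1],
            class = c("covariance_matrix", "matrix"))
}

#' Median-eigenvalue covariance regularization
#'
#' Eigendecomposes a symmetric covariance matrix and replaces every
#' eigenvalue smaller than the median eigenvalue with the median itself,
#' reconstructing with unchanged eigenvectors. No eigenvalue is ever
#' decreased, so the result is positive definite whenever the median
#' eigenvalue is positive, with condition number at most
#' `max(eigenvalue) / median(eigenvalue)`.
#'
#' @param cov symmetric channels x channels matrix.
#' @return regularized matrix (class `covariance_matrix`) with attributes
#'   `median_eig` and `eigenvalues` (the originals).
#' @export
regularize_median_eig <- function(cov) {
  .assert(is.matrix(cov) && nrow(cov) == ncol(cov), "cov must be square")
  scale <- max(abs(cov))
  .assert(max(abs(cov - t(cov))) <= 1e-10 * max(scale, .Machine$double.eps),
          "cov must be symmetric")
  e <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  med <- median(e$values)
  vals <- pmax(e$values, med)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- (out + t(out)) / 2
  structure(out, median_eig = med, eigenvalues = e$values,
            class = c("covariance_matrix", "matrix"))
}

## symmetric pseudo-inverse with relative eigenvalue threshold
.sym_pinv <- function(m, tol = 1e-12) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values))
  iv <- ifelse(keep, 1 / e$values, 0)
  e$vectors %*% (iv * t(e$vectors))
}

#' LCMV beamformer weights with cortical-orientation projection
#'
#' For each vertex v with free-orientation lead field `L_v` (channels x 3),
#' computes the 3D minimum-variance weights
#' `W_v = (L_v' C^-1 L_v)^-1 L_v' C^-1` and projects them onto the outward
#' surface normal `n_v`, giving the constrained filter `w_v = n_v' W_v`
#' (`orientation = "weights"`, the default). With
#' `orientation = "leadfield"` the lead field is first constrained
#' (`l_v = L_v n_v`) and the scalar LCMV filter
#' `w_v = (l_v' C^-1 l_v)^-1 l_v' C^-1` is used. Because a spherical
#' conductor renders the radial source orientation silent, `L_v' C^-1 L_v`
#' is rank-deficient by construction; it is inverted on its numerical range
#' (eigenvalue pseudo-inverse, relative threshold 1e-10) and the projected
#' weight is renormalized so that the unit-gain constraint `w_v' l_v = 1`
#' holds exactly for the constrained lead field `l_v = L_v n_v`. Fully
#' degenerate vertices are flagged and their weights zeroed.
#'
#' @param leadfield free-orientation `leadfield` (channels x 3V).
#' @param cov regularized data covariance (channels x channels), e.g. from
#'   [regularize_median_eig()].
#' @param normals V x 3 outward unit normals.
#' @param orientation `"weights"` (project the 3D weights) or `"leadfield"`
#'   (constrain the lead field first).
#' @param tol relative pseudo-inverse threshold.
#' @return V x channels matrix of class `beamformer_weights`, with attribute
#'   `flagged` (logical V).
#' @export
lcmv_weights <- function(leadfield, cov, normals,
                         orientation = c("weights", "leadfield"),
                         tol = 1e-12) {
  orientation <- match.arg(orientation)
  .assert(attr(leadfield, "mode") %||% "free" == "free",
          "leadfield must be free-orientation (channels x 3V)")
  V <- ncol(leadfield) / 3L
  .assert(V == nrow(normals), "normals do not match lead field")
  .assert(nrow(leadfield) == nrow(cov), "channel dimensions differ")
  Cinv <- .sym_pinv(unclass(cov), tol)
  lf <- unclass(leadfield)
  CinvL <- Cinv %*% lf
  W <- matrix(0, V, nrow(cov))
  flagged <- logical(V)
  for (v in seq_len(V)) {
    cols <- (3 * (v - 1) + 1):(3 * v)
    if (orientation == "weights") {
      G <- crossprod(lf[, cols], CinvL[, cols])
      G <- (G + t(G)) / 2
      ## in a spherical conductor the 3D lead field has an exact null (radial)
      ## direction, so G is rank-deficient by construction: invert on its
      ## numerical range and renormalize to unit gain along the normal
      eG <- eigen(G, symmetric = TRUE)
      keep <- eG$values > 1e-10 * max(eG$values, 0)
      if (!any(keep)) {
        flagged[v] <- TRUE
        next
      }
      Ginv <- eG$vectors %*% (ifelse(keep, 1 / eG$values, 0) * t(eG$vectors))
      W3 <- Ginv %*% t(CinvL[, cols, drop = FALSE])
      w <- as.vector(normals[v, ] %*% W3)
      gain <- sum(w * (lf[, cols, drop = FALSE] %*% normals[v, ]))
      if (abs(gain) < 1e-12) {
        flagged[v] <- TRUE
        next
      }
      W[v, ] <- w / gain
    } else {
      l <- lf[, cols, drop = FALSE] %*% normals[v, ]
      den <- as.numeric(crossprod(l, Cinv %*% l))
      if (den <= .Machine$double.eps * sum(l^2)) {
        flagged[v] <- TRUE
        next
      }
      W[v, ] <- t(Cinv %*% l) / den
    }
  }
  if (any(flagged)) {
    message(sprintf("lcmv_weights: %d vertex/vertices flagged singular and zeroed",
                    sum(flagged)))
  }
  structure(W, flagged = flagged, orientation = orientation,
            class = c("beamformer_weights", "matrix"))
}

#' Apply beamformer weights to sensor data
#'
#' Linear spatial filtering: per epoch, `source = W %*% sensor`.
#'
#' @param weights `beamformer_weights` (V x channels).
#' @param epochs a sensor-level `epoch_set`, or a channels x samples matrix.
#' @return a source-level `epoch_set` (epochs x V x samples) or a V x samples
#'   matrix, matching the input.
#' @export
apply_inverse <- function(weights, epochs) {
  W <- unclass(weights)
  if (is.matrix(epochs)) {
    .assert(ncol(W) == nrow(epochs), "channel dimensions differ")
    return(W %*% epochs)
  }
  .assert(inherits(epochs, "epoch_set"), "need an epoch_set or matrix")
  d <- epochs$data
  .assert(ncol(W) == dim(d)[2], "channel dimensions differ")
  E <- dim(d)[1]; S <- dim(d)[3]
  out <- array(0, c(E, nrow(W), S))
  for (e in seq_len(E)) out[e, , ] <- W %*% d[e, , ]
  res <- epochs
  res$data <- out
  res
}

#' Beamformer output power map
#'
#' Source variance per vertex, `w_v' C w_v`, for a (typically unregularized)
#' data covariance.
#'
#' @param weights `beamformer_weights`.
#' @param cov channels x channels covariance.
#' @return numeric vector of per-vertex power.
#' @export
beamformer_power <- function(weights, cov) {
  W <- unclass(weights)
  rowSums((W %*% unclass(cov)) * W)
}

#' Neural activity index (noise-normalized beamformer power)
#'
#' Van Veen's NAI: output power divided by the filter's white-noise gain,
#' `(w_v' C w_v) / (w_v' w_v)`. Unit-gain output power alone is inflated at
#' vertices with weak lead fields (the filter amplifies noise there); the
#' NAI removes that bias, so its argmax localizes a dominant source.
#'
#' @inheritParams beamformer_power
#' @return numeric vector of per-vertex NAI.
#' @export
beamformer_nai <- function(weights, cov) {
  W <- unclass(weights)
  num <- rowSums((W %*% unclass(cov)) * W)
  den <- rowSums(W^2)
  ifelse(den > 0, num / den, 0)
}
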