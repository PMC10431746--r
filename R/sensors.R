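#' Construct a helmet-like MEG sensor array
#'
#' Places sensors quasi-uniformly (Fibonacci lattice) on a sphere of radius
#' `radius`, keeping only positions above `min_z * radius` to emulate a
#' helmet. Magnetometers measure the field component along their orientation
#' (radial by default). Optional planar gradiometers are modeled as the
#' difference of two point magnetometers separated by `grad_baseline` along a
#' tangential axis, divided by the baseline (units T/m).
#'
#' @param n_sites number of sensor sites.
#' @param radius sensor shell radius in metres.
#' @param min_z keep sites with z > `min_z * radius` (helmet opening).
#' @param gradiometers if `TRUE`, add two orthogonal planar gradiometers per
#'   site (triple-sensor layout); default magnetometers only.
#' @param grad_baseline planar gradiometer baseline in metres.
#' @param center centre of the sensor shell.
#' @return An object of class `sensor_array`: list with `pos` (n x 3), `ori`
#'   (n x 3 measurement direction), `pos2` (n x 3, second coil position for
#'   gradiometers, `NA` for magnetometers), `type` (character), `baseline`,
#'   and `n_channels`.
#' @export
sensor_array <- function(n_sites = 102, radius = 0.102, min_z = -0.35,
                         gradiometers = FALSE, grad_baseline = 0.0168,
                         center = c(0, 0, 0)) {
  .assert(.is_count(n_sites), "n_sites must be a positive integer")
  .assert(radius > 0, "radius must be positive")
  ## Fibonacci lattice on the full sphere, clipped to the helmet, then topped
  ## up so exactly n_sites survive
  golden <- pi * (3 - sqrt(5))
  n_try <- n_sites
  repeat {
    i <- seq_len(n_try) - 0.5
    z <- 1 - 2 * i / n_try
    keep <- z > min_z
    if (sum(keep) >= n_sites) break
    n_try <- n_try + max(1L, n_sites %/% 8L)
  }
  i <- which(keep)[seq_len(n_sites)]
  z <- 1 - 2 * (i - 0.5) / n_try
  th <- golden * (i - 1)
  rho <- sqrt(pmax(0, 1 - z^2))
  u <- cbind(rho * cos(th), rho * sin(th), z)
  pos <- u * radius + matrix(center, n_sites, 3, byrow = TRUE)
  ori <- u                                 # radial measurement direction
  pos2 <- matrix(NA_real_, n_sites, 3)
  type <- rep("magnetometer", n_sites)
  if (gradiometers) {
    ## two tangential axes per site
    ref <- matrix(rep(c(0, 0, 1), n_sites), n_sites, 3, byrow = TRUE)
    swap <- abs(u[, 3]) > 0.9
    ref[swap, ] <- matrix(rep(c(1, 0, 0), sum(swap)), sum(swap), 3, byrow = TRUE)
    t1 <- cbind(u[, 2] * ref[, 3] - u[, 3] * ref[, 2],
                u[, 3] * ref[, 1] - u[, 1] * ref[, 3],
                u[, 1] * ref[, 2] - u[, 2] * ref[, 1])
    t1 <- t1 / sqrt(rowSums(t1^2))
    t2 <- cbind(u[, 2] * t1[, 3] - u[, 3] * t1[, 2],
                u[, 3] * t1[, 1] - u[, 1] * t1[, 3],
                u[, 1] * t1[, 2] - u[, 2] * t1[, 1])
    gpos <- rbind(pos - t1 * grad_baseline / 2, pos - t2 * grad_baseline / 2)
    gpos2 <- rbind(pos + t1 * grad_baseline / 2, pos + t2 * grad_baseline / 2)
    gori <- rbind(ori, ori)
    pos <- rbind(pos, gpos)
    pos2 <- rbind(pos2, gpos2)
    ori <- rbind(ori, gori)
    type <- c(type, rep("gradiometer", 2 * n_sites))
  }
  structure(list(pos = pos, pos2 = pos2, ori = ori, type = type,
                 baseline = grad_baseline, center = center,
                 n_channels = nrow(pos)), class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d channels (%d magnetometer, %d gradiometer)\n",
              x$n_channels, sum(x$type == "magnetometer"),
              sum(x$type == "gradiometer")))
  invisible(x)
}
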