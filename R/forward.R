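## Spherical-conductor MEG forward solution.
##
## The magnetic field of a current dipole in a spherically symmetric conductor
## has the closed form of Sarvas (J. Phys. Med. Biol. 1987): with the sphere
## centre at the origin, dipole moment Q at r0, field point r,
##   a = r - r0,  F = a (r a + r^2 - r0.r)
##   grad F = (a^2/r + (a.r)/a + 2a + 2r) r - (a + 2r + (a.r)/a) r0
##   B(r) = mu0/(4 pi F^2) * (F (Q x r0) - ((Q x r0).r) grad F)
## Two classical properties are exploited by the tests: the field is linear in
## Q, and a radial dipole (Q parallel to r0) produces exactly zero external
## field. The solution is independent of the conductor radius; the radius
## enters only through the validity requirement that sources lie inside and
## sensors outside the conductor.

MU0_4PI <- 1e-7  # T m / A

## Field of dipoles at rows of R0 (relative to sphere centre) with moments Q
## (V x 3), evaluated at a single point r (relative to centre). Returns V x 3.
.sarvas_field <- function(r, R0, Q) {
  rn <- sqrt(sum(r^2))
  A <- matrix(r, nrow(R0), 3, byrow = TRUE) - R0
  an <- sqrt(rowSums(A^2))
  r0_dot_r <- as.vector(R0 %*% r)
  a_dot_r <- as.vector(A %*% r)
  F <- an * (rn * an + rn^2 - r0_dot_r)
  c1 <- an^2 / rn + a_dot_r / an + 2 * an + 2 * rn
  c2 <- an + 2 * rn + a_dot_r / an
  gradF <- cbind(c1 * r[1] - c2 * R0[, 1],
                 c1 * r[2] - c2 * R0[, 2],
                 c1 * r[3] - c2 * R0[, 3])
  QxR0 <- cbind(Q[, 2] * R0[, 3] - Q[, 3] * R0[, 2],
                Q[, 3] * R0[, 1] - Q[, 1] * R0[, 3],
                Q[, 1] * R0[, 2] - Q[, 2] * R0[, 1])
  qr <- as.vector(QxR0 %*% r)
  (MU0_4PI / F^2) * (F * QxR0 - qr * gradF)
}

#' Spherical-head MEG lead field
#'
#' Computes the lead field of every source-space vertex for a sensor array
#' using the analytic spherical-conductor solution. Gradiometer channels are
#' modeled as the difference of two point magnetometers divided by the
#' baseline. With `mode = "free"` the result has three columns per vertex
#' (x/y/z unit dipole moments, units T per A m); with `mode = "constrained"`
#' the three components are projected onto the vertex's outward surface
#' normal, giving one column per vertex.
#'
#' @param src a `source_space`.
#' @param sensors a `sensor_array`.
#' @param sphere_center conductor centre (head frame, metres).
#' @param conductor_radius conductor radius used only to validate geometry
#'   (sources strictly inside, sensors strictly outside).
#' @param mode `"free"` or `"constrained"`.
#' @return A numeric matrix of class `leadfield` (channels x 3V or channels x
#'   V) with attributes `n_vertices`, `mode`.
#' @export
sphere_forward <- function(src, sensors, sphere_center = src$center,
                           conductor_radius = 0.09,
                           mode = c("free", "constrained")) {
  mode <- match.arg(mode)
  .assert(inherits(src, "source_space"), "src must be a source_space")
  .assert(inherits(sensors, "sensor_array"), "sensors must be a sensor_array")
  V <- src$n_vertices
  R0 <- src$vertices - matrix(sphere_center, V, 3, byrow = TRUE)
  rad <- sqrt(rowSums(R0^2))
  .assert(all(rad < conductor_radius),
          "all sources must lie strictly inside the conductor sphere")
  .assert(all(rad > 1e-4 * conductor_radius),
          "source at the sphere centre is degenerate")
  spos <- sensors$pos - matrix(sphere_center, nrow(sensors$pos), 3, byrow = TRUE)
  .assert(all(sqrt(rowSums(spos^2)) > conductor_radius),
          "all sensors must lie outside the conductor sphere")

  basis <- diag(3)
  point_row <- function(r, ori) {
    ## 3V-vector: ori-projected field per vertex per basis moment
    out <- matrix(0, V, 3)
    for (k in 1:3) {
      Q <- matrix(basis[k, ], V, 3, byrow = TRUE)
      out[, k] <- .sarvas_field(r, R0, Q) %*% ori
    }
    as.vector(t(out))  # v1x v1y v1z v2x ...
  }
  n_ch <- sensors$n_channels
  lf <- matrix(0, n_ch, 3 * V)
  for (ch in seq_len(n_ch)) {
    ori <- sensors$ori[ch, ]
    if (sensors$type[ch] == "gradiometer") {
      p1 <- sensors$pos[ch, ] - sphere_center
      p2 <- sensors$pos2[ch, ] - sphere_center
      lf[ch, ] <- (point_row(p2, ori) - point_row(p1, ori)) / sensors$baseline
    } else {
      lf[ch, ] <- point_row(spos[ch, ], ori)
    }
  }
  if (mode == "constrained") lf <- .constrain_lf(lf, src$normals)
  structure(lf, n_vertices = V, mode = mode, class = c("leadfield", "matrix"))
}

.constrain_lf <- function(lf, normals) {
  V <- nrow(normals)
  ix <- seq(1, 3 * V, by = 3)
  lf[, ix, drop = FALSE] * matrix(normals[, 1], nrow(lf), V, byrow = TRUE) +
    lf[, ix + 1, drop = FALSE] * matrix(normals[, 2], nrow(lf), V, byrow = TRUE) +
    lf[, ix + 2, drop = FALSE] * matrix(normals[, 3], nrow(lf), V, byrow = TRUE)
}

#' Constrain a free-orientation lead field to surface normals
#'
#' @param lf a `leadfield` in free-orientation mode (channels x 3V).
#' @param normals V x 3 unit normals.
#' @return channels x V constrained lead field.
#' @export
constrain_leadfield <- function(lf, normals) {
  .assert(attr(lf, "mode") == "free", "lead field is not free-orientation")
  .assert(ncol(lf) == 3 * nrow(normals), "normals do not match lead field")
  out <- .constrain_lf(unclass(lf), normals)
  structure(out, n_vertices = nrow(normals), mode = "constrained",
            class = c("leadfield", "matrix"))
}

## ---------------------------------------------------------------------------
## Independent numerical oracle: Biot-Savart quadrature of the conductor's
## secondary (volume) currents, reduced to the boundary by the Geselowitz
## surface formula
##   B(r) = B_primary(r) - mu0 sigma/(4 pi) \oint V(r') n' x (r - r')/|r-r'|^3 dS'
## with the surface potential V of a dipole in a homogeneous sphere given by
## its classical zonal-harmonic series. This route shares no algebra with the
## Sarvas closed form above and is used only for validation.

.gauss_legendre <- function(n) {
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = 2 * e$vectors[1, ord]^2)
}

## Surface potential on a homogeneous conducting sphere (radius R, centre at
## origin, insulating exterior) of a dipole p at r0. x = cos(angle between
## field point and r0 axis); phi = azimuth about the r0 axis measured from the
## tangential component of p. Series over degrees n:
##   V = 1/(4 pi sigma) sum_n (2n+1)/n b^(n-1)/R^(n+1)
##         [ n p_rad P_n(x) + p_tan A_n(x) cos(phi) ]
## where A_n is the order-1 associated Legendre function without the
## Condon-Shortley phase (A_1 = sqrt(1-x^2)).
.sphere_surface_potential <- function(x, phi, b, R, p_rad, p_tan, sigma,
                                      n_terms = 80L) {
  s <- sqrt(pmax(0, 1 - x^2))
  P_prev <- rep(1, length(x))   # P_0
  P_cur <- x                    # P_1
  A_prev <- rep(0, length(x))   # A_0
  A_cur <- s                    # A_1
  acc <- (3 / R^2) * (1 * p_rad * P_cur + p_tan * A_cur * cos(phi))
  if (n_terms >= 2) {
    for (n in 2:n_terms) {
      P_new <- ((2 * n - 1) * x * P_cur - (n - 1) * P_prev) / n
      A_new <- ((2 * n - 1) * x * A_cur - n * A_prev) / (n - 1)
      coef <- (2 * n + 1) / n * b^(n - 1) / R^(n + 1)
      acc <- acc + coef * (n * p_rad * P_new + p_tan * A_new * cos(phi))
      P_prev <- P_cur; P_cur <- P_new
      A_prev <- A_cur; A_cur <- A_new
    }
  }
  acc / (4 * pi * sigma)
}

#' Reference dipole field by boundary-current quadrature
#'
#' Numerical cross-check for [sphere_forward()]: the total external field is
#' computed as the Biot-Savart field of the primary current dipole plus the
#' Biot-Savart quadrature of the conductor's secondary currents over the
#' sphere boundary (Geselowitz surface integral), using the classical
#' Legendre-series surface potential of a dipole in a homogeneous sphere.
#' Slow but entirely independent of the closed-form solution.
#'
#' @param dipole_pos 3-vector, dipole location (head frame, m).
#' @param moment 3-vector, dipole moment (A m).
#' @param sensor_pos matrix n x 3 (or 3-vector) of field points outside the
#'   conductor.
#' @param sphere_center conductor centre.
#' @param conductor_radius conductor radius (m).
#' @param sigma conductivity (S/m); cancels in the result.
#' @param n_theta,n_phi quadrature resolution over the boundary.
#' @param n_terms Legendre series length for the surface potential.
#' @return n x 3 matrix of field vectors (T).
#' @export
field_quadrature_oracle <- function(dipole_pos, moment, sensor_pos,
                                    sphere_center = c(0, 0, 0),
                                    conductor_radius = 0.09, sigma = 0.33,
                                    n_theta = 160L, n_phi = 320L,
                                    n_terms = 80L) {
  if (is.null(dim(sensor_pos))) sensor_pos <- matrix(sensor_pos, 1, 3)
  r0 <- dipole_pos - sphere_center
  b <- sqrt(sum(r0^2))
  R <- conductor_radius
  .assert(b < R, "dipole must be inside the conductor")
  ## frame aligned with the dipole position axis
  e3 <- r0 / b
  p_rad <- sum(moment * e3)
  p_tan_vec <- moment - p_rad * e3
  p_tan <- sqrt(sum(p_tan_vec^2))
  if (p_tan > 1e-14 * sqrt(sum(moment^2))) {
    e1 <- p_tan_vec / p_tan
  } else {
    ref <- if (abs(e3[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * e3) * e3
    e1 <- e1 / sqrt(sum(e1^2))
  }
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  gl <- .gauss_legendre(n_theta)
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  grid <- expand.grid(i = seq_len(n_theta), j = seq_len(n_phi))
  x <- gl$nodes[grid$i]
  ph <- phi[grid$j]
  w <- gl$weights[grid$i] * (2 * pi / n_phi) * R^2   # dS' weights
  s <- sqrt(pmax(0, 1 - x^2))
  nhat <- cbind(s * cos(ph), s * sin(ph), x) %*% rbind(e1, e2, e3)
  rp <- nhat * R + matrix(sphere_center, length(x), 3, byrow = TRUE)
  Vs <- .sphere_surface_potential(x, ph, b, R, p_rad, p_tan, sigma, n_terms)

  out <- matrix(0, nrow(sensor_pos), 3)
  for (i in seq_len(nrow(sensor_pos))) {
    r <- sensor_pos[i, ]
    ## primary dipole Biot-Savart term
    d <- r - dipole_pos
    dn3 <- sum(d^2)^1.5
    Bp <- MU0_4PI * c(moment[2] * d[3] - moment[3] * d[2],
                      moment[3] * d[1] - moment[1] * d[3],
                      moment[1] * d[2] - moment[2] * d[1]) / dn3
    ## secondary (boundary) term
    dd <- matrix(r, nrow(rp), 3, byrow = TRUE) - rp
    dn <- rowSums(dd^2)^1.5
    cr <- cbind(nhat[, 2] * dd[, 3] - nhat[, 3] * dd[, 2],
                nhat[, 3] * dd[, 1] - nhat[, 1] * dd[, 3],
                nhat[, 1] * dd[, 2] - nhat[, 2] * dd[, 1])
    Bs <- -MU0_4PI * sigma * colSums((w * Vs / dn) * cr)
    out[i, ] <- Bp + Bs
  }
  out
}

#' Field of one dipole at arbitrary points (closed form)
#'
#' Convenience wrapper around the analytic spherical solution for a single
#' dipole, returning full field vectors.
#'
#' @inheritParams field_quadrature_oracle
#' @return n x 3 matrix of field vectors (T).
#' @export
dipole_field <- function(dipole_pos, moment, sensor_pos,
                         sphere_center = c(0, 0, 0)) {
  if (is.null(dim(sensor_pos))) sensor_pos <- matrix(sensor_pos, 1, 3)
  r0 <- matrix(dipole_pos - sphere_center, 1, 3)
  Q <- matrix(moment, 1, 3)
  out <- matrix(0, nrow(sensor_pos), 3)
  for (i in seq_len(nrow(sensor_pos))) {
    r <- sensor_pos[i, ] - sphere_center
    out[i, ] <- as.vector(.sarvas_field(r, r0, Q))
  }
  out
}
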