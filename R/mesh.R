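## Synthetic cortical source space: a closed triangulated surface obtained by
## icosahedron subdivision, radially perturbed so that surface normals are not
## purely radial (a radial dipole is magnetically silent in a spherical
## conductor, so a perfectly spherical "cortex" would be invisible to MEG).

.icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, triangles = f)
}

.subdivide_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$triangles
  key <- function(a, b) paste0(min(a, b), "_", max(a, b))
  midcache <- new.env(hash = TRUE, parent = emptyenv())
  verts <- lapply(seq_len(nrow(v)), function(i) v[i, ])
  midpoint <- function(a, b) {
    k <- key(a, b)
    if (!is.null(midcache[[k]])) return(midcache[[k]])
    m <- (v[a, ] + v[b, ]) / 2
    m <- m / sqrt(sum(m^2))
    verts[[length(verts) + 1L]] <<- m
    idx <- length(verts)
    midcache[[k]] <- idx
    idx
  }
  nf <- matrix(0L, nrow(f) * 4L, 3L)
  r <- 0L
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
    nf[r + 1L, ] <- c(a, ab, ca)
    nf[r + 2L, ] <- c(b, bc, ab)
    nf[r + 3L, ] <- c(c3, ca, bc)
    nf[r + 4L, ] <- c(ab, bc, ca)
    r <- r + 4L
  }
  list(vertices = do.call(rbind, verts), triangles = nf)
}

.vertex_normals <- function(vertices, triangles) {
  n <- matrix(0, nrow(vertices), 3L)
  p1 <- vertices[triangles[, 1], , drop = FALSE]
  p2 <- vertices[triangles[, 2], , drop = FALSE]
  p3 <- vertices[triangles[, 3], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  for (k in 1:3) {
    idx <- triangles[, k]
    for (d in 1:3) n[, d] <- n[, d] + tapply_add(fn[, d], idx, nrow(vertices))
  }
  n / sqrt(rowSums(n^2))
}

## sum x into bins given by idx (length-n output); small helper avoiding a
## dependency for a one-line scatter-add
tapply_add <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

.mesh_edges <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

.adjacency_list <- function(edges, n) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  sp1 <- split(edges[, 2], edges[, 1])
  sp2 <- split(edges[, 1], edges[, 2])
  for (k in names(sp1)) adj[[as.integer(k)]] <- c(adj[[as.integer(k)]], sp1[[k]])
  for (k in names(sp2)) adj[[as.integer(k)]] <- c(adj[[as.integer(k)]], sp2[[k]])
  lapply(adj, function(x) sort(unique(x)))
}

#' Build a synthetic cortical source space
#'
#' Subdivides an icosahedron into a closed triangle mesh and perturbs the
#' radius with a smooth angular pattern, emulating gyral/sulcal folding at a
#' coarse scale. The perturbation tilts the outward normals away from the
#' radial direction, which is what makes constrained cortical sources visible
#' to MEG in a spherical conductor.
#'
#' @param subdivisions number of icosahedron subdivision rounds; vertex counts
#'   are 12, 42, 162, 642, 2562, ... The study-scale surface (15,000 vertices)
#'   corresponds to between 4 and 5 rounds; smaller meshes keep the same
#'   geometry class.
#' @param radius mean cortical radius in metres (head frame, origin at the
#'   conductor centre).
#' @param bump_amp relative amplitude of the radial perturbation.
#' @param bump_freq angular frequency of the perturbation pattern.
#' @param center 3-vector, centre of the surface in head coordinates.
#' @return An object of class `source_space`: list with `vertices` (V x 3, m),
#'   `triangles` (F x 3 indices), `normals` (V x 3 outward unit normals),
#'   `edges` (E x 2), `adjacency` (list of neighbor indices), `n_vertices`,
#'   and `center`.
#' @export
cortical_mesh <- function(subdivisions = 3, radius = 0.07, bump_amp = 0.06,
                          bump_freq = 4, center = c(0, 0, 0)) {
  .assert(.is_count(subdivisions + 1), "subdivisions must be a non-negative integer")
  .assert(radius > 0, "radius must be positive")
  m <- .icosahedron()
  for (i in seq_len(subdivisions)) m <- .subdivide_mesh(m)
  u <- m$vertices                       # unit directions
  bump <- sin(bump_freq * u[, 1] + 0.7) * cos(bump_freq * u[, 2]) +
    0.5 * sin(bump_freq * u[, 3] - 0.3)
  bump <- bump / max(abs(bump))
  r <- radius * (1 + bump_amp * bump)
  vertices <- u * r + matrix(center, nrow(u), 3, byrow = TRUE)
  normals <- .vertex_normals(vertices, m$triangles)
  ## orient outward
  flip <- rowSums(normals * u) < 0
  normals[flip, ] <- -normals[flip, ]
  edges <- .mesh_edges(m$triangles)
  structure(list(
    vertices = vertices,
    triangles = m$triangles,
    normals = normals,
    edges = edges,
    adjacency = .adjacency_list(edges, nrow(vertices)),
    n_vertices = nrow(vertices),
    center = center
  ), class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("<source_space> %d vertices, %d triangles, %d edges\n",
              x$n_vertices, nrow(x$triangles), nrow(x$edges)))
  invisible(x)
}

#' Breadth-first geodesic neighborhood on the mesh
#'
#' Returns vertices ordered by edge (hop) distance from `center`, then by
#' vertex index within each ring — the deterministic tie-break used for scout
#' construction.
#'
#' @param src a `source_space`.
#' @param center center vertex index.
#' @param n number of vertices to return (including the center).
#' @return integer vector of `n` vertex indices.
#' @export
mesh_neighborhood <- function(src, center, n) {
  .assert(inherits(src, "source_space"), "src must be a source_space")
  .assert(center >= 1 && center <= src$n_vertices, "center out of range")
  .assert(n >= 1 && n <= src$n_vertices, "n out of range")
  visited <- logical(src$n_vertices)
  out <- integer(0)
  frontier <- as.integer(center)
  visited[center] <- TRUE
  while (length(out) < n && length(frontier)) {
    out <- c(out, sort(frontier))
    nxt <- unique(unlist(src$adjacency[frontier]))
    nxt <- nxt[!visited[nxt]]
    visited[nxt] <- TRUE
    frontier <- nxt
  }
  head(out, n)
}

#' Hop distance between two vertices
#' @param src a `source_space`.
#' @param a,b vertex indices.
#' @return integer number of edges on the shortest path.
#' @export
mesh_edge_distance <- function(src, a, b) {
  if (a == b) return(0L)
  visited <- logical(src$n_vertices)
  visited[a] <- TRUE
  frontier <- as.integer(a)
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(src$adjacency[frontier]))
    nxt <- nxt[!visited[nxt]]
    if (b %in% nxt) return(d)
    visited[nxt] <- TRUE
    frontier <- nxt
  }
  Inf
}

#' Vertex nearest to a spatial direction
#'
#' Utility to pick anatomical-style landmarks (e.g. a left-central "S1"
#' location) on the synthetic surface.
#'
#' @param src a `source_space`.
#' @param direction 3-vector; compared against vertex directions from the
#'   surface centre.
#' @return vertex index.
#' @export
nearest_vertex <- function(src, direction) {
  u <- src$vertices - matrix(src$center, src$n_vertices, 3, byrow = TRUE)
  u <- u / sqrt(rowSums(u^2))
  d <- direction / sqrt(sum(direction^2))
  which.max(u %*% d)
}
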