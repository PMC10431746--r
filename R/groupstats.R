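## Group-level brain-behavior statistics: vertex-wise OLS regression of
## per-subject connectivity maps on a behavioral covariate, TFCE with
## max-statistic permutation FWE correction, extent-filtered cluster tables,
## and the nonparametric tests used on peak vertices and evoked amplitudes.

#' Vertex-wise regression of connectivity maps on a covariate
#'
#' Per vertex, the two-tailed t statistic of the OLS slope of FC on the
#' covariate (single-regressor design). With one regressor the t statistic
#' equals `r * sqrt((n - 2) / (1 - r^2))` for the Pearson correlation `r`.
#' Vertices with zero variance across subjects are flagged and given t = 0;
#' vertices where FC is numerically collinear with the covariate (`r^2`
#' within 1e-12 of 1) are flagged and capped.
#'
#' @param maps subjects x vertices matrix of per-subject connectivity values.
#' @param covariate numeric vector, one value per subject.
#' @return list of class `vertex_stat`: `t`, `r`, `flagged`, `df`.
#' @export
vertexwise_regression <- function(maps, covariate) {
  .assert(is.matrix(maps), "maps must be subjects x vertices")
  n <- nrow(maps)
  .assert(length(covariate) == n, "covariate length must match subjects")
  .assert(n >= 4, "need at least 4 subjects")
  .assert(var(covariate) > 0, "covariate has zero variance")
  xc <- covariate - mean(covariate)
  mc <- sweep(maps, 2, colMeans(maps))
  sx <- sqrt(sum(xc^2))
  sv <- sqrt(colSums(mc^2))
  flagged <- sv == 0
  r <- numeric(ncol(maps))
  r[!flagged] <- as.vector(xc %*% mc[, !flagged, drop = FALSE]) /
    (sx * sv[!flagged])
  r <- pmin(pmax(r, -1), 1)
  sat <- r^2 > 1 - 1e-12
  t <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  t[flagged] <- 0
  flagged <- flagged | sat
  structure(list(t = t, r = r, flagged = flagged, df = n - 2),
            class = "vertex_stat")
}

#' Threshold-free cluster enhancement
#'
#' Enhances a vertex statistic map on a mesh: `TFCE(v) = sum_h e(v,h)^E *
#' h^H * dh` over `n_steps` equally spaced thresholds up to the map maximum,
#' where `e(v,h)` is the extent (vertex count) of the connected
#' supra-threshold component containing `v`. With the default two-tailed
#' handling, positive and negative parts are enhanced separately and
#' recombined with their signs.
#'
#' @param stat_map numeric vertex statistic (finite).
#' @param edges E x 2 matrix of 1-based mesh edges (e.g. `src$edges`).
#' @param E,H TFCE exponents (defaults 0.5 and 2).
#' @param n_steps threshold ladder resolution per sign; the step is
#'   `h_max / n_steps` (default 100).
#' @param two_tailed enhance the negative tail as well (default `TRUE`).
#' @param h_max top of the threshold ladder; defaults to the map maximum
#'   (per tail). Supplying a common `h_max` makes scores comparable across
#'   maps (e.g. for monotonicity checks); values above `h_max` still
#'   contribute through every rung below it.
#' @return numeric vector of enhanced values (signed if two-tailed).
#' @export
tfce_enhance <- function(stat_map, edges, E = 0.5, H = 2, n_steps = 100,
                         two_tailed = TRUE, h_max = NULL) {
  .assert(all(is.finite(stat_map)), "stat map must be finite")
  .assert(E > 0 && H > 0, "E and H must be positive")
  .assert(n_steps >= 1, "n_steps must be >= 1 (dh > 0)")
  a <- as.integer(edges[, 1])
  b <- as.integer(edges[, 2])
  one_tail <- function(x) {
    .tfce_cpp(x, a, b, E, H, as.integer(n_steps), h_max %||% -1)
  }
  pos <- one_tail(pmax(stat_map, 0))
  if (!two_tailed) return(pos)
  neg <- one_tail(pmax(-stat_map, 0))
  pos - neg
}

#' Permutation FWE-corrected TFCE inference
#'
#' Max-statistic permutation test for the vertex-wise regression: the
#' covariate is permuted across subjects, the full t map and its two-tailed
#' TFCE enhancement are recomputed for every permutation, and the null
#' distribution of the maximum |TFCE| over vertices (pooled over both tails)
#' yields family-wise-error-corrected p values with the add-one estimator
#' `p(v) = (1 + #(max_perm >= TFCE(v))) / (1 + n_permutations)`. When the
#' number of distinct permutations `n!` does not exceed `n_permutations`,
#' all of them are enumerated instead and `p(v) = #(max >= TFCE(v)) / n!`
#' (the identity permutation included).
#'
#' @param maps subjects x vertices matrix.
#' @param covariate numeric covariate per subject.
#' @param edges mesh edges (E x 2).
#' @param E,H,n_steps TFCE parameters, see [tfce_enhance()].
#' @param n_permutations number of random permutations (study-scale 10,000;
#'   default 1000 for desk use).
#' @param rng_seed integer seed for the permutation draw.
#' @return list of class `fwe_result`: `t`, `tfce` (signed), `p` (FWE), `r`,
#'   `flagged`, `null_max`, `exact`, `n_permutations`, `rng_seed`.
#' @export
permutation_fwe <- function(maps, covariate, edges, E = 0.5, H = 2,
                            n_steps = 100, n_permutations = 1000,
                            rng_seed = 1) {
  .assert(n_permutations >= 100, "need at least 100 permutations")
  vs <- vertexwise_regression(maps, covariate)
  tf <- tfce_enhance(vs$t, edges, E, H, n_steps)
  n <- nrow(maps)
  a <- as.integer(edges[, 1]); b <- as.integer(edges[, 2])
  max_tfce <- function(tvec) {
    p <- .tfce_cpp(pmax(tvec, 0), a, b, E, H, as.integer(n_steps), -1)
    q <- .tfce_cpp(pmax(-tvec, 0), a, b, E, H, as.integer(n_steps), -1)
    max(max(p), max(q))
  }
  exact <- factorial(n) <= n_permutations
  if (exact) {
    perms <- .all_perms(n)
    null_max <- apply(perms, 1, function(ix) {
      max_tfce(vertexwise_regression(maps, covariate[ix])$t)
    })
    p <- vapply(abs(tf), function(v) mean(null_max >= v - 1e-12), 0)
  } else {
    null_max <- with_rng_seed(rng_seed, {
      vapply(seq_len(n_permutations), function(i) {
        max_tfce(vertexwise_regression(maps, sample(covariate))$t)
      }, 0)
    })
    p <- vapply(abs(tf), function(v) {
      (1 + sum(null_max >= v - 1e-12)) / (1 + n_permutations)
    }, 0)
  }
  structure(list(t = vs$t, tfce = tf, p = p, r = vs$r, flagged = vs$flagged,
                 null_max = null_max, exact = exact,
                 n_permutations = if (exact) length(null_max) else n_permutations,
                 rng_seed = rng_seed),
            class = "fwe_result")
}

#' Extent-filtered cluster table
#'
#' Connected components of vertices significant at `alpha`, dropping
#' components whose extent does not exceed `k_min` vertices. The table
#' reports, per surviving cluster, the extent `k_e`, the peak vertex (lowest
#' p, ties broken by lowest index), and the peak p value.
#'
#' @param p_map vertex-wise (FWE-corrected) p values.
#' @param edges mesh edges (E x 2).
#' @param alpha significance threshold (default 0.05).
#' @param k_min cluster-forming extent floor; clusters must have
#'   `k_e > k_min` (default 50).
#' @return data frame with columns `cluster`, `k_e`, `peak_vertex`,
#'   `peak_p`, and attribute `vertices` (list of member indices).
#' @export
cluster_filter <- function(p_map, edges, alpha = 0.05, k_min = 50) {
  .assert(all(p_map >= 0 & p_map <= 1, na.rm = TRUE), "invalid p values")
  sig <- which(p_map < alpha)
  empty <- data.frame(cluster = integer(0), k_e = integer(0),
                      peak_vertex = integer(0), peak_p = numeric(0))
  if (!length(sig)) return(structure(empty, vertices = list()))
  keep_e <- edges[, 1] %in% sig & edges[, 2] %in% sig
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges[keep_e, 1]),
                   to = as.character(edges[keep_e, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(sig)))
  comp <- igraph::components(g)
  memb <- split(as.integer(igraph::V(g)$name), comp$membership)
  memb <- memb[vapply(memb, length, 0L) > k_min]
  if (!length(memb)) return(structure(empty, vertices = list()))
  ## order clusters by extent (largest first), then by peak p
  ord <- order(-vapply(memb, length, 0L),
               vapply(memb, function(v) min(p_map[v]), 0))
  memb <- memb[ord]
  rows <- lapply(seq_along(memb), function(i) {
    v <- sort(memb[[i]])
    pv <- p_map[v]
    peak <- v[which.min(pv)]
    data.frame(cluster = i, k_e = length(v), peak_vertex = peak,
               peak_p = min(pv))
  })
  structure(do.call(rbind, rows), vertices = unname(memb))
}

#' Spearman rank correlation with Bonferroni correction
#'
#' Two-tailed Spearman correlation (average ranks for ties). For n <= 9
#' without ties the p value is exact, from full enumeration of all rank
#' permutations (`p = P(|rho_perm| >= |rho_obs|)`); otherwise the
#' t-distribution approximation is used.
#'
#' @param x,y numeric vectors (n >= 4).
#' @param n_comparisons Bonferroni divisor for the family (e.g. 3 for the
#'   three evoked components).
#' @return list: `R`, `p`, `p_bonferroni`, `n`, `method`, `flagged`.
#' @export
spearman_test <- function(x, y, n_comparisons = 1) {
  n <- length(x)
  .assert(length(y) == n, "lengths differ")
  .assert(n >= 4, "need n >= 4")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(R = NA_real_, p = NA_real_, p_bonferroni = NA_real_, n = n,
                method = "undefined", flagged = TRUE))
  }
  rx <- rank(x); ry <- rank(y)
  R <- cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 9 && !ties) {
    perms <- .all_perms(n)
    ## rho is linear in sum(rx * ry[perm]); enumerate that inner product
    s_obs <- sum(rx * ry)
    sums <- as.vector(perms %*% rx)  # sum over i of rx[i]*ry[perm... ] via symmetry
    ## cor(rx, ry[p]) monotone in sum(rx * ry[p]); map to |rho|
    mu <- n * (n + 1)^2 / 4
    denom <- sum(rx^2) - n * mean(rx)^2
    rho_perm <- (sums - mu) / denom
    rho_obs <- (s_obs - mu) / denom
    p <- mean(abs(rho_perm) >= abs(rho_obs) - 1e-12)
    method <- "exact"
  } else {
    tt <- R * sqrt((n - 2) / max(1 - R^2, 1e-15))
    p <- 2 * pt(-abs(tt), n - 2)
    method <- "t-approximation"
  }
  list(R = R, p = p, p_bonferroni = min(1, p * n_comparisons), n = n,
       method = method, flagged = FALSE)
}

#' Wilcoxon signed-rank test with Bonferroni correction
#'
#' Two-tailed paired signed-rank test (zero differences dropped): exact null
#' distribution for n <= 25 without ties, normal approximation with
#' continuity correction otherwise. If all differences are zero the test is
#' degenerate and p = 1 is returned with a flag.
#'
#' @param a,b paired numeric vectors.
#' @param n_comparisons Bonferroni divisor.
#' @return list: `statistic` (V), `p`, `p_bonferroni`, `n` (nonzero pairs),
#'   `exact`, `flagged`.
#' @export
wilcoxon_signed_rank <- function(a, b, n_comparisons = 1) {
  .assert(length(a) == length(b), "paired vectors differ in length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = NA_real_, p = 1, p_bonferroni = 1, n = 0,
                exact = FALSE, flagged = TRUE))
  }
  .assert(n >= 5, "need at least 5 nonzero differences")
  exact <- n <= 25 && !anyDuplicated(abs(d))
  wt <- suppressWarnings(
    wilcox.test(a, b, paired = TRUE, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       p_bonferroni = min(1, wt$p.value * n_comparisons), n = n,
       exact = exact, flagged = FALSE)
}
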