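test_that("vertex-wise regression matches lm and flips sign with the covariate", {
  set.seed(10)
  n <- 12; V <- 20
  maps <- matrix(rnorm(n * V), n, V)
  x <- rnorm(n)
  vs <- vertexwise_regression(maps, x)
  ## oracle: per-vertex lm t statistic
  t_lm <- vapply(seq_len(V), function(v) {
    summary(lm(maps[, v] ~ x))$coefficients[2, 3]
  }, 0)
  expect_equal(vs$t, t_lm, tolerance = 1e-8)
  vs2 <- vertexwise_regression(maps, -x)
  expect_equal(vs2$t, -vs$t, tolerance = 1e-10)
  ## zero-variance vertex flagged with t = 0
  maps[, 3] <- 5
  vs3 <- vertexwise_regression(maps, x)
  expect_true(vs3$flagged[3])
  expect_equal(vs3$t[3], 0)
  ## collinear vertex flagged and capped, not infinite
  maps[, 4] <- 2 * x + 1
  vs4 <- vertexwise_regression(maps, x)
  expect_true(vs4$flagged[4])
  expect_true(is.finite(vs4$t[4]))
  expect_error(vertexwise_regression(maps, rep(1, n)), "variance")
})

test_that("null t statistics follow Student-t(n-2) moments", {
  set.seed(11)
  n <- 15
  maps <- matrix(rnorm(n * 800), n, 800)
  t0 <- vertexwise_regression(maps, rnorm(n))$t
  df <- n - 2
  expect_lt(abs(mean(t0)), 0.1)
  expect_equal(var(t0), df / (df - 2), tolerance = 0.2)
  ## empirical quantiles against the reference distribution
  expect_equal(unname(quantile(t0, 0.9)), qt(0.9, df), tolerance = 0.15)
})

test_that("TFCE reproduces the analytic single-vertex value and discretization bounds", {
  src <- small_mesh(3)
  x <- numeric(src$n_vertices)
  x[5] <- 1
  enh <- tfce_enhance(x, src$edges, E = 0.5, H = 2, n_steps = 100,
                      two_tailed = FALSE)
  ## isolated unit vertex: integral of h^2 dh = 1/3 (Riemann sum within 2%)
  expect_lt(abs(enh[5] - 1 / 3) / (1 / 3), 0.02)
  expect_true(all(enh[-5] == 0))
  ## uniform map: identical score everywhere
  eu <- tfce_enhance(rep(2.5, src$n_vertices), src$edges, two_tailed = FALSE)
  expect_equal(diff(range(eu)), 0)
  ## fine-ladder refinement agrees within 2%
  set.seed(2)
  m <- rnorm(src$n_vertices)
  e1 <- tfce_enhance(m, src$edges, n_steps = 100)
  e2 <- tfce_enhance(m, src$edges, n_steps = 1000)
  expect_lt(max(abs(e1 - e2)) / max(abs(e2)), 0.02)
  expect_error(tfce_enhance(m, src$edges, n_steps = 0), "n_steps")
})

test_that("TFCE is monotone: pointwise-larger maps never get smaller scores", {
  src <- small_mesh(2)
  set.seed(14)
  for (i in 1:10) {
    m <- pmax(rnorm(src$n_vertices), 0)
    m2 <- m + runif(src$n_vertices, 0, 0.5)
    hm <- max(m2)
    e1 <- tfce_enhance(m, src$edges, two_tailed = FALSE, h_max = hm)
    e2 <- tfce_enhance(m2, src$edges, two_tailed = FALSE, h_max = hm)
    expect_true(all(e2 >= e1 - 1e-9))
  }
})

test_that("permutation FWE is reproducible, valid under the null, and exact for tiny cohorts", {
  src <- small_mesh(2)
  co <- simulate_fc_cohort(src, 20, 40, coupling_slope = 0, rng_seed = 5)
  r1 <- permutation_fwe(co$maps, co$covariate, src$edges,
                        n_permutations = 200, rng_seed = 9)
  r2 <- permutation_fwe(co$maps, co$covariate, src$edges,
                        n_permutations = 200, rng_seed = 9)
  expect_identical(r1$p, r2$p)
  expect_true(all(r1$p > 0 & r1$p <= 1))
  ## add-one estimator never returns exactly zero
  expect_gte(min(r1$p), 1 / 201)
  ## n = 5 subjects: 120 distinct permutations < requested, exact enumeration
  co5 <- simulate_fc_cohort(src, 5, 40, coupling_slope = 0, rng_seed = 6)
  r5 <- permutation_fwe(co5$maps, co5$covariate, src$edges,
                        n_permutations = 500, rng_seed = 1)
  expect_true(r5$exact)
  expect_equal(r5$n_permutations, 120L)
})

test_that("cluster tables respect the significance threshold and the extent floor", {
  src <- small_mesh(3)
  p <- rep(0.9, src$n_vertices)
  expect_equal(nrow(cluster_filter(p, src$edges)), 0L)
  ## one 60-vertex significant patch survives k > 50 with k_e = 60
  patch <- mesh_neighborhood(src, 100, 60)
  p[patch] <- 0.01
  p[patch[1]] <- 0.001
  tab <- cluster_filter(p, src$edges, alpha = 0.05, k_min = 50)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$k_e, 60L)
  expect_equal(tab$peak_vertex, 100L)
  expect_equal(tab$peak_p, 0.001)
  ## a 40-vertex patch is dropped by the extent floor
  p2 <- rep(0.9, src$n_vertices)
  p2[mesh_neighborhood(src, 300, 40)] <- 0.01
  expect_equal(nrow(cluster_filter(p2, src$edges, k_min = 50)), 0L)
  expect_equal(cluster_filter(p2, src$edges, k_min = 30)$k_e, 40L)
})

test_that("Spearman matches exhaustive rank-permutation enumeration for small n", {
  ## independent oracle via the sum-of-squared-rank-differences statistic
  exact_oracle <- function(x, y) {
    n <- length(x)
    rx <- rank(x); ry <- rank(y)
    rho_of <- function(z) 1 - 6 * sum((rx - z)^2) / (n * (n^2 - 1))
    perms <- somameg:::.all_perms(n)
    rho_all <- apply(perms, 1, function(ix) rho_of(ry[ix]))
    rho_obs <- rho_of(ry)
    mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
  }
  set.seed(17)
  for (n in c(5, 6, 7)) {
    x <- rnorm(n); y <- rnorm(n)
    st <- spearman_test(x, y)
    expect_equal(st$method, "exact")
    expect_equal(st$p, exact_oracle(x, y), tolerance = 1e-12)
  }
  ## trivial values
  expect_equal(spearman_test(c(1, 2, 3, 4), c(4, 3, 2, 1))$R, -1)
  expect_equal(spearman_test(1:5, exp(1:5))$R, 1)
  ## Bonferroni
  st3 <- spearman_test(rnorm(10), rnorm(10), n_comparisons = 3)
  expect_equal(st3$p_bonferroni, min(1, st3$p * 3))
  ## constant input flagged
  expect_true(spearman_test(rep(1, 6), rnorm(6))$flagged)
})

test_that("Wilcoxon signed-rank matches exhaustive sign enumeration", {
  ## oracle: enumerate all 2^n sign assignments of the rank statistic
  exact_oracle <- function(a, b) {
    d <- a - b
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.vector(signs %*% r)
    lower <- mean(v_all <= v_obs)
    upper <- mean(v_all >= v_obs)
    if (v_obs > n * (n + 1) / 4) min(1, 2 * upper) else min(1, 2 * lower)
  }
  set.seed(19)
  a <- rnorm(10); b <- rnorm(10)
  wt <- wilcoxon_signed_rank(a, b)
  expect_true(wt$exact)
  expect_equal(wt$p, exact_oracle(a, b), tolerance = 1e-12)
  ## all-positive differences, n = 6: p = 2/2^6
  a6 <- 1:6; b6 <- a6 - seq(0.5, 3, by = 0.5)
  w6 <- wilcoxon_signed_rank(a6, b6)
  expect_equal(w6$p, 2 / 2^6, tolerance = 1e-12)
  ## identical samples: degenerate path
  wd <- wilcoxon_signed_rank(1:8, 1:8)
  expect_true(wd$flagged)
  expect_equal(wd$p, 1)
})
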