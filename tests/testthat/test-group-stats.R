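test_that("Tucker congruence matches hand-computed values and properties", {
  expect_equal(tucker_congruence(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(tucker_congruence(c(1, 0), c(0, 1)), 0)
  expect_equal(tucker_congruence(c(1, 2, 3), c(3, 2, 1)), 10 / 14)
  # symmetry and scale invariance on random non-negative vectors
  set.seed(2)
  for (i in 1:10) {
    x <- runif(25); y <- runif(25)
    expect_equal(tucker_congruence(x, y), tucker_congruence(y, x))
    expect_equal(tucker_congruence(3.7 * x, 0.2 * y), tucker_congruence(x, y))
    expect_gte(tucker_congruence(x, y), 0)
    expect_lte(tucker_congruence(x, y), 1 + 1e-12)
  }
  expect_error(tucker_congruence(rep(0, 3), c(1, 2, 3)), "zero")
  expect_error(tucker_congruence(1:3, 1:4), "equal length")
})

test_that("cluster finding agrees with an independent graph-components oracle", {
  grid <- small_leadfield()$grid
  set.seed(8)
  for (rep in 1:20) {
    members <- which(runif(nrow(grid$coords)) < runif(1, 0.05, 0.4))
    ours <- arcomp:::find_clusters(members, grid$adjacency)
    oracle <- igraph_clusters(members, grid$adjacency)
    key <- function(cl) paste(sapply(cl, paste, collapse = ","))
    expect_setequal(key(ours), key(oracle))
  }
})

test_that("identical loadings give a zero t map and no clusters", {
  grid <- small_leadfield()$grid
  set.seed(1)
  A <- matrix(runif(5 * nrow(grid$coords)), 5)
  res <- cluster_permutation_test(A, A, grid, n_perm = 50, seed = 3)
  for (co in res$contrasts) {
    expect_true(all(co$t_map == 0))
    expect_length(co$clusters, 0)
  }
})

test_that("a planted loading difference is detected in the right place", {
  grid <- full_leadfield()$grid
  n_src <- nrow(grid$coords)
  seedpt <- which(grid$region_labels == "occipito-parietal")[10]
  patch <- sort(unique(c(seedpt, unlist(grid$adjacency[c(
    seedpt, grid$adjacency[[seedpt]])])) ))
  set.seed(42)
  base <- matrix(abs(rnorm(20 * n_src, sd = 0.3)), 20)
  eff <- matrix(0, 20, n_src); eff[, patch] <- 0.6
  res <- cluster_permutation_test(base + eff, base, grid,
                                  n_perm = 1000, seed = 9)
  co <- res$contrasts[[1]]
  expect_gt(length(co$clusters), 0)
  top <- co$clusters[[1]]
  jaccard <- length(intersect(top, patch)) / length(union(top, patch))
  expect_gt(jaccard, 0.5)
  expect_lt(co$p_values[1], 0.05)
})

test_that("permutation p-values are seeded-deterministic and subject-order invariant", {
  grid <- small_leadfield()$grid
  set.seed(5)
  A <- matrix(runif(8 * nrow(grid$coords)), 8)
  B <- matrix(runif(8 * nrow(grid$coords)), 8)
  r1 <- cluster_permutation_test(A, B, grid, n_perm = 200, seed = 11)
  r2 <- cluster_permutation_test(A, B, grid, n_perm = 200, seed = 11)
  expect_identical(r1$contrasts[[1]]$p_values, r2$contrasts[[1]]$p_values)
  perm <- sample(8)
  r3 <- cluster_permutation_test(A[perm, ], B[perm, ], grid,
                                 n_perm = 200, seed = 11)
  expect_identical(r1$contrasts[[1]]$clusters, r3$contrasts[[1]]$clusters)
  expect_identical(r1$contrasts[[1]]$p_values, r3$contrasts[[1]]$p_values)
  expect_error(cluster_permutation_test(A[1:2, ], B[1:2, ], grid), "3 subjects")
})

test_that("repeated-measures F matches aov and handles the constant case", {
  X <- matrix(c(0.35, 0.38, 0.36, 0.37,
                0.40, 0.41, 0.39, 0.42,
                0.30, 0.33, 0.31, 0.32), 3, 4, byrow = TRUE)
  res <- rec_period_stability(X)
  df_long <- data.frame(y = as.vector(X),
                        subject = factor(rep(1:3, 4)),
                        period = factor(rep(1:4, each = 3)))
  fit <- stats::aov(y ~ period + Error(subject / period), data = df_long)
  F_aov <- summary(fit)[["Error: subject:period"]][[1]]["period", "F value"]
  expect_equal(res$F, F_aov, tolerance = 1e-10)
  expect_equal(res$df, c(3, 6))
  # constant temporal loading: all period means equal, F = 0
  res0 <- rec_period_stability(matrix(0.4, 3, 4))
  expect_equal(res0$F, 0)
  expect_equal(res0$p_value, 1)
})

test_that("per-period means use max-normalized loadings and validate periods", {
  loading <- c(rep(2, 5), rep(4, 5))
  seg <- rep(1:2, each = 5)
  m <- rec_period_means(loading, seg)
  expect_equal(unname(m), c(0.5, 1))
  expect_named(m, c("REC1", "REC2"))
  expect_error(rec_period_means(loading, rep(1L, 10)), "2 periods")
})

test_that("replicability across two seeded sessions is high", {
  lf <- small_leadfield()
  dec1 <- small_case()$dec
  sim2 <- simulate_recording(small_two_arc_scenario(seed = 31), lf)
  dec2 <- decompose_subject(sim2$recording, small_config(seed = 77),
                            leadfield = lf)
  rep <- replicability_report(dec1, dec2)
  spatial <- rep[rep$mode == "source", ]
  expect_true(all(spatial$tcc > 0.85))
  expect_true(all(rep$tcc[rep$mode == "frequency"] > 0.85))
})
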