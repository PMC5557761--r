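test_that("noiseless low-rank tensors are recovered essentially exactly", {
  st <- simulate_tensor(2, c(12, 15, 18), noise_sd = 0, seed = 3)
  m <- parafac_als(st$tensor, 2, seed = 7)
  expect_gte(m$fit, 1 - 1e-6)
  gt <- st$ground_truth
  mm <- match_components(gt$A, m$A)
  for (i in 1:2) {
    expect_gt(tucker_congruence(gt$A[, i], m$A[, mm[i]]), 0.999)
    expect_gt(tucker_congruence(gt$B[, i], m$B[, mm[i]]), 0.999)
    expect_gt(tucker_congruence(gt$C[, i], m$C[, mm[i]]), 0.999)
  }
})

test_that("rank-1 all-ones tensor gives constant loading columns", {
  X <- array(1, c(4, 5, 6))
  m <- parafac_als(X, 1, seed = 2, n_starts = 2)
  expect_gte(m$fit, 1 - 1e-9)
  for (M in list(m$A, m$B, m$C)) {
    expect_lt(diff(range(M)) / max(M), 1e-6)
  }
  # unit-maximum convention on non-first modes
  expect_equal(max(m$B), 1)
  expect_equal(max(m$C), 1)
})

test_that("explained variation is non-decreasing over ALS sweeps", {
  st <- simulate_tensor(3, c(10, 12, 14), noise_sd = 0.05, seed = 9)
  m <- parafac_als(st$tensor, 3, n_starts = 2, seed = 5)
  expect_true(all(diff(m$fit_trace) > -1e-10))
  expect_true(all(m$A >= 0) && all(m$B >= 0) && all(m$C >= 0))
})

test_that("reconstruction is invariant to the normalization convention", {
  st <- simulate_tensor(2, c(8, 9, 10), noise_sd = 0.02, seed = 12)
  m <- parafac_als(st$tensor, 2, n_starts = 3, seed = 8)
  X <- arcomp:::parafac_data_array(st$tensor)
  rec1 <- arcomp:::parafac_reconstruct(m)
  # undo the unit-max convention by pushing arbitrary positive scales around
  m2 <- m
  s_b <- c(2, 0.5); s_c <- c(3, 0.1)
  m2$B <- sweep(m$B, 2, s_b, "*")
  m2$C <- sweep(m$C, 2, s_c, "*")
  m2$A <- sweep(m$A, 2, s_b * s_c, "/")
  rec2 <- arcomp:::parafac_reconstruct(m2)
  expect_lt(max(abs(rec1 - rec2)) / max(abs(rec1)), 1e-12)
  expect_equal(sqrt(sum((X - rec1)^2)), m$residual_norm, tolerance = 1e-6)
})

test_that("solutions agree across seeds after congruence matching", {
  st <- simulate_tensor(2, c(10, 11, 12), noise_sd = 0, seed = 21)
  models <- lapply(1:5, function(s) parafac_als(st$tensor, 2, n_starts = 3,
                                                seed = s))
  ref <- models[[1]]
  for (m in models[-1]) {
    mm <- match_components(ref$A, m$A)
    for (i in 1:2) {
      expect_gt(tucker_congruence(ref$A[, i], m$A[, mm[i]]), 0.99)
      expect_gt(tucker_congruence(ref$B[, i], m$B[, mm[i]]), 0.99)
    }
  }
})

test_that("fixed modes are returned bit-identical and only free modes vary", {
  st <- simulate_tensor(2, c(10, 14, 12), noise_sd = 0.05, seed = 33)
  free_fit <- parafac_als(st$tensor, 2, n_starts = 4, seed = 1)
  fixed <- list(frequency = free_fit$A, time = free_fit$C)
  runs <- lapply(1:3, function(s) parafac_als(st$tensor, 2, fixed = fixed,
                                              n_starts = 1, seed = 100 + s))
  for (r in runs) {
    expect_identical(r$A, free_fit$A)
    expect_identical(r$C, free_fit$C)
    expect_equal(r$fixed_modes, c("frequency", "time"))
  }
  # the single free mode solves a convex problem: same B across seeds
  expect_equal(runs[[1]]$B, runs[[2]]$B, tolerance = 1e-6)
  expect_error(parafac_als(st$tensor, 2,
                           fixed = list(frequency = free_fit$A[, 1, drop = FALSE])),
               "non-negative")
})

test_that("core consistency is 100 for correct models and collapses when over-factored", {
  st <- simulate_tensor(2, c(10, 12, 14), noise_sd = 0, seed = 41)
  m2 <- parafac_als(st$tensor, 2, seed = 6)
  expect_equal(corcondia(st$tensor, m2), 100, tolerance = 0.1)
  expect_equal(corcondia(st$tensor, parafac_als(st$tensor, 1, seed = 6)), 100)
  stn <- simulate_tensor(2, c(10, 12, 14), noise_sd = 0.01, seed = 42)
  m3 <- parafac_als(stn$tensor, 3, seed = 6)
  expect_lt(corcondia(stn$tensor, m3), 90)
})

test_that("core consistency equals the dense normal-equations oracle", {
  for (s in 1:4) {
    stn <- simulate_tensor(2, c(6, 7, 8), noise_sd = 0.05, seed = s)
    for (K in 2:3) {
      m <- parafac_als(stn$tensor, K, n_starts = 3, seed = s + 50)
      expect_equal(corcondia(stn$tensor, m), dense_corcondia(stn$tensor, m),
                   tolerance = 1e-8)
    }
  }
})

test_that("model order selection finds the construction rank", {
  st2 <- simulate_tensor(2, c(12, 14, 16), noise_sd = 0, seed = 55)
  sel <- select_num_components(st2$tensor, K_max = 4, seed = 9)
  expect_equal(sel$K, 2L)
  expect_lt(sel$diagnostics$corcondia[3], 90)
  st1 <- simulate_tensor(1, c(8, 8, 8), noise_sd = 0, seed = 56)
  expect_equal(select_num_components(st1$tensor, K_max = 3, seed = 9)$K, 1L)
})

test_that("simulate_tensor honors its contract", {
  expect_error(simulate_tensor(2, c(10, 10, 10), noise_sd = -1), "non-negative")
  expect_error(simulate_tensor(5, c(3, 10, 10)))
  # K=1 all-ones loadings -> all-ones tensor
  st <- simulate_tensor(1, c(2, 2, 2), noise_sd = 0, seed = 1)
  gt <- st$ground_truth
  ones <- st$tensor$values / (gt$B[, 1] %o% gt$A[, 1] %o% gt$C[, 1])
  expect_equal(as.numeric(ones), rep(1, 8), tolerance = 1e-12)
  # noisy construction: residual of the true model matches injected noise
  stn <- simulate_tensor(3, c(15, 15, 15), noise_sd = 0.01, seed = 77)
  m <- parafac_als(stn$tensor, 3, n_starts = 5, seed = 3)
  noise_ss <- sum(stn$ground_truth$noise^2)
  resid_ss <- m$residual_norm^2
  expect_lt(abs(resid_ss - noise_ss) / noise_ss, 0.15)
  # determinism
  sta <- simulate_tensor(2, c(6, 6, 6), noise_sd = 0.1, seed = 5)
  stb <- simulate_tensor(2, c(6, 6, 6), noise_sd = 0.1, seed = 5)
  expect_identical(sta$tensor$values, stb$tensor$values)
})
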