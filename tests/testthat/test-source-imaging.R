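test_that("387-point grid is quasi-uniform with symmetric adjacency", {
  grid <- full_leadfield()$grid
  expect_equal(nrow(grid$coords), 387)
  expect_lt(sd(grid$nn_distance) / mean(grid$nn_distance), 0.2)
  for (i in c(1, 50, 200, 387)) {
    expect_false(i %in% grid$adjacency[[i]])
    for (j in grid$adjacency[[i]]) expect_true(i %in% grid$adjacency[[j]])
  }
  expect_true(all(lengths(grid$adjacency) >= 1))
})

test_that("three-shell potential matches the homogeneous-sphere closed form", {
  # with equal conductivities the shell solution must reduce to the single
  # homogeneous sphere, whose scalp potential has a closed form
  sig <- 0.33
  hm <- head_model(conductivities = rep(sig, 3))
  b <- 0.075; R <- hm$radii[3]; f <- b / R
  cg <- seq(-0.99, 0.99, length.out = 41)
  v <- dipole_potential(cg, b, hm, n_terms = 250)
  s <- sqrt(1 - 2 * f * cg + f^2)
  closed <- (1 / (4 * pi * sig * R^2)) *
    (2 * (cg - f) / s^3 + (1 / f) * (1 / s - 1))
  expect_lt(max(abs(v - closed)) / max(abs(closed)), 1e-6)
  # truncation convergence of the heterogeneous series
  v1 <- dipole_potential(cg, b, head_model(), 150)
  v2 <- dipole_potential(cg, b, head_model(), 400)
  expect_lt(max(abs(v1 - v2)) / max(abs(v2)), 1e-10)
})

test_that("lead field geometry and referencing are sound", {
  lf <- small_leadfield()
  # common-average: every source column sums to zero over channels
  expect_lt(max(abs(colSums(lf$gain))), 1e-10 * max(abs(lf$gain)))
  # a dipole directly beneath an electrode drives that electrode hardest
  eu <- lf$positions / sqrt(rowSums(lf$positions^2))
  su <- lf$grid$coords / lf$grid$radius
  align <- eu %*% t(su)                  # channels x sources alignment
  checked <- 0
  for (ch in seq_len(nrow(eu))) {
    j <- which.max(align[ch, ])
    # only assess sources sitting essentially beneath this channel and
    # clearly closer to it than to any other channel
    if (align[ch, j] > cos(6 * pi / 180) &&
        which.max(align[, j]) == ch &&
        sort(align[, j], decreasing = TRUE)[2] < cos(9 * pi / 180)) {
      expect_equal(unname(which.max(lf$gain[, j])), ch)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 3)
  expect_error(build_leadfield(lf$positions * 1.5), "10%")
})

test_that("LORETA localizes single grid sources within one neighbor step", {
  lf <- full_leadfield()
  inv <- loreta_inverse(lf)
  est <- abs(inv$T %*% lf$gain)
  hits <- vapply(seq_len(ncol(est)), function(j) {
    i <- which.max(est[, j])
    i == j || i %in% lf$grid$adjacency[[j]]
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("inverse operator is linear, reference-invariant, and shrinks with alpha", {
  lf <- small_leadfield()
  inv <- loreta_inverse(lf)
  expect_equal(dim(inv$T), c(ncol(lf$gain), nrow(lf$gain)))
  expect_equal(as.numeric(inv$T %*% rep(0, nrow(lf$gain))),
               rep(0, ncol(lf$gain)))
  # adding a channel-constant offset changes nothing
  x <- lf$gain[, 17]
  expect_equal(inv$T %*% x, inv$T %*% (x + 5), tolerance = 1e-8)
  nrms <- vapply(inv$alpha * c(1, 2, 5, 20), function(a) {
    norm(loreta_inverse(lf, alpha = a)$T, "F")
  }, 0)
  expect_true(all(diff(nrms) < 1e-12))
  # weighted minimum norm variant runs and differs
  expect_gt(norm(loreta_inverse(lf, method = "mnorm")$T - inv$T, "F"), 0)
})

test_that("source amplitude spectra equal the brute-force congruence diagonal", {
  rec <- white_recording(10, 15, fs = 250, seed = 17)
  csd <- cross_spectral_density(stft(rec))
  set.seed(4)
  Tm <- matrix(rnorm(25 * 10), 25, 10)
  inv <- structure(list(T = Tm, alpha = 0, method = "loreta",
                        grid = NULL, channel_names = NULL),
                   class = "inverse_operator")
  asd <- source_amplitude_spectrum(inv, csd)
  expect_true(all(asd$values >= 0))
  for (idx in list(c(2, 1), c(30, 4))) {
    S <- csd_matrix(csd, idx[1], idx[2])
    brute <- Tm %*% S %*% Conj(t(Tm))
    expect_lt(max(abs(Im(diag(brute)))), 1e-10 * max(abs(diag(brute))))
    expect_equal(asd$values[, idx[1], idx[2]], sqrt(Re(diag(brute))),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("simulated two-patch recording peaks inside the correct source region", {
  cs <- small_case()
  sim <- cs$sim
  csd <- cross_spectral_density(stft(sim$recording))
  inv <- loreta_inverse(small_leadfield())
  asd <- source_amplitude_spectrum(inv, csd)
  f104 <- which.min(abs(asd$freqs - 10.4))
  prof <- rowMeans(asd$values[, f104, ])
  top <- order(prof, decreasing = TRUE)[1:10]
  in_patch <- sim$ground_truth$true_source_profiles[, 1] > 0
  expect_gt(mean(in_patch[top]), 0.5)
})
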