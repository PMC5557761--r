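test_that("5-s windows at 500 Hz give 0.2 Hz resolution and 51 alpha-band bins", {
  rec <- eeg_recording(matrix(rnorm(2 * 5000), 2), 500,
                       channel_positions = sensor_layout(2)$positions)
  sp <- stft(rec)
  expect_equal(sp$df, 0.2)
  expect_length(sp$freqs, 51)
  expect_equal(range(sp$freqs), c(5, 15))
  expect_equal(diff(sp$freqs), rep(0.2, 50))
})

test_that("periodic Hann taper has mean squared value exactly 3/8", {
  for (L in c(4, 10, 128, 2500)) {
    expect_equal(mean(arcomp:::hann_taper(L)^2), 0.375)
  }
  sp <- stft(white_recording(2, 10))
  expect_equal(mean(sp$taper_values^2), 0.375)
})

test_that("all-zero recording yields all-zero STFT", {
  rec <- eeg_recording(matrix(0, 3, 2500), 250,
                       channel_positions = sensor_layout(3)$positions)
  expect_true(all(stft(rec)$values == 0))
})

test_that("STFT matches the naive per-window DFT oracle", {
  # pure 10 Hz sinusoid, one prominent channel
  fs <- 250; n <- fs * 12
  dat <- rbind(sin(2 * pi * 10 * (0:(n - 1)) / fs), rnorm(n, sd = 0.1))
  rec <- eeg_recording(dat, fs, channel_positions = sensor_layout(2)$positions)
  sp <- stft(rec)
  or <- naive_stft(rec, 5, 0.5, c(5, 15))
  expect_lt(max(abs(sp$values - or$values)) / max(abs(or$values)), 1e-10)
  # and on a random multichannel recording with a segment seam
  rec2 <- white_recording(4, 30, fs = 250, seed = 3,
                          segment_starts = c(1L, 3751L))
  sp2 <- stft(rec2)
  or2 <- naive_stft(rec2, 5, 0.5, c(5, 15))
  expect_lt(max(abs(sp2$values - or2$values)) / max(abs(or2$values)), 1e-10)
})

test_that("windows never straddle segment boundaries and pooling segments is equivalent", {
  fs <- 250
  rec <- white_recording(3, 24, fs = fs, seed = 11,
                         segment_starts = c(1L, as.integer(11.4 * fs) + 1L))
  sp <- stft(rec)
  spans <- arcomp:::segment_spans(rec)
  L <- sp$window_length_samples
  starts <- sp$window_centers - L %/% 2L
  for (w in seq_along(starts)) {
    s <- sp$window_segment[w]
    expect_gte(starts[w], spans[s, 1])
    expect_lte(starts[w] + L - 1L, spans[s, 2])
  }
  # analyzing the two segments as separate recordings and pooling windows
  pos <- rec$channel_positions
  r1 <- eeg_recording(rec$data[, spans[1, 1]:spans[1, 2]], fs, pos)
  r2 <- eeg_recording(rec$data[, spans[2, 1]:spans[2, 2]], fs, pos)
  pooled <- array(c(stft(r1)$values, stft(r2)$values),
                  dim = dim(sp$values))
  expect_equal(sp$values, pooled, ignore_attr = TRUE)
})

test_that("narrow band or short segments are rejected appropriately", {
  rec <- white_recording(2, 12, fs = 250)
  expect_error(stft(rec, band = c(0, 15)), "band")
  expect_error(stft(rec, band = c(5, 200)), "band")
  expect_error(stft(rec, window_seconds = 1 / 3), "integer")
  short <- eeg_recording(matrix(rnorm(2 * 500), 2), 250,
                         channel_positions = sensor_layout(2)$positions)
  expect_error(suppressWarnings(stft(short)), "no segment")
})

test_that("amplitude threshold drops contaminated windows", {
  rec <- white_recording(2, 30, fs = 250, seed = 2)
  rec$data[1, 2000] <- 500
  sp_all <- stft(rec)
  sp_cut <- stft(rec, amplitude_threshold = 100)
  expect_lt(dim(sp_cut$values)[3], dim(sp_all$values)[3])
  expect_false(any(abs(sp_cut$window_centers - 2000) <=
                     sp_cut$window_length_samples / 2))
})

test_that("CSD normalization uses the taper and slices are Hermitian PSD", {
  sp <- stft(white_recording(3, 20, fs = 250, seed = 5))
  csd <- cross_spectral_density(sp)
  expect_equal(csd$taper_mean_square, 0.375)
  expect_equal(csd$normalization, 2 / (0.375 * 0.2))
  for (idx in list(c(1, 1), c(25, 3), c(51, 5))) {
    S <- csd_matrix(csd, idx[1], idx[2])
    expect_lt(max(abs(S - Conj(t(S)))), 1e-12 * max(abs(S)))
    expect_true(all(Re(diag(S)) >= 0))
    expect_lt(max(abs(Im(diag(S)))), 1e-14 * max(abs(S)))
  }
  # single channel: 1x1 CSD equals normalized |phi|^2
  r1 <- white_recording(2, 10, fs = 250, seed = 9)
  c1 <- cross_spectral_density(stft(r1))
  expect_equal(as.numeric(Re(csd_matrix(c1, 3, 1)[1, 1])),
               unname(c1$normalization * abs(c1$phi[1, 3, 1])^2))
})

test_that("white-noise CSD level approaches the analytic flat spectrum", {
  sigma <- 2
  rec <- white_recording(2, 120, fs = 250, sd = sigma, seed = 13)
  asd <- amplitude_spectrum(cross_spectral_density(stft(rec)))
  level <- mean(asd$values^2)          # average one-sided PSD in the band
  expect_equal(level, 2 * sigma^2 / 250, tolerance = 0.05)
})

test_that("amplitude spectrum is the square root of the CSD diagonal", {
  sp <- stft(white_recording(3, 20, fs = 250, seed = 21))
  csd <- cross_spectral_density(sp)
  asd <- amplitude_spectrum(csd)
  expect_true(all(asd$values >= 0))
  S <- csd_matrix(csd, 17, 2)
  expect_equal(asd$values[, 17, 2], sqrt(Re(diag(S))), ignore_attr = TRUE)
  # 10 Hz sinusoid peaks at the 10 Hz bin in every window
  fs <- 250; n <- fs * 15
  dat <- rbind(sin(2 * pi * 10 * (0:(n - 1)) / fs), rnorm(n, sd = 0.01))
  rec <- eeg_recording(dat, fs, channel_positions = sensor_layout(2)$positions)
  a2 <- amplitude_spectrum(cross_spectral_density(stft(rec)))
  peaks <- apply(a2$values[1, , ], 2, which.max)
  expect_true(all(a2$freqs[peaks] == 10))
})

test_that("band-limited Parseval identity holds on tapered windows", {
  fs <- 250
  rec <- white_recording(2, 20, fs = fs, seed = 31)
  sp <- stft(rec, band = c(0.2, fs / 2 - 0.2))
  asd <- amplitude_spectrum(cross_spectral_density(sp))
  w <- sp$taper_values; L <- sp$window_length_samples
  msq <- mean(w^2)
  for (t in c(1, 3)) {
    st <- sp$window_centers[t] - L %/% 2L
    for (m in 1:2) {
      xw <- rec$data[m, st:(st + L - 1)] * w
      dc <- mean(xw)^2
      nyq <- abs(mean(xw * (-1)^(0:(L - 1))))^2
      lhs <- sum(asd$values[m, , t]^2) * sp$df
      rhs <- (mean(xw^2) - dc - nyq) / msq
      expect_equal(lhs, rhs, tolerance = 1e-8)
    }
  }
})

test_that("recording container validates its invariants", {
  pos <- sensor_layout(3)$positions
  expect_error(eeg_recording(matrix(c(1, NA, 1, 1, 1, 1), 3), 100, pos), "finite")
  expect_error(eeg_recording(matrix(1, 1, 10), 100, pos[1, , drop = FALSE]),
               "2 channels")
  expect_error(eeg_recording(matrix(1, 3, 10), 100, pos,
                             segment_starts = c(2L, 5L)), "segment_starts")
  expect_error(eeg_recording(matrix(1, 3, 10), 100, pos,
                             segment_starts = c(1L, 20L)), "segment_starts")
})
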