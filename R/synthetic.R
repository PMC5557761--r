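# --- spectral-domain noise shaping ------------------------------------------

# Zero-phase filtering of white Gaussian noise by multiplying its DFT with a
# real non-negative amplitude response |H(f)| (symmetric over +/- freqs).
shaped_noise <- function(n, fs, amplitude_response) {
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  h <- amplitude_response(f)
  x <- stats::rnorm(n)
  Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / n
}

# Gaussian band-pass amplitude response centered at f0 with the given FWHM.
gaussian_band <- function(f0, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  function(f) exp(-(f - f0)^2 / (2 * sigma^2))
}

# Unit-variance narrowband oscillation: white noise band-pass filtered
# around f0 (zero-phase), giving a spectral peak of finite width (FWHM).
narrowband_oscillation <- function(n, fs, f0, fwhm) {
  x <- shaped_noise(n, fs, gaussian_band(f0, fwhm))
  x / stats::sd(x)
}

# Non-negative amplitude envelope: low-pass filtered Gaussian noise,
# rectified, then scaled to the requested mean (microvolts at source).
# `timescale` (seconds) sets the fluctuation time constant.
amplitude_envelope <- function(n, fs, mean_amplitude, timescale) {
  fc <- 1 / timescale
  e <- abs(shaped_noise(n, fs, function(f) exp(-(f / fc)^2)))
  e * (mean_amplitude / mean(e))
}

# --- scenario types ---------------------------------------------------------

#' Specification of one oscillatory cortical source patch
#'
#' @param center 3-D coordinate of the patch center (meters); must lie on
#'   the source shell of the lead field used for simulation.
#' @param radius patch extent (meters, chord distance on the shell); > 0.
#' @param peak_frequency spectral peak of the oscillation (Hz).
#' @param bandwidth FWHM of the component's spectral profile (Hz).
#' @param mean_amplitude mean envelope amplitude (scalp-equivalent
#'   microvolts at source); > 0.
#' @param timescale envelope fluctuation timescale (seconds).
#' @param label text tag, e.g. "ARC1-like".
#' @return object of class `source_patch`.
#' @export
source_patch <- function(center, radius, peak_frequency, bandwidth,
                         mean_amplitude, timescale, label = "") {
  stopifnot(length(center) == 3)
  stopifnot_scalar(radius, "radius", lower = 1e-9)
  stopifnot_scalar(peak_frequency, "peak_frequency", lower = 1e-9)
  stopifnot_scalar(bandwidth, "bandwidth", lower = 1e-9)
  stopifnot_scalar(mean_amplitude, "mean_amplitude", lower = 1e-12)
  stopifnot_scalar(timescale, "timescale", lower = 1e-9)
  structure(list(center = as.numeric(center), radius = radius,
                 peak_frequency = peak_frequency, bandwidth = bandwidth,
                 mean_amplitude = mean_amplitude, timescale = timescale,
                 label = label),
            class = "source_patch")
}

#' Simulation scenario for synthetic resting-state EEG
#'
#' @param patches list of [source_patch()] objects (may be empty).
#' @param n_channels electrode count.
#' @param sampling_rate Hz.
#' @param duration total duration in seconds, split into `n_segments`
#'   equal concatenated segments (REC-like blocks).
#' @param n_segments number of concatenated segments.
#' @param noise list: `onef_exponent` (1/f^a background exponent),
#'   `background_amplitude` (RMS source amplitude of each diffuse
#'   background dipole, scalp-equivalent microvolts), `n_background`
#'   (number of diffuse dipoles), `sensor_sd` (white sensor noise standard
#'   deviation, microvolts).
#' @param seed random seed; a fixed seed makes the output bit-reproducible.
#' @return object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(patches, n_channels = 62, sampling_rate = 500,
                                duration = 240, n_segments = 4,
                                noise = list(onef_exponent = 1,
                                             background_amplitude = 2,
                                             n_background = 100,
                                             sensor_sd = 0.3),
                                seed = 1) {
  stopifnot(is.list(patches),
            all(vapply(patches, inherits, TRUE, "source_patch")))
  stopifnot_scalar(duration, "duration", lower = 1e-9)
  stopifnot(n_segments >= 1, duration / n_segments > 0)
  noise_defaults <- list(onef_exponent = 1, background_amplitude = 2,
                         n_background = 100, sensor_sd = 0.3)
  noise <- utils::modifyList(noise_defaults, noise)
  if (noise$sensor_sd < 0 || noise$background_amplitude < 0) {
    stop("noise amplitudes must be non-negative")
  }
  structure(list(patches = patches, n_channels = n_channels,
                 sampling_rate = sampling_rate, duration = duration,
                 n_segments = n_segments, noise = noise, seed = seed),
            class = "simulation_scenario")
}

#' Default two-component alpha scenario
#'
#' Two posterior oscillatory patches with the group-mean peak frequencies of
#' the high- and low-frequency alpha components (10.4 and 9.4 Hz): an
#' occipito-parietal patch near the midline and a left occipito-temporal
#' patch, with independently fluctuating envelopes, 1/f background from
#' diffuse random dipoles, and white sensor noise. Amplitudes are set so the
#' posterior-channel alpha peak stands roughly 3-10x above the background
#' spectrum: recoverable but not trivial.
#'
#' @param seed random seed.
#' @param duration total duration (seconds) over `n_segments` segments.
#' @param n_segments number of concatenated REC-like segments.
#' @param source_radius source-shell radius the patch centers are placed on
#'   (must match the lead field used).
#' @return a [simulation_scenario()].
#' @export
default_two_arc_scenario <- function(seed = 1, duration = 240, n_segments = 4,
                                     source_radius = 0.9 * 0.087) {
  unit <- function(v) v / sqrt(sum(v^2))
  patches <- list(
    source_patch(center = unit(c(0.10, -0.75, 0.65)) * source_radius,
                 radius = 0.045, peak_frequency = 10.4, bandwidth = 0.8,
                 mean_amplitude = 0.7, timescale = 6, label = "ARC1-like"),
    source_patch(center = unit(c(-0.60, -0.75, -0.15)) * source_radius,
                 radius = 0.050, peak_frequency = 9.4, bandwidth = 0.8,
                 mean_amplitude = 0.55, timescale = 8, label = "ARC2-like")
  )
  simulation_scenario(patches, seed = seed, duration = duration,
                      n_segments = n_segments)
}

# Gaussian spatial taper of a patch over the source grid (non-negative,
# zero outside `radius`; sigma = radius / 2).
patch_weights <- function(patch, grid) {
  d <- sqrt(colSums((t(grid$coords) - patch$center)^2))
  w <- exp(-d^2 / (2 * (patch$radius / 2)^2))
  w[d > patch$radius] <- 0
  if (sum(w > 0) < 1) stop("patch contains no source-grid points")
  w
}

# --- main generators --------------------------------------------------------

#' Simulate a multichannel EEG recording with known component structure
#'
#' The alpha-band content is a sum over patches of envelope-modulated
#' narrowband oscillations (white noise band-pass filtered at the patch's
#' peak frequency with the stated FWHM, zero-phase), spatially weighted by a
#' Gaussian taper over the patch and projected through the lead field;
#' added to it are a 1/f background generated by many weak random diffuse
#' dipoles and white sensor noise. Each concatenated segment draws fresh
#' envelopes and noise. The output is common-average referenced.
#'
#' @param scenario a [simulation_scenario()].
#' @param leadfield a [build_leadfield()] model whose channel count matches
#'   the scenario; every patch center must lie on its source shell.
#' @param seed optional override of `scenario$seed`.
#' @return list with `recording` (an [eeg_recording()]) and `ground_truth`
#'   (class `arc_ground_truth`): per patch the frequency profile on the
#'   5-15 Hz analysis grid, source- and channel-space spatial profiles
#'   (max-normalized; channel profile = |gain %*% source profile|),
#'   envelope time courses, per-window envelope RMS at the default STFT
#'   window centers, and the realized patch source signals.
#' @export
simulate_recording <- function(scenario, leadfield, seed = NULL) {
  stopifnot(inherits(scenario, "simulation_scenario"),
            inherits(leadfield, "leadfield_model"))
  if (nrow(leadfield$gain) != scenario$n_channels) {
    stop("lead field channel count does not match the scenario")
  }
  r_shell <- leadfield$grid$radius
  for (p in scenario$patches) {
    if (abs(sqrt(sum(p$center^2)) - r_shell) > 0.01 * r_shell) {
      stop(sprintf("patch '%s' center does not lie on the source shell (r = %.4f m)",
                   p$label, r_shell))
    }
  }
  fs <- scenario$sampling_rate
  seg_len <- as.integer(round(fs * scenario$duration / scenario$n_segments))
  if (seg_len < 5 * fs) {
    stop("each segment must be at least one 5-s analysis window long")
  }
  n_total <- seg_len * scenario$n_segments
  n_ch <- scenario$n_channels
  n_patch <- length(scenario$patches)
  K <- leadfield$gain

  W <- if (n_patch) vapply(scenario$patches, patch_weights, numeric(ncol(K)),
                           grid = leadfield$grid) else NULL  # sources x patches
  sensor_maps <- if (n_patch) K %*% W else NULL              # channels x patches

  gen <- function() {
    data <- matrix(0, n_ch, n_total)
    envelopes <- matrix(0, n_total, max(1, n_patch))[, seq_len(n_patch), drop = FALSE]
    patch_signals <- envelopes
    for (s in seq_len(scenario$n_segments)) {
      idx <- ((s - 1) * seg_len + 1):(s * seg_len)
      seg <- matrix(0, n_ch, seg_len)
      for (p in seq_len(n_patch)) {
        pa <- scenario$patches[[p]]
        osc <- narrowband_oscillation(seg_len, fs, pa$peak_frequency, pa$bandwidth)
        env <- amplitude_envelope(seg_len, fs, pa$mean_amplitude, pa$timescale)
        sig <- env * osc
        envelopes[idx, p] <- env
        patch_signals[idx, p] <- sig
        seg <- seg + sensor_maps[, p] %*% t(sig)
      }
      nz <- scenario$noise
      if (nz$background_amplitude > 0 && nz$n_background > 0) {
        bg_src <- sample.int(ncol(K), nz$n_background, replace = FALSE)
        resp <- function(f) ifelse(f > 0, f^(-nz$onef_exponent / 2), 0)
        bg <- vapply(seq_len(nz$n_background), function(i) {
          x <- shaped_noise(seg_len, fs, resp)
          x / stats::sd(x) * nz$background_amplitude
        }, numeric(seg_len))                      # samples x n_background
        seg <- seg + K[, bg_src, drop = FALSE] %*% t(bg)
      }
      if (nz$sensor_sd > 0) {
        seg <- seg + matrix(stats::rnorm(n_ch * seg_len, sd = nz$sensor_sd),
                            n_ch, seg_len)
      }
      data[, idx] <- seg
    }
    list(data = data, envelopes = envelopes, patch_signals = patch_signals)
  }
  out <- with_seed(seed %||% scenario$seed, gen())
  # common-average reference (lead-field part is already average-free)
  data <- sweep(out$data, 2, colMeans(out$data))

  rec <- eeg_recording(
    data, fs, channel_positions = leadfield$positions,
    channel_names = leadfield$channel_names,
    segment_starts = seg_len * (seq_len(scenario$n_segments) - 1L) + 1L)

  freqs <- seq(5, 15, by = 0.2)
  gt <- ground_truth_from_parts(scenario, leadfield, W, sensor_maps,
                                out$envelopes, out$patch_signals, freqs, fs,
                                seg_len)
  list(recording = rec, ground_truth = gt)
}

ground_truth_from_parts <- function(scenario, leadfield, W, sensor_maps,
                                    envelopes, patch_signals, freqs, fs,
                                    seg_len) {
  n_patch <- length(scenario$patches)
  freq_prof <- src_prof <- ch_prof <- NULL
  if (n_patch) {
    freq_prof <- vapply(scenario$patches, function(p) {
      max_normalize(gaussian_band(p$peak_frequency, p$bandwidth)(freqs))
    }, numeric(length(freqs)))
    src_prof <- apply(W, 2, max_normalize)
    ch_prof <- apply(abs(sensor_maps), 2, max_normalize)
  }
  # envelope RMS in the default 5-s / 50%-overlap windows, seam-respecting
  L <- as.integer(5 * fs); hop <- L %/% 2L
  centers <- integer(0); temporal <- NULL
  if (seg_len >= L) {
    starts <- unlist(lapply(seq_len(scenario$n_segments), function(s) {
      seq.int((s - 1) * seg_len + 1L, s * seg_len - L + 1L, by = hop)
    }))
    centers <- starts + L %/% 2L
    if (n_patch) {
      temporal <- vapply(seq_len(n_patch), function(p) {
        vapply(starts, function(st) {
          sqrt(mean(envelopes[st:(st + L - 1L), p]^2))
        }, 0)
      }, numeric(length(starts)))
    }
  }
  structure(
    list(freqs = freqs,
         true_frequency_profiles = freq_prof,
         true_source_profiles = src_prof,
         true_channel_profiles = ch_prof,
         true_temporal_profiles = temporal,
         window_centers = centers,
         envelopes = envelopes, patch_signals = patch_signals,
         patch_labels = vapply(scenario$patches, `[[`, "", "label"),
         peak_frequencies = vapply(scenario$patches, `[[`, 0, "peak_frequency")),
    class = "arc_ground_truth"
  )
}

#' Simulate a tensor with exact low trilinear rank
#'
#' Builds the exact K-component trilinear product of randomly drawn
#' non-negative loading vectors (uniform on [0.2, 1], keeping tensor entries
#' bounded away from zero so additive noise rarely clips) plus Gaussian
#' noise of the stated standard deviation; negative entries caused by noise
#' are clipped at zero.
#'
#' @param K number of components (>= 1).
#' @param dims integer triple `(n_space, n_freq, n_time)`, each >= K.
#' @param noise_sd additive noise standard deviation (>= 0).
#' @param seed optional seed.
#' @return list with `tensor` (a `spectral_tensor`, space x freq x time)
#'   and `ground_truth` (drawn loadings `A` frequency, `B` space, `C` time,
#'   plus the realized noise array).
#' @export
simulate_tensor <- function(K, dims, noise_sd = 0, seed = NULL) {
  stopifnot(K >= 1, length(dims) == 3, all(dims >= K))
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  out <- with_seed(seed, {
    B <- matrix(runif(dims[1] * K, 0.2, 1), dims[1], K)   # space
    A <- matrix(runif(dims[2] * K, 0.2, 1), dims[2], K)   # frequency
    C <- matrix(runif(dims[3] * K, 0.2, 1), dims[3], K)   # time
    noise <- if (noise_sd > 0) array(rnorm(prod(dims), sd = noise_sd), dims)
             else array(0, dims)
    list(A = A, B = B, C = C, noise = noise)
  })
  X <- array(0, dims)                                      # space x freq x time
  Xf <- out$B %*% t(khatri_rao(out$C, out$A))              # space x (freq*time)
  dim(Xf) <- dims
  X <- pmax(Xf + out$noise, 0)
  tensor <- new_spectral_tensor(X, "sensor",
                                freqs = 5 + 0.2 * (seq_len(dims[2]) - 1),
                                window_centers = seq_len(dims[3]),
                                window_segment = rep(1L, dims[3]),
                                units = "a.u.")
  list(tensor = tensor,
       ground_truth = structure(list(A = out$A, B = out$B, C = out$C,
                                     noise = out$noise),
                                class = "tensor_ground_truth"))
}
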