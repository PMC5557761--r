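#' EEG recording container
#'
#' A channels x samples matrix in microvolts with sampling rate, channel
#' positions, and the start indices of the concatenated resting-state
#' segments (REC periods).
#'
#' @param data channels x samples numeric matrix (microvolts), no NaN/Inf.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_positions channels x 3 coordinates (meters; head frame
#'   with origin at the sphere center, +x right, +y anterior, +z superior).
#' @param channel_names optional channel names (default from positions or
#'   generic).
#' @param segment_starts 1-based sample indices at which each concatenated
#'   segment begins; must start at 1, be strictly increasing, and stay
#'   within the recording.
#' @param reference reference tag; the pipeline expects "common-average".
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, channel_positions,
                          channel_names = NULL, segment_starts = 1L,
                          reference = "common-average") {
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data))) {
    stop("`data` must be a finite numeric matrix (channels x samples)")
  }
  if (nrow(data) < 2) stop("need at least 2 channels")
  stopifnot_scalar(sampling_rate, "sampling_rate", lower = 1)
  channel_positions <- as.matrix(channel_positions)
  stopifnot(nrow(channel_positions) == nrow(data), ncol(channel_positions) == 3)
  segment_starts <- as.integer(segment_starts)
  if (segment_starts[1] != 1L || any(diff(segment_starts) <= 0) ||
      any(segment_starts > ncol(data))) {
    stop("`segment_starts` must begin at 1, increase strictly, and stay within the recording")
  }
  if (is.null(channel_names)) {
    channel_names <- rownames(channel_positions) %||% sprintf("E%02d", seq_len(nrow(data)))
  }
  rownames(data) <- channel_names
  structure(
    list(data = data, sampling_rate = sampling_rate,
         channel_names = channel_names, channel_positions = channel_positions,
         segment_starts = segment_starts, reference = reference),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz; %d segment(s); ref %s\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              length(x$segment_starts), x$reference))
  invisible(x)
}

# (start, end) sample spans of the concatenated segments
segment_spans <- function(recording) {
  starts <- recording$segment_starts
  ends <- c(starts[-1] - 1L, ncol(recording$data))
  cbind(start = starts, end = ends)
}

# Hann taper, periodic convention: mean of squared values is exactly 3/8.
hann_taper <- function(L) 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1) / L))

#' Short-time Fourier transform of an EEG recording
#'
#' Computes Hann-tapered windowed DFTs, scaled by 1/L, on windows that never
#' straddle a concatenated-segment boundary: windowing restarts at the first
#' sample of each segment, with the given overlap. Only frequency bins inside
#' `band` (inclusive) are kept; the frequency spacing is
#' `1 / window_seconds`.
#'
#' @param recording an [eeg_recording()].
#' @param window_seconds window length in seconds (default 5, giving 0.2 Hz
#'   resolution); `sampling_rate * window_seconds` must be an integer.
#' @param overlap fractional window overlap in `[0, 1)` (default 0.5).
#' @param band inclusive analysis band in Hz (default the extended alpha
#'   range 5-15 Hz); must lie strictly inside (0, Nyquist).
#' @param amplitude_threshold optional artifact guard in microvolts: windows
#'   containing any sample exceeding it in magnitude are dropped.
#' @return object of class `stft_tensor` with complex `values`
#'   (channels x frequencies x windows), `freqs`, `window_centers` (sample
#'   indices), `window_segment` (segment index per window), the taper, and
#'   axis metadata.
#' @export
stft <- function(recording, window_seconds = 5, overlap = 0.5,
                 band = c(5, 15), amplitude_threshold = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  stopifnot_scalar(window_seconds, "window_seconds", lower = 1e-6)
  stopifnot_scalar(overlap, "overlap", lower = 0, upper = 1 - 1e-9)
  fs <- recording$sampling_rate
  L_real <- fs * window_seconds
  L <- as.integer(round(L_real))
  if (abs(L_real - L) > 1e-8) {
    stop("`sampling_rate * window_seconds` must be an integer number of samples")
  }
  nyq <- fs / 2
  if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2]) {
    stop("`band` must lie strictly inside (0, Nyquist)")
  }
  taper <- hann_taper(L)
  freqs_all <- (0:(L - 1)) * fs / L
  keep <- which(freqs_all >= band[1] - 1e-9 & freqs_all <= band[2] + 1e-9)
  hop <- max(1L, as.integer(round(L * (1 - overlap))))

  spans <- segment_spans(recording)
  starts <- integer(0); seg_of <- integer(0)
  for (s in seq_len(nrow(spans))) {
    if (spans[s, "end"] - spans[s, "start"] + 1L < L) {
      warning(sprintf("segment %d shorter than one window; skipped", s))
      next
    }
    st <- seq.int(spans[s, "start"], spans[s, "end"] - L + 1L, by = hop)
    starts <- c(starts, st)
    seg_of <- c(seg_of, rep(s, length(st)))
  }
  if (length(starts) == 0) stop("no segment long enough for a single window")

  n_ch <- nrow(recording$data)
  dropped <- logical(length(starts))
  values <- array(0i, dim = c(n_ch, length(keep), length(starts)))
  for (w in seq_along(starts)) {
    seg <- recording$data[, starts[w]:(starts[w] + L - 1L), drop = FALSE]
    if (!is.null(amplitude_threshold) && max(abs(seg)) > amplitude_threshold) {
      dropped[w] <- TRUE
      next
    }
    ft <- stats::mvfft(t(seg) * taper) / L        # L x channels
    values[, , w] <- t(ft[keep, , drop = FALSE])
  }
  if (any(dropped)) {
    values <- values[, , !dropped, drop = FALSE]
    starts <- starts[!dropped]; seg_of <- seg_of[!dropped]
    if (length(starts) == 0) stop("all windows rejected by the amplitude threshold")
  }
  dimnames(values) <- list(recording$channel_names, NULL, NULL)
  structure(
    list(values = values, freqs = freqs_all[keep],
         window_length_samples = L, window_centers = starts + L %/% 2L,
         window_segment = seg_of, taper = "hann", taper_values = taper,
         overlap = overlap, sampling_rate = fs, df = fs / L,
         channel_names = recording$channel_names,
         channel_positions = recording$channel_positions),
    class = "stft_tensor"
  )
}

#' @export
print.stft_tensor <- function(x, ...) {
  cat(sprintf("<stft_tensor> %d channels x %d freqs (%.3g-%.3g Hz, df=%.3g) x %d windows\n",
              dim(x$values)[1], dim(x$values)[2], min(x$freqs), max(x$freqs),
              x$df, dim(x$values)[3]))
  invisible(x)
}

#' Cross-spectral density set from an STFT tensor
#'
#' For each frequency f and window t the cross-spectral density matrix is
#' `2 / (mean(W^2) * df) * phi phi*`, the rank-one outer product of the
#' channel STFT vector with its conjugate. The normalization uses the mean
#' squared value of the actual taper samples (exactly 0.375 for the periodic
#' Hann taper); the one-sided factor 2 applies uniformly since the analysis
#' band excludes DC and Nyquist. The rank-one structure is kept implicit
#' (the STFT vectors are stored); use [csd_matrix()] to materialize any
#' channels x channels slice.
#'
#' @param stft an `stft_tensor`.
#' @return object of class `csd_set` with the STFT values, the scalar
#'   `normalization`, and shared axis metadata.
#' @export
cross_spectral_density <- function(stft) {
  stopifnot(inherits(stft, "stft_tensor"))
  if (length(stft$values) == 0) stop("empty STFT")
  msq <- mean(stft$taper_values^2)
  structure(
    list(phi = stft$values, normalization = 2 / (msq * stft$df),
         taper_mean_square = msq, freqs = stft$freqs,
         window_centers = stft$window_centers,
         window_segment = stft$window_segment, df = stft$df,
         channel_names = stft$channel_names,
         channel_positions = stft$channel_positions),
    class = "csd_set"
  )
}

#' Materialize one cross-spectral density matrix
#'
#' @param csd a `csd_set`.
#' @param f_index frequency bin index.
#' @param t_index window index.
#' @return Hermitian channels x channels complex matrix.
#' @export
csd_matrix <- function(csd, f_index, t_index) {
  phi <- csd$phi[, f_index, t_index]
  csd$normalization * (phi %*% Conj(t(phi)))
}

#' @export
print.csd_set <- function(x, ...) {
  cat(sprintf("<csd_set> %d channels, %d freqs x %d windows; normalization %.4g (mean W^2 = %.4g)\n",
              dim(x$phi)[1], dim(x$phi)[2], dim(x$phi)[3],
              x$normalization, x$taper_mean_square))
  invisible(x)
}

# internal constructor shared by sensor- and source-space ASD
new_spectral_tensor <- function(values, space_kind, freqs, window_centers,
                                window_segment, space_names = NULL,
                                units = "uV/sqrt(Hz)") {
  if (min(values) < -1e-9) {
    stop("amplitude spectrum has a significantly negative entry; internal inconsistency")
  }
  values[values < 0] <- 0
  dimnames(values) <- list(space_names, NULL, NULL)
  structure(
    list(values = values, space_kind = space_kind, freqs = freqs,
         window_centers = window_centers, window_segment = window_segment,
         units = units),
    class = "spectral_tensor"
  )
}

#' Three-way amplitude-spectrum tensor (sensor space)
#'
#' The amplitude spectral density is the square root of the diagonal of each
#' cross-spectral density matrix, arranged as a non-negative
#' space x frequency x time array: the input to the first PARAFAC stage.
#'
#' @param csd a `csd_set`.
#' @return object of class `spectral_tensor` (`space_kind = "sensor"`).
#' @export
amplitude_spectrum <- function(csd) {
  stopifnot(inherits(csd, "csd_set"))
  # diag(norm * phi phi*) = norm * |phi|^2, non-negative by construction
  values <- sqrt(csd$normalization) * abs(csd$phi)
  new_spectral_tensor(values, "sensor", csd$freqs, csd$window_centers,
                      csd$window_segment, space_names = csd$channel_names)
}

#' @export
print.spectral_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<spectral_tensor> %s space: %d x %d freqs x %d windows [%s]\n",
              x$space_kind, d[1], d[2], d[3], x$units))
  invisible(x)
}
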