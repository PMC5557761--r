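# spectral flatness: geometric over arithmetic mean; 1 for a flat profile,
# near 0 for a single-bin peak
spectral_flatness <- function(x) {
  if (any(x < 0)) stop("spectral flatness needs a non-negative profile")
  m <- mean(x)
  if (m == 0) return(1)
  exp(mean(log(pmax(x, .Machine$double.xmin)))) / m
}

posterior_fraction <- function(loading, mask) sum(loading[mask]) / sum(loading)

#' Remove noise components from a sensor-space PARAFAC model
#'
#' Drops components whose frequency loading is spectrally flat (geometric /
#' arithmetic mean ratio above `flatness_max`: noise-like rather than
#' peaked) or whose spatial loading mass falls mostly outside the posterior
#' mask (fraction below `posterior_min`: e.g. frontal eye/muscle artifact
#' topographies). Remaining components are re-indexed; the decision log is
#' attached as attribute `"rejection_log"`.
#'
#' @param model a `parafac_model` fitted in sensor space.
#' @param posterior_mask logical vector over the spatial dimension (TRUE =
#'   posterior).
#' @param flatness_max maximum admissible spectral flatness.
#' @param posterior_min minimum admissible posterior loading fraction.
#' @return the pruned `parafac_model`; error if every component is rejected.
#' @export
reject_noise_components <- function(model, posterior_mask, flatness_max = 0.7,
                                    posterior_min = 0.5) {
  stopifnot(inherits(model, "parafac_model"),
            length(posterior_mask) == nrow(model$B))
  flat <- apply(model$A, 2, spectral_flatness)
  post <- apply(model$B, 2, posterior_fraction, mask = posterior_mask)
  keep <- flat <= flatness_max & post >= posterior_min
  log <- data.frame(component = seq_len(model$K), flatness = flat,
                    posterior_fraction = post, kept = keep)
  if (!any(keep)) {
    stop("all components rejected as noise; decomposition invalid")
  }
  model$A <- model$A[, keep, drop = FALSE]
  model$B <- model$B[, keep, drop = FALSE]
  model$C <- model$C[, keep, drop = FALSE]
  model$K <- sum(keep)
  attr(model, "rejection_log") <- log
  model
}

#' Label alpha rhythm components by peak frequency and topography
#'
#' With two retained components the higher-peak one is ARC1 and the lower
#' ARC2; with three, the lowest-frequency component is ARC2 and the two
#' higher-frequency (typically occipito-parietal) ones are ARC1a/ARC1b in
#' descending peak order; a single component is left "unclassified" (a lone
#' posterior component cannot be identified with either class). Equal peak
#' frequencies are resolved by the larger first-mode (frequency-loading)
#' magnitude.
#'
#' @param components list of `arc_component` objects (fields
#'   `peak_frequency` and `magnitude` must be present).
#' @return the list with `label` fields assigned.
#' @export
label_components <- function(components) {
  n <- length(components)
  if (n < 1) stop("need at least one component")
  peaks <- vapply(components, `[[`, 0, "peak_frequency")
  mags <- vapply(components, `[[`, 0, "magnitude")
  ord <- order(peaks, mags, decreasing = TRUE)   # ties -> larger magnitude first
  labels <- rep("unclassified", n)
  if (n == 2) {
    labels[ord] <- c("ARC1", "ARC2")
  } else if (n >= 3) {
    labels[ord[n]] <- "ARC2"                     # lowest frequency
    labels[ord[1:2]] <- c("ARC1a", "ARC1b")      # two highest
  }
  for (i in seq_len(n)) components[[i]]$label <- labels[i]
  components
}

new_arc_component <- function(freq_loading, sensor_loading, source_loading,
                              temporal_loading, freqs, posterior_mask_src,
                              magnitude) {
  list(label = "unclassified",
       peak_frequency = freqs[which.max(freq_loading)],
       frequency_loading = max_normalize(freq_loading),
       sensor_loading = if (is.null(sensor_loading)) NULL
                        else max_normalize(sensor_loading),
       source_loading = max_normalize(source_loading),
       temporal_loading = max_normalize(temporal_loading),
       spectral_flatness = spectral_flatness(freq_loading),
       posterior_fraction = posterior_fraction(source_loading,
                                               posterior_mask_src),
       magnitude = magnitude)
}

#' Two-stage frequency-space-time decomposition of one subject's EEG
#'
#' Runs the full single-subject pipeline: (1) seam-respecting STFT and
#' cross-spectra of the concatenated resting segments, (2) sensor-space
#' amplitude-spectrum tensor and non-negative PARAFAC with CORCONDIA model
#' order selection, (3) rejection of flat-spectrum / non-posterior noise
#' components, (4) LORETA source imaging of the cross-spectra and a second
#' PARAFAC in source space with the frequency and temporal modes fixed to
#' the retained sensor-space estimates, and (5) component labeling by peak
#' frequency.
#'
#' @param recording an [eeg_recording()].
#' @param config an [arc_config()] list of pipeline parameters.
#' @param leadfield optional precomputed [build_leadfield()]; by default one
#'   is built from the recording's channel positions with
#'   `config$n_sources` sources.
#' @return object of class `arc_decomposition`: `sensor_model` (pruned),
#'   `sensor_model_full`, `source_model`, `components` (labeled
#'   `arc_component` list), `selection` diagnostics, `inverse`, STFT axis
#'   metadata, and the config used.
#' @export
decompose_subject <- function(recording, config = arc_config(),
                              leadfield = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  config <- validate_config(config)

  sp <- stft(recording, window_seconds = config$window_seconds,
             overlap = config$overlap, band = config$band,
             amplitude_threshold = config$amplitude_threshold)
  csd <- cross_spectral_density(sp)
  asd <- amplitude_spectrum(csd)

  sel <- select_num_components(asd, K_max = config$K_max,
                               threshold = config$corcondia_threshold,
                               n_starts = config$n_starts, tol = config$tol,
                               max_iter = config$max_iter,
                               seed = config$seed)
  sensor_model_full <- sel$models[[sel$K]]

  posterior_sensors <- recording$channel_positions[, 2] < 0
  sensor_model <- reject_noise_components(
    sensor_model_full, posterior_sensors,
    flatness_max = config$flatness_max, posterior_min = config$posterior_min)

  if (is.null(leadfield)) {
    leadfield <- build_leadfield(recording$channel_positions,
                                 n_sources = config$n_sources)
  }
  inv <- loreta_inverse(leadfield, alpha = config$alpha,
                        method = config$inverse_method)
  asd_src <- source_amplitude_spectrum(inv, csd)

  source_model <- parafac_als(
    asd_src, K = sensor_model$K,
    fixed = list(frequency = sensor_model$A, time = sensor_model$C),
    n_starts = 1, tol = config$tol, max_iter = config$max_iter,
    seed = config$seed)
  source_model$corcondia <- corcondia(asd_src, source_model)

  posterior_sources <- inv$grid$coords[, 2] < 0
  components <- lapply(seq_len(sensor_model$K), function(k) {
    new_arc_component(
      freq_loading = sensor_model$A[, k],
      sensor_loading = sensor_model$B[, k],
      source_loading = source_model$B[, k],
      temporal_loading = sensor_model$C[, k],
      freqs = sp$freqs, posterior_mask_src = posterior_sources,
      magnitude = sum(sensor_model$A[, k]^2))
  })
  components <- label_components(components)

  structure(
    list(sensor_model = sensor_model, sensor_model_full = sensor_model_full,
         source_model = source_model, components = components,
         selection = sel$diagnostics, K = sensor_model$K,
         none_valid = sel$none_valid, inverse = inv,
         freqs = sp$freqs, window_centers = sp$window_centers,
         window_segment = sp$window_segment, config = config),
    class = "arc_decomposition"
  )
}

#' @export
print.arc_decomposition <- function(x, ...) {
  cat(sprintf("<arc_decomposition> %d component(s) retained (K selected = %d)\n",
              length(x$components), x$sensor_model_full$K))
  print(component_table(x))
  invisible(x)
}

#' Summary table of labeled components
#'
#' @param decomposition an `arc_decomposition`.
#' @return data.frame: label, peak frequency (Hz), spectral flatness,
#'   posterior source-loading fraction.
#' @export
component_table <- function(decomposition) {
  comps <- decomposition$components
  data.frame(
    label = vapply(comps, `[[`, "", "label"),
    peak_frequency = vapply(comps, `[[`, 0, "peak_frequency"),
    spectral_flatness = vapply(comps, `[[`, 0, "spectral_flatness"),
    posterior_fraction = vapply(comps, `[[`, 0, "posterior_fraction"))
}

#' Congruence between recovered components and simulation ground truth
#'
#' Matches recovered components to the ground-truth patches by their
#' frequency loadings and reports the Tucker congruence per mode
#' (frequency, source-space spatial, channel-space spatial).
#'
#' @param decomposition an `arc_decomposition` of a simulated recording.
#' @param ground_truth the matching `arc_ground_truth`.
#' @return data.frame with one row per ground-truth patch: matched
#'   component label and per-mode congruence.
#' @export
recovery_congruence <- function(decomposition, ground_truth) {
  stopifnot(inherits(decomposition, "arc_decomposition"),
            inherits(ground_truth, "arc_ground_truth"))
  est_freq <- sapply(decomposition$components, `[[`, "frequency_loading")
  m <- match_components(ground_truth$true_frequency_profiles, est_freq)
  rows <- lapply(seq_along(m), function(i) {
    comp <- decomposition$components[[m[i]]]
    data.frame(
      patch = ground_truth$patch_labels[i],
      matched_label = comp$label,
      tcc_frequency = tucker_congruence(
        ground_truth$true_frequency_profiles[, i], comp$frequency_loading),
      tcc_source = tucker_congruence(
        ground_truth$true_source_profiles[, i], comp$source_loading),
      tcc_channel = if (is.null(comp$sensor_loading)) NA_real_ else
        tucker_congruence(ground_truth$true_channel_profiles[, i],
                          comp$sensor_loading))
  })
  do.call(rbind, rows)
}
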