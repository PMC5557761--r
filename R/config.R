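#' Pipeline configuration
#'
#' Collects every tunable parameter of the decomposition pipeline with the
#' defaults used throughout: 5-s Hann windows with 50 percent overlap over
#' the 5-15 Hz extended alpha band, a 387-point source grid, CORCONDIA
#' model selection up to K_max = 6 with a 90 percent validity threshold,
#' flat-spectrum / non-posterior component rejection, and 5000-permutation
#' cluster statistics at the 99th-percentile cluster-forming threshold.
#'
#' @param window_seconds STFT window length (seconds).
#' @param overlap fractional window overlap in `[0, 1)`.
#' @param band inclusive analysis band (Hz), strictly inside (0, Nyquist).
#' @param amplitude_threshold artifact guard (microvolts); windows with any
#'   sample beyond it are dropped. `NULL` disables the guard.
#' @param n_sources source-grid size.
#' @param K_max largest PARAFAC order tried.
#' @param corcondia_threshold core-consistency validity threshold (percent).
#' @param n_starts ALS multi-start count.
#' @param tol ALS convergence tolerance (relative fit change).
#' @param max_iter maximum ALS sweeps.
#' @param flatness_max spectral-flatness rejection threshold.
#' @param posterior_min minimum posterior loading fraction.
#' @param alpha inverse regularization; `NULL` = automatic.
#' @param inverse_method "loreta" or "mnorm".
#' @param n_perm permutations for group statistics.
#' @param cluster_percentile cluster-forming percentile.
#' @param seed top-level seed; stage seeds are derived from it.
#' @return named list of class `arc_config`.
#' @export
arc_config <- function(window_seconds = 5, overlap = 0.5, band = c(5, 15),
                       amplitude_threshold = 100, n_sources = 387,
                       K_max = 6, corcondia_threshold = 90, n_starts = 10,
                       tol = 1e-8, max_iter = 2000, flatness_max = 0.7,
                       posterior_min = 0.5, alpha = NULL,
                       inverse_method = "loreta", n_perm = 5000,
                       cluster_percentile = 99, seed = 1) {
  cfg <- structure(
    list(window_seconds = window_seconds, overlap = overlap, band = band,
         amplitude_threshold = amplitude_threshold, n_sources = n_sources,
         K_max = K_max, corcondia_threshold = corcondia_threshold,
         n_starts = n_starts, tol = tol, max_iter = max_iter,
         flatness_max = flatness_max, posterior_min = posterior_min,
         alpha = alpha, inverse_method = inverse_method, n_perm = n_perm,
         cluster_percentile = cluster_percentile, seed = seed),
    class = "arc_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot_scalar(cfg$window_seconds, "window_seconds", lower = 1e-6)
  stopifnot_scalar(cfg$overlap, "overlap", lower = 0, upper = 1 - 1e-9)
  stopifnot(length(cfg$band) == 2, cfg$band[1] > 0, cfg$band[1] < cfg$band[2])
  if (!is.null(cfg$amplitude_threshold)) {
    stopifnot_scalar(cfg$amplitude_threshold, "amplitude_threshold", lower = 1e-9)
  }
  stopifnot_scalar(cfg$n_sources, "n_sources", lower = 10)
  stopifnot_scalar(cfg$K_max, "K_max", lower = 1)
  stopifnot_scalar(cfg$corcondia_threshold, "corcondia_threshold",
                   lower = -1e6, upper = 100)
  stopifnot_scalar(cfg$n_starts, "n_starts", lower = 1)
  stopifnot_scalar(cfg$tol, "tol", lower = 1e-15)
  stopifnot_scalar(cfg$max_iter, "max_iter", lower = 1)
  stopifnot_scalar(cfg$flatness_max, "flatness_max", lower = 0, upper = 1)
  stopifnot_scalar(cfg$posterior_min, "posterior_min", lower = 0, upper = 1)
  if (!is.null(cfg$alpha)) stopifnot_scalar(cfg$alpha, "alpha", lower = 0)
  stopifnot(cfg$inverse_method %in% c("loreta", "mnorm"))
  stopifnot_scalar(cfg$n_perm, "n_perm", lower = 1)
  stopifnot_scalar(cfg$cluster_percentile, "cluster_percentile",
                   lower = 50, upper = 100 - 1e-9)
  stopifnot_scalar(cfg$seed, "seed", lower = -2^31, upper = 2^31)
  cfg
}

#' Read / write a pipeline configuration (YAML)
#'
#' The configuration round-trips losslessly through a YAML key-value file.
#'
#' @param path file path.
#' @return `read_config` returns a validated `arc_config`;
#'   `write_config` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- arc_config()
  for (nm in names(raw)) {
    if (!nm %in% names(cfg)) stop(sprintf("unknown config field '%s'", nm))
    cfg[[nm]] <- if (nm == "band") as.numeric(raw[[nm]]) else raw[[nm]]
  }
  validate_config(cfg)
}

#' @param config an `arc_config`.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(config[!vapply(config, is.null, TRUE)], path, precision = 17)
  invisible(path)
}

#' Content hash of a configuration
#'
#' MD5 digest of the canonical YAML serialization, for run provenance logs.
#'
#' @param config an `arc_config`.
#' @return hex digest string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}
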