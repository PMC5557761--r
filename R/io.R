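# Plain-text persistence: recordings as TSV matrix + YAML sidecar,
# models/components as TSV tables. All artifacts round-trip losslessly at
# full double precision.

#' Write / read an EEG recording as TSV + YAML sidecar
#'
#' The sample matrix is written channels-in-columns to `<prefix>.tsv`
#' (full double precision) and the metadata (sampling rate, channel names
#' and positions, segment starts, reference) to `<prefix>.yaml`.
#'
#' @param recording an [eeg_recording()].
#' @param prefix file path prefix (without extension).
#' @return `write_recording` returns `prefix` invisibly; `read_recording`
#'   returns the reconstructed [eeg_recording()].
#' @export
write_recording <- function(recording, prefix) {
  stopifnot(inherits(recording, "eeg_recording"))
  tsv <- paste0(prefix, ".tsv")
  write.table(format(t(recording$data), digits = 17, trim = TRUE,
                     scientific = TRUE),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = recording$channel_names)
  meta <- list(sampling_rate = recording$sampling_rate,
               channel_names = as.list(recording$channel_names),
               channel_positions = apply(recording$channel_positions, 1,
                                         as.numeric, simplify = FALSE),
               segment_starts = as.integer(recording$segment_starts),
               reference = recording$reference)
  yaml::write_yaml(meta, paste0(prefix, ".yaml"), precision = 17)
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, ".yaml"))
  mat <- as.matrix(read.table(paste0(prefix, ".tsv"), sep = "\t",
                              header = TRUE, check.names = FALSE))
  pos <- do.call(rbind, meta$channel_positions)
  eeg_recording(t(mat), meta$sampling_rate, channel_positions = pos,
                channel_names = unlist(meta$channel_names),
                segment_starts = meta$segment_starts,
                reference = meta$reference)
}

#' Write / read a PARAFAC model as TSV tables
#'
#' Loadings are stored as three TSV tables (`A` frequency, `B` space, `C`
#' time) plus a YAML file of scalar diagnostics under `dir`.
#'
#' @param model a `parafac_model`.
#' @param dir output directory (created if missing).
#' @return `write_parafac` returns `dir` invisibly; `read_parafac` the
#'   reconstructed model.
#' @export
write_parafac <- function(model, dir) {
  stopifnot(inherits(model, "parafac_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("A", "B", "C")) {
    write.table(format(model[[nm]], digits = 17, trim = TRUE,
                       scientific = TRUE),
                file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE,
                col.names = paste0("k", seq_len(model$K)))
  }
  meta <- model[c("K", "fixed_modes", "fit", "residual_norm", "n_iterations",
                  "converged", "degenerate", "corcondia", "dims")]
  meta$fixed_modes <- as.list(meta$fixed_modes)
  yaml::write_yaml(meta, file.path(dir, "model.yaml"), precision = 17)
  invisible(dir)
}

#' @rdname write_parafac
#' @export
read_parafac <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "model.yaml"))
  mats <- lapply(c("A", "B", "C"), function(nm) {
    as.matrix(read.table(file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                         header = TRUE, check.names = FALSE))
  })
  structure(
    list(K = meta$K, A = unname(mats[[1]]), B = unname(mats[[2]]),
         C = unname(mats[[3]]),
         fixed_modes = unlist(meta$fixed_modes) %||% character(0),
         fit = meta$fit, residual_norm = meta$residual_norm,
         n_iterations = meta$n_iterations, converged = meta$converged,
         fit_trace = NULL, degenerate = meta$degenerate,
         corcondia = meta$corcondia %||% NA_real_,
         dims = unlist(meta$dims)),
    class = "parafac_model")
}

#' Export the labeled component table as TSV
#'
#' @param decomposition an `arc_decomposition`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_component_table <- function(decomposition, path) {
  write.table(component_table(decomposition), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export source-grid region labels as a coordinate table (TSV)
#'
#' @param grid a [source_grid()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(grid, path) {
  df <- data.frame(grid$coords, region = grid$region_labels)
  names(df)[1:3] <- c("x", "y", "z")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
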