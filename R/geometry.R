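#' Quasi-uniform points on a sphere (Fibonacci lattice)
#'
#' Generates `n` points that cover a sphere (or a spherical cap) almost
#' uniformly, using the golden-angle spiral. Deterministic: no randomness.
#'
#' @param n number of points.
#' @param radius sphere radius in meters.
#' @param z_range inclusive range of z/radius covered; `c(-1, 1)` is the full
#'   sphere, e.g. `c(-0.25, 0.995)` is an EEG-cap-like upper cap.
#' @return n x 3 matrix of coordinates (meters); head frame: +x right,
#'   +y anterior, +z superior, origin at the sphere center.
#' @export
fibonacci_sphere <- function(n, radius = 1, z_range = c(-1, 1)) {
  stopifnot(n >= 1, z_range[1] < z_range[2])
  i <- seq_len(n) - 0.5
  z <- z_range[2] - (z_range[2] - z_range[1]) * i / n
  golden <- pi * (3 - sqrt(5))
  theta <- golden * (seq_len(n) - 1)
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(x = rho * cos(theta), y = rho * sin(theta), z = z) * radius
}

#' Generic 62-channel sensor layout on the scalp sphere
#'
#' Places electrodes quasi-uniformly over an upper spherical cap reaching
#' slightly below the equator, mimicking the coverage of a mid-density EEG
#' cap. Channel names are generic (`E01`, `E02`, ...).
#'
#' @param n_channels number of electrodes.
#' @param radius scalp radius in meters.
#' @return list with `positions` (n x 3 matrix, meters) and `names`.
#' @export
sensor_layout <- function(n_channels = 62, radius = 0.1) {
  pos <- fibonacci_sphere(n_channels, radius, z_range = c(-0.35, 0.98))
  rownames(pos) <- sprintf("E%02d", seq_len(n_channels))
  list(positions = pos, names = rownames(pos))
}

#' Geometric region labels for points on a head-frame sphere
#'
#' Assigns coarse geometric sector labels that stand in for anatomical
#' parcellation: points well behind the coronal plane are posterior
#' ("occipito-parietal" if superior, "occipito-temporal" if inferior),
#' points well in front are "frontal", the rest "central".
#'
#' @param coords n x 3 matrix in the head frame (+y anterior, +z superior).
#' @return character vector of labels.
#' @export
grid_regions <- function(coords) {
  r <- sqrt(rowSums(coords^2))
  y <- coords[, 2] / r
  z <- coords[, 3] / r
  lab <- rep("central", nrow(coords))
  lab[y > 0.25] <- "frontal"
  lab[y < -0.25 & z >= 0] <- "occipito-parietal"
  lab[y < -0.25 & z < 0] <- "occipito-temporal"
  lab
}

#' Build a source grid on a spherical shell
#'
#' Creates a quasi-uniform grid of `n_sources` points at the given radius,
#' together with a symmetric spatial adjacency (pairs closer than
#' `adjacency_factor` times the median nearest-neighbor distance) and
#' geometric region labels. By default the grid covers a cerebrum-like
#' spherical cap (down to `z = -0.3` radius below the axial plane) rather
#' than the full sphere: cortical gray matter does not extend under the
#' head, and sources far below the electrode cap would be unobservable.
#'
#' @param n_sources number of grid points.
#' @param radius shell radius in meters.
#' @param adjacency_factor multiple of the median nearest-neighbor distance
#'   below which two grid points count as neighbors.
#' @param z_range extent of the covered cap as a fraction of the radius.
#' @return object of class `source_grid`: `coords`, `adjacency` (list of
#'   integer neighbor vectors), `r_adj`, `region_labels`, `radius`.
#' @export
source_grid <- function(n_sources = 387, radius = 0.078, adjacency_factor = 1.3,
                        z_range = c(-0.3, 0.995)) {
  stopifnot(n_sources >= 10)
  coords <- fibonacci_sphere(n_sources, radius, z_range = z_range)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  r_adj <- adjacency_factor * stats::median(nn)
  adjacency <- lapply(seq_len(n_sources), function(i) which(d[i, ] <= r_adj))
  if (any(lengths(adjacency) == 0)) {
    stop("source grid has isolated points; increase `adjacency_factor`")
  }
  structure(
    list(coords = coords, adjacency = adjacency, r_adj = r_adj,
         region_labels = grid_regions(coords), radius = radius,
         nn_distance = nn),
    class = "source_grid"
  )
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("<source_grid> %d points on shell r = %.3f m; r_adj = %.4f m\n",
              nrow(x$coords), x$radius, x$r_adj))
  print(table(x$region_labels))
  invisible(x)
}
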