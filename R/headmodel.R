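#' Three-shell concentric spherical head model
#'
#' Geometry and conductivities of the classical brain / skull / scalp
#' concentric-sphere conductor used for the analytic EEG forward solution.
#'
#' @param radii shell radii in meters, strictly increasing
#'   (brain, skull outer, scalp outer).
#' @param conductivities shell conductivities in S/m (brain, skull, scalp).
#' @return object of class `head_model`.
#' @export
head_model <- function(radii = c(0.087, 0.092, 0.100),
                       conductivities = c(0.33, 0.0042, 0.33)) {
  stopifnot(length(radii) == 3, length(conductivities) == 3,
            all(diff(radii) > 0), all(conductivities > 0))
  structure(list(radii = radii, conductivities = conductivities),
            class = "head_model")
}

# Legendre-series coefficients d_n for the scalp potential of a unit radial
# dipole at radius b inside a 3-shell concentric sphere:
#   V(scalp, gamma) = sum_n d_n P_n(cos gamma).
# For each harmonic order the five boundary conditions (potential and radial
# current continuity at the two inner interfaces, zero current at the scalp)
# are solved as a 5x5 linear system. The radial basis functions are scaled
# per shell, (r/r_outer)^n and (r_inner/r)^(n+1), so all matrix entries stay
# O(1) up to high orders.
shell3_coefficients <- function(b, head, n_terms) {
  R <- head$radii; s <- head$conductivities
  if (b <= 0 || b >= R[1]) stop("dipole radius must lie inside the innermost shell")
  d <- numeric(n_terms)
  for (n in seq_len(n_terms)) {
    q12 <- (R[1] / R[2])^n
    q23 <- (R[2] / R[3])^n
    p12 <- (R[1] / R[2])^(n + 1)
    p23 <- (R[2] / R[3])^(n + 1)
    # primary (infinite-medium) potential of the radial dipole at r = R1
    prim <- n * (b / R[1])^(n - 1) / (4 * pi * s[1] * R[1]^2)
    # unknowns: A1, A2, B2, A3, B3 (region-scaled amplitudes)
    M <- matrix(0, 5, 5)
    rhs <- numeric(5)
    # potential continuity at R1
    M[1, ] <- c(1, -q12, -1, 0, 0); rhs[1] <- -prim
    # radial current continuity at R1 (times R1)
    M[2, ] <- c(s[1] * n, -s[2] * n * q12, s[2] * (n + 1), 0, 0)
    rhs[2] <- s[1] * (n + 1) * prim
    # potential continuity at R2
    M[3, ] <- c(0, 1, p12, -q23, -1)
    # radial current continuity at R2 (times R2)
    M[4, ] <- c(0, s[2] * n, -s[2] * (n + 1) * p12,
                -s[3] * n * q23, s[3] * (n + 1))
    # zero radial current at the scalp surface (times R3)
    M[5, ] <- c(0, 0, 0, n, -(n + 1) * p23)
    u <- solve(M, rhs)
    d[n] <- u[4] + u[5] * p23
  }
  d
}

#' Scalp potential of a radial dipole in the three-shell sphere
#'
#' Analytic (Legendre-series) electric potential on the outer surface of a
#' three-shell concentric spherical conductor, generated by a radial unit
#' dipole at radius `b`, as a function of the angle between dipole and
#' electrode position vectors.
#'
#' @param cos_gamma cosine(s) of the source-electrode angle; any numeric
#'   array shape is preserved.
#' @param b dipole eccentricity (meters), inside the innermost shell.
#' @param head a [head_model()].
#' @param n_terms number of Legendre terms; the series converges
#'   geometrically at rate `b / radii[3]`.
#' @return potential values, same shape as `cos_gamma` (V per unit
#'   dipole moment).
#' @export
dipole_potential <- function(cos_gamma, b, head = head_model(), n_terms = 150) {
  d <- shell3_coefficients(b, head, n_terms)
  x <- cos_gamma
  p_prev <- array(1, dim = dim(x) %||% length(x))   # P_0
  p_cur <- x                                        # P_1
  v <- d[1] * p_cur
  if (n_terms >= 2) {
    for (n in 1:(n_terms - 1)) {
      p_next <- ((2 * n + 1) * x * p_cur - n * p_prev) / (n + 1)
      v <- v + d[n + 1] * p_next
      p_prev <- p_cur
      p_cur <- p_next
    }
  }
  v
}

#' Build a lead field on the three-shell spherical head model
#'
#' Computes the channels x sources gain matrix for radial dipoles on a
#' quasi-uniform spherical source shell, using the analytic three-shell
#' forward solution, and projects it onto the common-average reference
#' (every source column has zero mean across channels). Gains are scaled so
#' the largest absolute entry is 1, i.e. unit source amplitude produces at
#' most 1 microvolt at the scalp; source amplitudes are therefore expressed
#' in scalp-equivalent microvolts.
#'
#' @param positions channels x 3 electrode coordinates (meters); must lie
#'   within 10 percent of the outer shell radius.
#' @param n_sources number of source-grid points.
#' @param head a [head_model()].
#' @param source_radius radius of the source shell (meters); default 90
#'   percent of the innermost (brain) radius, a gray-matter-like depth.
#' @param n_terms Legendre truncation order of the forward series.
#' @return object of class `leadfield_model`: `gain` (channels x sources),
#'   `grid` (a [source_grid()]), `head`, `channel_names`, `positions`.
#' @export
build_leadfield <- function(positions, n_sources = 387, head = head_model(),
                            source_radius = 0.9 * head$radii[1],
                            n_terms = 150) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, n_sources >= 10)
  rad <- sqrt(rowSums(positions^2))
  if (any(abs(rad - head$radii[3]) > 0.1 * head$radii[3])) {
    stop("electrode positions must lie within 10% of the outer shell radius")
  }
  grid <- source_grid(n_sources, radius = source_radius)
  eu <- positions / rad                      # electrode unit vectors
  su <- grid$coords / source_radius          # source unit vectors
  cos_gamma <- pmin(pmax(eu %*% t(su), -1), 1)
  gain <- dipole_potential(cos_gamma, b = source_radius, head = head,
                           n_terms = n_terms)
  gain <- sweep(gain, 2, colMeans(gain))     # common-average reference
  gain <- gain / max(abs(gain))
  if (any(colSums(abs(gain)) == 0)) stop("lead field has an all-zero column")
  rownames(gain) <- rownames(positions)
  structure(
    list(gain = gain, grid = grid, head = head,
         channel_names = rownames(positions), positions = positions),
    class = "leadfield_model"
  )
}

#' @export
print.leadfield_model <- function(x, ...) {
  cat(sprintf("<leadfield_model> %d channels x %d sources; shells %s m\n",
              nrow(x$gain), ncol(x$gain),
              paste(x$head$radii, collapse = "/")))
  invisible(x)
}
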