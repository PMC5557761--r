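#' LORETA-style linear inverse operator
#'
#' Builds the sources x channels inverse matrix
#' `T = M K' (K M K' + alpha H)^+`, where `K` is the lead-field gain, `H`
#' the common-average projector, and `M` the inverse of the source-space
#' penalty. For `method = "loreta"` the penalty is the squared discrete
#' graph Laplacian of the source grid composed with gain-column-norm
#' weighting (favoring spatially smooth, depth-compensated solutions); for
#' `method = "mnorm"` the Laplacian is replaced by the identity, giving a
#' weighted minimum-norm operator. The Laplacian uses the row-normalized
#' (neighbor-averaging) convention `I - D^-1 A`, which behaves consistently
#' at the boundary of a cap grid, ridge-shifted by a small identity multiple
#' so the penalty is invertible.
#'
#' @param leadfield a [build_leadfield()] result.
#' @param alpha Tikhonov regularization; `NULL` (default) uses
#'   `0.05 * mean eigenvalue of K M K'`.
#' @param method "loreta" or "mnorm".
#' @param laplacian_ridge identity shift added to the row-normalized graph
#'   Laplacian before squaring.
#' @return object of class `inverse_operator` with `T` (sources x channels),
#'   `alpha`, `method`, and the source grid.
#' @export
loreta_inverse <- function(leadfield, alpha = NULL,
                           method = c("loreta", "mnorm"),
                           laplacian_ridge = 0.3) {
  stopifnot(inherits(leadfield, "leadfield_model"))
  method <- match.arg(method)
  K <- leadfield$gain
  n_ch <- nrow(K); n_src <- ncol(K)
  w <- sqrt(colSums(K^2))                      # column-norm (depth) weights
  if (method == "loreta") {
    adj <- leadfield$grid$adjacency
    Lap <- diag(1 + laplacian_ridge, n_src)
    for (i in seq_len(n_src)) {
      Lap[i, adj[[i]]] <- Lap[i, adj[[i]]] - 1 / length(adj[[i]])
    }
    P <- crossprod(Lap)                         # squared smoothness penalty
  } else {
    P <- diag(n_src)
  }
  # M = (W P W)^{-1} = W^{-1} P^{-1} W^{-1} with diagonal W
  Pinv <- solve(P)
  M <- t(Pinv / w) / w
  G <- K %*% M %*% t(K)
  if (is.null(alpha)) alpha <- 0.05 * mean(diag(G))
  stopifnot_scalar(alpha, "alpha", lower = 0)
  H <- diag(n_ch) - matrix(1 / n_ch, n_ch, n_ch)
  Tmat <- M %*% t(K) %*% pinv(G + alpha * H)
  structure(
    list(T = Tmat, alpha = alpha, method = method, grid = leadfield$grid,
         channel_names = leadfield$channel_names),
    class = "inverse_operator"
  )
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("<inverse_operator> %s: %d sources x %d channels, alpha = %.4g\n",
              x$method, nrow(x$T), ncol(x$T), x$alpha))
  invisible(x)
}

#' Source-space amplitude-spectrum tensor
#'
#' Maps sensor cross-spectra to source space, `CSDj = T CSDphi T'`, and
#' takes the square root of the diagonal for every frequency and window.
#' Because each sensor CSD slice is the rank-one product `c phi phi*`, the
#' diagonal of the congruence is computed as `c |T phi|^2` without forming
#' any sources x sources matrix; the result is exact and non-negative.
#'
#' @param inverse an [loreta_inverse()] operator.
#' @param csd a `csd_set` from [cross_spectral_density()].
#' @return object of class `spectral_tensor` (`space_kind = "source"`),
#'   sources x frequencies x windows.
#' @export
source_amplitude_spectrum <- function(inverse, csd) {
  stopifnot(inherits(inverse, "inverse_operator"), inherits(csd, "csd_set"))
  if (ncol(inverse$T) != dim(csd$phi)[1]) {
    stop("channel counts of inverse operator and cross-spectra disagree")
  }
  d <- dim(csd$phi)
  n_src <- nrow(inverse$T)
  values <- array(0, dim = c(n_src, d[2], d[3]))
  scale <- sqrt(csd$normalization)
  for (t in seq_len(d[3])) {
    values[, , t] <- scale * Mod(inverse$T %*% csd$phi[, , t])
  }
  new_spectral_tensor(values, "source", csd$freqs, csd$window_centers,
                      csd$window_segment)
}
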