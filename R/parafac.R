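# --- tensor utilities -------------------------------------------------------

# Column-wise Khatri-Rao product; row block order has V's index fastest,
# matching R's column-major unfoldings below.
khatri_rao <- function(U, V) {
  K <- ncol(U)
  U[rep(seq_len(nrow(U)), each = nrow(V)), , drop = FALSE] *
    V[rep(seq_len(nrow(V)), nrow(U)), , drop = FALSE]
}

# Mode-n unfoldings of a 3-way array X (n1 x n2 x n3), arranged so that
# X1 ~ A kr(C,B)', X2 ~ B kr(C,A)', X3 ~ C kr(B,A)'.
unfold1 <- function(X) { d <- dim(X); dim(X) <- c(d[1], d[2] * d[3]); X }
unfold2 <- function(X) { d <- dim(X); Y <- aperm(X, c(2, 1, 3)); dim(Y) <- c(d[2], d[1] * d[3]); Y }
unfold3 <- function(X) { d <- dim(X); Y <- aperm(X, c(3, 1, 2)); dim(Y) <- c(d[3], d[1] * d[2]); Y }

# Extract the (frequency x space x time)-ordered data array from a
# spectral_tensor (stored space x frequency x time) or a plain array.
parafac_data_array <- function(tensor) {
  if (inherits(tensor, "spectral_tensor")) {
    aperm(tensor$values, c(2, 1, 3))
  } else if (is.array(tensor) && length(dim(tensor)) == 3) {
    aperm(tensor, c(2, 1, 3))
  } else {
    stop("`tensor` must be a spectral_tensor or a 3-way array (space x frequency x time)")
  }
}

random_loading <- function(n, K) matrix(runif(n * K, 0.1, 1), n, K)

# --- ALS fitting ------------------------------------------------------------

# One ALS pass over the free modes. `mats` is list(A, B, C) in
# (frequency, space, time) order; `free` a logical vector per mode.
# Each update solves the exactly-optimal non-negativity-constrained
# least-squares problem for that mode given the other two, so the fit is
# non-decreasing over sweeps.
als_sweep <- function(unf, mats, free, gram) {
  for (m in which(free)) {
    others <- setdiff(1:3, m)
    hi <- max(others); lo <- min(others)
    Z_gram <- gram[[hi]] * gram[[lo]]
    F <- unf[[m]] %*% khatri_rao(mats[[hi]], mats[[lo]])
    upd <- nnls_gram_rows(Z_gram, F)
    # guard against collapsed (all-zero) columns
    zero <- colSums(upd) <= 0
    if (any(zero)) upd[, zero] <- matrix(runif(sum(zero) * nrow(upd), 0, 1e-6),
                                         nrow(upd))
    mats[[m]] <- upd
    gram[[m]] <- crossprod(upd)
  }
  # keep the variance in the first (frequency) mode while fitting: rescale
  # free non-first modes to unit Euclidean norm, pushing scale into mode 1
  if (free[1]) {
    for (m in 2:3) {
      if (!free[m]) next
      nrm <- sqrt(colSums(mats[[m]]^2))
      nrm[nrm == 0] <- 1
      mats[[m]] <- sweep(mats[[m]], 2, nrm, "/")
      mats[[1]] <- sweep(mats[[1]], 2, nrm, "*")
      gram[[m]] <- crossprod(mats[[m]])
    }
    gram[[1]] <- crossprod(mats[[1]])
  }
  list(mats = mats, gram = gram)
}

als_fit_value <- function(unf1, mats, gram, ssq_x) {
  # ||Xhat||^2 and <X, Xhat> from Gram matrices / unfolding products
  ip_hat <- sum(gram[[1]] * gram[[2]] * gram[[3]])
  ip_xh <- sum(mats[[1]] * (unf1 %*% khatri_rao(mats[[3]], mats[[2]])))
  ssr <- max(0, ssq_x - 2 * ip_xh + ip_hat)
  1 - ssr / ssq_x
}

run_als <- function(unf, mats, free, ssq_x, tol, max_iter) {
  gram <- lapply(mats, crossprod)
  fit_trace <- numeric(0)
  fit <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sw <- als_sweep(unf, mats, free, gram)
    mats <- sw$mats; gram <- sw$gram
    new_fit <- als_fit_value(unf[[1]], mats, gram, ssq_x)
    fit_trace <- c(fit_trace, new_fit)
    if (is.finite(fit) && abs(new_fit - fit) < tol * max(abs(fit), 1e-12)) {
      fit <- new_fit; converged <- TRUE; break
    }
    fit <- new_fit
  }
  list(mats = mats, fit = fit, fit_trace = fit_trace,
       n_iterations = length(fit_trace), converged = converged)
}

#' Non-negative 3-way PARAFAC by alternating least squares
#'
#' Decomposes a non-negative space x frequency x time amplitude-spectrum
#' tensor into `K` trilinear components
#' `X[s,f,t] = sum_k a[f,k] b[s,k] c[t,k] + eps` with non-negative loadings,
#' fitted by alternating least squares: each sweep solves, for every free
#' mode in turn, the exact non-negativity-constrained least-squares problem
#' given the other two modes, so the explained variation is non-decreasing.
#' Modes listed in `fixed` are never updated and are returned bit-identical
#' to their inputs. Multi-start initialization guards against local minima:
#' `n_starts` random non-negative starts are each run for `start_sweeps`
#' sweeps and the best is refined to convergence.
#'
#' While fitting, the free second (space) and third (time) modes are
#' rescaled to unit norm each sweep so the data variance accumulates in the
#' first (frequency) mode; after fitting, free non-first modes are rescaled
#' to unit maximum per column, the first mode carrying the magnitude, and
#' components are ordered by decreasing first-mode magnitude.
#'
#' @param tensor a `spectral_tensor` or plain non-negative 3-way array
#'   (space x frequency x time).
#' @param K number of components (>= 1).
#' @param fixed optional named list of fixed loading matrices, names among
#'   "frequency", "space", "time"; matrices must be non-negative with `K`
#'   columns and the matching mode length.
#' @param n_starts number of random multi-start initializations.
#' @param tol convergence tolerance on the relative change of explained
#'   variation between sweeps.
#' @param max_iter maximum ALS sweeps.
#' @param start_sweeps sweeps run per candidate start before the best
#'   candidate is refined.
#' @param seed optional seed for the random starts (caller RNG untouched).
#' @return object of class `parafac_model`: loading matrices `A` (frequency,
#'   N_f x K), `B` (space), `C` (time), `K`, `fit` (explained variation in
#'   [0,1]), `fixed_modes`, `residual_norm`, convergence diagnostics
#'   (`n_iterations`, `converged`, `fit_trace`), and a `degenerate` flag
#'   (a pair of components with overall congruence > 0.98).
#' @export
parafac_als <- function(tensor, K, fixed = NULL, n_starts = 10, tol = 1e-8,
                        max_iter = 2000, start_sweeps = 30, seed = NULL) {
  X <- parafac_data_array(tensor)
  if (min(X) < 0) stop("tensor must be non-negative")
  stopifnot(K >= 1, n_starts >= 1, max_iter >= 1, tol > 0)
  d <- dim(X)                     # (n_freq, n_space, n_time)
  mode_names <- c("frequency", "space", "time")
  free <- c(TRUE, TRUE, TRUE)
  init_fixed <- vector("list", 3)
  if (!is.null(fixed)) {
    if (!all(names(fixed) %in% mode_names)) {
      stop("`fixed` names must be among 'frequency', 'space', 'time'")
    }
    for (m in seq_along(mode_names)) {
      fm <- fixed[[mode_names[m]]]
      if (is.null(fm)) next
      fm <- as.matrix(fm)
      if (nrow(fm) != d[m] || ncol(fm) != K || min(fm) < 0) {
        stop(sprintf("fixed '%s' loadings must be a non-negative %d x %d matrix",
                     mode_names[m], d[m], K))
      }
      init_fixed[[m]] <- fm
      free[m] <- FALSE
    }
    if (!any(free)) stop("at least one mode must be free")
  }
  unf <- list(unfold1(X), unfold2(X), unfold3(X))
  ssq_x <- sum(X^2)
  if (ssq_x == 0) stop("tensor is identically zero")

  fit_one <- function() {
    starts <- lapply(seq_len(n_starts), function(i) {
      mats <- list(random_loading(d[1], K), random_loading(d[2], K),
                   random_loading(d[3], K))
      for (m in 1:3) if (!free[m]) mats[[m]] <- init_fixed[[m]]
      run_als(unf, mats, free, ssq_x, tol, min(start_sweeps, max_iter))
    })
    best <- starts[[which.max(vapply(starts, `[[`, 0, "fit"))]]
    run_als(unf, best$mats, free, ssq_x, tol, max_iter)
  }
  res <- with_seed(seed, fit_one())
  mats <- res$mats

  # post-fit normalization: free non-first modes to unit maximum per column,
  # magnitude carried by the first free mode in (frequency, space, time) order
  carrier <- which(free)[1]
  for (m in setdiff(which(free), carrier)) {
    mx <- apply(mats[[m]], 2, max)
    mx[mx == 0] <- 1
    mats[[m]] <- sweep(mats[[m]], 2, mx, "/")
    mats[[carrier]] <- sweep(mats[[carrier]], 2, mx, "*")
  }
  # deterministic component order by decreasing carrier-mode magnitude;
  # with any mode fixed, the input column order is preserved so fixed
  # loadings stay aligned with their source
  if (all(free) && K > 1) {
    ord <- order(colSums(mats[[carrier]]^2), decreasing = TRUE)
    mats <- lapply(mats, function(m) m[, ord, drop = FALSE])
  }

  congr <- function(M) {
    nrm <- sqrt(colSums(M^2)); nrm[nrm == 0] <- 1
    crossprod(sweep(M, 2, nrm, "/"))
  }
  degenerate <- FALSE
  if (K > 1) {
    cc <- congr(mats[[1]]) * congr(mats[[2]]) * congr(mats[[3]])
    degenerate <- max(cc[upper.tri(cc)]) > 0.98
  }
  structure(
    list(K = K, A = mats[[1]], B = mats[[2]], C = mats[[3]],
         fixed_modes = mode_names[!free], fit = res$fit,
         residual_norm = sqrt(max(0, (1 - res$fit) * ssq_x)),
         n_iterations = res$n_iterations, converged = res$converged,
         fit_trace = res$fit_trace, degenerate = degenerate,
         corcondia = NA_real_, dims = d),
    class = "parafac_model"
  )
}

#' @export
print.parafac_model <- function(x, ...) {
  cat(sprintf("<parafac_model> K = %d; fit = %.4f; corcondia = %s; %s%d sweeps\n",
              x$K, x$fit,
              if (is.na(x$corcondia)) "NA" else sprintf("%.1f%%", x$corcondia),
              if (x$converged) "converged in " else "NOT converged at ",
              x$n_iterations))
  if (length(x$fixed_modes)) {
    cat("  fixed modes:", paste(x$fixed_modes, collapse = ", "), "\n")
  }
  invisible(x)
}

# Reconstruct the model tensor in (frequency, space, time) order.
parafac_reconstruct <- function(model) {
  d <- model$dims
  Xh <- model$A %*% t(khatri_rao(model$C, model$B))
  dim(Xh) <- d
  Xh
}

# mode-n product of a 3-way array with a matrix (rows replace mode n)
ttm <- function(X, M, mode) {
  d <- dim(X)
  perm <- switch(mode, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  Y <- aperm(X, perm)
  dy <- dim(Y)
  dim(Y) <- c(dy[1], dy[2] * dy[3])
  Z <- M %*% Y
  dim(Z) <- c(nrow(M), dy[2], dy[3])
  aperm(Z, order(perm))
}

#' Core consistency diagnostic (CORCONDIA)
#'
#' Measures how well a fitted PARAFAC model's loadings explain the tensor
#' through a superdiagonal core. The least-squares Tucker core `G` for the
#' model's loadings is computed by mode-wise pseudo-inverse products and
#' compared with the K x K x K superidentity `T` (ones on the
#' superdiagonal): `100 * (1 - sum((g - t)^2) / sum(t^2))`. The value is
#' 100 exactly when the core is superdiagonal, near 100 for an appropriate
#' model, and near or below 0 for an invalid (over-factored) one. For
#' `K = 1` the single-element core is scale-normalized, so the diagnostic
#' is 100 by construction.
#'
#' @param tensor the tensor the model was fitted to (`spectral_tensor` or
#'   3-way array, space x frequency x time).
#' @param model a [parafac_als()] model of matching shape.
#' @return core consistency in percent (may be negative).
#' @export
corcondia <- function(tensor, model) {
  stopifnot(inherits(model, "parafac_model"))
  X <- parafac_data_array(tensor)
  if (!all(dim(X) == model$dims)) stop("tensor shape does not match the model")
  K <- model$K
  if (K == 1) return(100)
  G <- ttm(ttm(ttm(X, pinv(model$A), 1), pinv(model$B), 2), pinv(model$C), 3)
  Tsup <- array(0, dim = c(K, K, K))
  for (k in seq_len(K)) Tsup[k, k, k] <- 1
  100 * (1 - sum((G - Tsup)^2) / K)
}

#' Select the number of PARAFAC components with CORCONDIA
#'
#' Fits models with `K = 1 ... K_max` and returns the largest `K` whose
#' core consistency is at or above `threshold` (the validity rule used for
#' alpha-component model order selection, default threshold 90 percent).
#' If no `K` passes, `K = 1` is returned with a warning flag.
#'
#' @param tensor non-negative `spectral_tensor` or 3-way array.
#' @param K_max largest model order to try.
#' @param threshold core-consistency validity threshold in percent.
#' @param seed optional seed; start `s` of order `K` is seeded
#'   deterministically from it.
#' @inheritParams parafac_als
#' @return list with `K` (selected order), `diagnostics` (per-K data.frame
#'   of fit, core consistency, convergence, degeneracy), `models` (per-K
#'   fitted models), and `none_valid` flag.
#' @export
select_num_components <- function(tensor, K_max = 6, threshold = 90,
                                  n_starts = 10, tol = 1e-8, max_iter = 2000,
                                  start_sweeps = 30, seed = NULL) {
  stopifnot(K_max >= 1)
  models <- vector("list", K_max)
  cc <- fit <- numeric(K_max)
  for (K in seq_len(K_max)) {
    sK <- if (is.null(seed)) NULL else seed + 1000L * K
    models[[K]] <- parafac_als(tensor, K, n_starts = n_starts, tol = tol,
                               max_iter = max_iter,
                               start_sweeps = start_sweeps, seed = sK)
    cc[K] <- corcondia(tensor, models[[K]])
    models[[K]]$corcondia <- cc[K]
    fit[K] <- models[[K]]$fit
  }
  valid <- which(cc >= threshold)
  none_valid <- length(valid) == 0
  K_sel <- if (none_valid) 1L else max(valid)
  if (none_valid) {
    warning("no model order reached the core-consistency threshold; returning K = 1")
  }
  list(
    K = K_sel,
    diagnostics = data.frame(
      K = seq_len(K_max), fit = fit, corcondia = cc,
      converged = vapply(models, `[[`, TRUE, "converged"),
      degenerate = vapply(models, `[[`, TRUE, "degenerate")),
    models = models,
    none_valid = none_valid
  )
}
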