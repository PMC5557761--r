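# Independent oracles, deliberately written as direct/brute-force
# computations that share no code with the implementation paths they check.

# Naive per-window tapered DFT (triple loop over channel, window, frequency).
naive_stft <- function(recording, window_seconds, overlap, band) {
  fs <- recording$sampling_rate
  L <- as.integer(round(fs * window_seconds))
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L))
  hop <- as.integer(round(L * (1 - overlap)))
  freqs <- (0:(L - 1)) * fs / L
  keep <- which(freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9)
  spans <- arcomp:::segment_spans(recording)
  starts <- unlist(lapply(seq_len(nrow(spans)), function(s) {
    if (spans[s, 2] - spans[s, 1] + 1 < L) return(integer(0))
    seq.int(spans[s, 1], spans[s, 2] - L + 1L, by = hop)
  }))
  out <- array(0i, c(nrow(recording$data), length(keep), length(starts)))
  for (m in seq_len(nrow(recording$data))) {
    for (t in seq_along(starts)) {
      x <- recording$data[m, starts[t]:(starts[t] + L - 1L)] * w
      for (fi in seq_along(keep)) {
        k <- keep[fi] - 1L
        out[m, fi, t] <- sum(x * exp(-2i * pi * k * (0:(L - 1)) / L)) / L
      }
    }
  }
  list(values = out, freqs = freqs[keep], starts = starts)
}

# Least-squares Tucker core by an explicit dense normal-equations solve.
dense_core <- function(X, A, B, C) {
  Z <- kronecker(C, kronecker(B, A))
  g <- solve(crossprod(Z), crossprod(Z, as.vector(X)))
  array(g, dim = c(ncol(A), ncol(B), ncol(C)))
}

dense_corcondia <- function(tensor, model) {
  X <- arcomp:::parafac_data_array(tensor)
  K <- model$K
  G <- dense_core(X, model$A, model$B, model$C)
  Tsup <- array(0, c(K, K, K))
  for (k in seq_len(K)) Tsup[k, k, k] <- 1
  100 * (1 - sum((G - Tsup)^2) / K)
}

# Connected components of a vertex subset via igraph (independent of the
# package's breadth-first search).
igraph_clusters <- function(members, adjacency) {
  if (length(members) == 0) return(list())
  edges <- do.call(rbind, lapply(members, function(i) {
    nb <- intersect(adjacency[[i]], members)
    if (length(nb)) cbind(i, nb) else NULL
  }))
  g <- igraph::graph_from_data_frame(
    d = if (is.null(edges)) data.frame(from = integer(0), to = integer(0))
        else data.frame(from = as.character(edges[, 1]),
                        to = as.character(edges[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(members)))
  comp <- igraph::components(g)
  unname(lapply(split(as.integer(names(comp$membership)), comp$membership),
                sort))
}

# exhaustive greedy matching helper for loading columns
tcc_matrix <- function(U, V) {
  outer(seq_len(ncol(U)), seq_len(ncol(V)),
        Vectorize(function(i, j) tucker_congruence(U[, i], V[, j])))
}
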