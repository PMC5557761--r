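#' Tucker congruence coefficient
#'
#' Cosine-type similarity between two loading vectors,
#' `sum(x y) / sqrt(sum(x^2) sum(y^2))`; for non-negative loadings it lies
#' in [0, 1]. Values above 0.85 indicate highly similar loadings; above
#' 0.95, nearly identical ones. Symmetric and invariant to positive
#' rescaling of either argument.
#'
#' @param x,y numeric loading vectors of equal length; neither all-zero.
#' @return scalar congruence coefficient.
#' @export
tucker_congruence <- function(x, y) {
  if (length(x) != length(y)) stop("loading vectors must have equal length")
  sx <- sum(x^2); sy <- sum(y^2)
  if (sx == 0 || sy == 0) stop("Tucker congruence is undefined for a zero vector")
  sum(x * y) / sqrt(sx * sy)
}

#' Match estimated components to reference components by congruence
#'
#' Greedy assignment: repeatedly pairs the reference/estimate columns with
#' the highest Tucker congruence among the unassigned ones. Resolves the
#' permutation indeterminacy of PARAFAC solutions.
#'
#' @param reference,estimate matrices with one loading column per component.
#' @return integer vector: for each reference column, the index of the
#'   matched estimate column.
#' @export
match_components <- function(reference, estimate) {
  reference <- as.matrix(reference); estimate <- as.matrix(estimate)
  stopifnot(nrow(reference) == nrow(estimate),
            ncol(estimate) >= ncol(reference))
  tcc <- outer(seq_len(ncol(reference)), seq_len(ncol(estimate)),
               Vectorize(function(i, j) tucker_congruence(reference[, i],
                                                          estimate[, j])))
  match <- integer(ncol(reference))
  for (step in seq_len(ncol(reference))) {
    best <- which(tcc == max(tcc), arr.ind = TRUE)[1, ]
    match[best[1]] <- best[2]
    tcc[best[1], ] <- -Inf
    tcc[, best[2]] <- -Inf
  }
  match
}

# Connected components of a vertex subset under the grid adjacency
# (breadth-first search). Returns a list of integer index sets.
find_clusters <- function(members, adjacency) {
  members <- sort(members)
  in_set <- logical(length(adjacency))
  in_set[members] <- TRUE
  seen <- logical(length(adjacency))
  clusters <- list()
  for (v in members) {
    if (seen[v]) next
    queue <- v; seen[v] <- TRUE; comp <- integer(0)
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, u)
      nb <- adjacency[[u]]
      nb <- nb[in_set[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    clusters[[length(clusters) + 1L]] <- sort(comp)
  }
  clusters
}

# one-sided paired t statistics per source from a subjects x sources
# difference matrix; returns the t map (0/0 treated as 0)
paired_t_map <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  s <- sqrt((colSums(D^2) - n * m^2) / (n - 1))
  t <- m / (s / sqrt(n))
  t[!is.finite(t)] <- 0
  t
}

max_cluster_stat <- function(t_map, threshold, adjacency) {
  above <- which(t_map > threshold)
  if (length(above) == 0) return(0)
  max(vapply(find_clusters(above, adjacency),
             function(cl) sum(t_map[cl]), 0))
}

#' Cluster-based permutation test of paired source-loading contrasts
#'
#' Tests, in both directions, where one component's normalized spatial
#' loadings exceed the other's across subjects. Per source a one-sided
#' paired t statistic is computed; sources with t above the given
#' percentile of the t distribution (n - 1 df) form spatially connected
#' clusters under the grid adjacency, each scored by the sum of its member
#' t values. The null distribution is the maximum cluster score over random
#' within-subject swaps of the two component labels (sign flips of the
#' paired differences); the permutation p-value of each observed cluster is
#' the fraction of null maxima strictly greater than its score (floored at
#' `1/n_perm`; set `plus_one = TRUE` for the add-one-permutation
#' correction).
#'
#' @param loadA,loadB subjects x sources loading matrices (one row per
#'   subject); rows are max-normalized internally.
#' @param grid a [source_grid()] providing the adjacency.
#' @param n_perm number of random permutations.
#' @param pct cluster-forming percentile of the t distribution.
#' @param seed seed for the permutation draws.
#' @param plus_one if TRUE, use (count + 1) / (n_perm + 1).
#' @param labels length-2 contrast labels, e.g. c("ARC1", "ARC2").
#' @return object of class `cluster_test_result`: per direction the t map,
#'   clusters (index sets), summed-t cluster statistics, and permutation
#'   p-values; plus the threshold, `n_perm`, and seed.
#' @export
cluster_permutation_test <- function(loadA, loadB, grid, n_perm = 5000,
                                     pct = 99, seed = 1, plus_one = FALSE,
                                     labels = c("ARC1", "ARC2")) {
  loadA <- as.matrix(loadA); loadB <- as.matrix(loadB)
  stopifnot(all(dim(loadA) == dim(loadB)),
            ncol(loadA) == nrow(grid$coords))
  n <- nrow(loadA)
  if (n < 3) stop("need at least 3 subjects")
  norm_rows <- function(M) t(apply(M, 1, max_normalize))
  D <- norm_rows(loadA) - norm_rows(loadB)
  threshold <- stats::qt(pct / 100, df = n - 1)
  t_obs <- paired_t_map(D)

  # sign-flip null: per permutation the t map only needs flipped means,
  # since sum(D^2) per source is flip-invariant
  colsq <- colSums(D^2)
  null_max <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    Mp <- (S %*% D) / n
    Sp <- sqrt(sweep(-n * Mp^2, 2, colsq, "+") / (n - 1))
    Tp <- Mp / (Sp / sqrt(n))
    Tp[!is.finite(Tp)] <- 0
    cbind(pos = vapply(seq_len(n_perm), function(i) {
            max_cluster_stat(Tp[i, ], threshold, grid$adjacency)
          }, 0),
          neg = vapply(seq_len(n_perm), function(i) {
            max_cluster_stat(-Tp[i, ], threshold, grid$adjacency)
          }, 0))
  })

  direction <- function(t_map, null) {
    above <- which(t_map > threshold)
    clusters <- if (length(above)) find_clusters(above, grid$adjacency) else list()
    stats <- vapply(clusters, function(cl) sum(t_map[cl]), 0)
    p <- vapply(stats, function(s) {
      cnt <- sum(null > s)
      if (plus_one) (cnt + 1) / (n_perm + 1) else max(cnt, 1) / n_perm
    }, 0)
    ord <- order(stats, decreasing = TRUE)
    list(t_map = t_map, clusters = clusters[ord],
         cluster_stats = stats[ord], p_values = p[ord])
  }
  res <- list(direction(t_obs, null_max[, "pos"]),
              direction(-t_obs, null_max[, "neg"]))
  names(res) <- c(paste0(labels[1], ">", labels[2]),
                  paste0(labels[2], ">", labels[1]))
  structure(
    list(contrasts = res, cluster_forming_threshold = threshold,
         n_permutations = n_perm, seed = seed, n_subjects = n),
    class = "cluster_test_result"
  )
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat(sprintf("<cluster_test_result> n = %d subjects, %d permutations, t threshold %.3f\n",
              x$n_subjects, x$n_permutations, x$cluster_forming_threshold))
  for (nm in names(x$contrasts)) {
    co <- x$contrasts[[nm]]
    if (length(co$clusters) == 0) {
      cat(sprintf("  %s: no suprathreshold cluster\n", nm))
    } else {
      cat(sprintf("  %s: %d cluster(s); top: %d sources, sum t = %.2f, p = %.4f\n",
                  nm, length(co$clusters), length(co$clusters[[1]]),
                  co$cluster_stats[1], co$p_values[1]))
    }
  }
  invisible(x)
}

#' Per-period temporal-loading means and repeated-measures stability test
#'
#' For each subject's decomposition, the max-normalized temporal loading of
#' a component is averaged within each concatenated REC period; across
#' subjects a one-way repeated-measures ANOVA (period as the within-subject
#' factor) tests whether the component's expression differs between
#' periods. The F statistic is the between-period mean square over the
#' subject-by-period residual mean square.
#'
#' @param period_means subjects x periods matrix of per-period mean
#'   normalized temporal loadings (see [rec_period_means()]); or a list of
#'   per-subject vectors.
#' @return list: `period_means` (the input matrix), `grand_means` (per
#'   period), `F`, `df`, `p_value`.
#' @export
rec_period_stability <- function(period_means) {
  if (is.list(period_means) && !is.matrix(period_means)) {
    period_means <- do.call(rbind, period_means)
  }
  X <- as.matrix(period_means)
  s <- nrow(X); p <- ncol(X)
  if (p < 2) stop("need at least 2 periods")
  if (s < 2) stop("need at least 2 subjects for the repeated-measures test")
  grand <- mean(X)
  ss_period <- s * sum((colMeans(X) - grand)^2)
  ss_subject <- p * sum((rowMeans(X) - grand)^2)
  ss_total <- sum((X - grand)^2)
  ss_err <- max(0, ss_total - ss_period - ss_subject)
  df1 <- p - 1; df2 <- (p - 1) * (s - 1)
  if (ss_period <= 1e-15 * max(ss_total, 1)) {
    F <- 0; pv <- 1
  } else {
    F <- (ss_period / df1) / (ss_err / df2)
    pv <- stats::pf(F, df1, df2, lower.tail = FALSE)
  }
  list(period_means = X, grand_means = colMeans(X),
       F = F, df = c(df1, df2), p_value = pv)
}

#' Per-REC-period means of a component's temporal loading
#'
#' @param temporal_loading non-negative temporal loading vector (one value
#'   per STFT window).
#' @param window_segment integer segment (REC period) index per window.
#' @return named vector of per-period means of the max-normalized loading.
#' @export
rec_period_means <- function(temporal_loading, window_segment) {
  stopifnot(length(temporal_loading) == length(window_segment))
  periods <- sort(unique(window_segment))
  if (length(periods) < 2) stop("need at least 2 periods")
  cnt <- table(factor(window_segment, levels = periods))
  if (any(cnt == 0)) stop("a period contains zero windows")
  x <- max_normalize(temporal_loading)
  vapply(periods, function(s) mean(x[window_segment == s]),
         0, USE.NAMES = FALSE) |>
    stats::setNames(paste0("REC", periods))
}

#' Replicability of two decompositions via Tucker congruence
#'
#' Matches the labeled components of two decompositions of the same subject
#' (e.g. two recording sessions) and reports the Tucker congruence of their
#' frequency, sensor-space, and source-space loadings, with verdicts at the
#' 0.85 ("highly similar") and 0.95 ("nearly identical") thresholds.
#'
#' @param dec1,dec2 `arc_decomposition` objects from [decompose_subject()].
#' @return data.frame with one row per matched component and mode.
#' @export
replicability_report <- function(dec1, dec2) {
  stopifnot(inherits(dec1, "arc_decomposition"),
            inherits(dec2, "arc_decomposition"))
  f1 <- sapply(dec1$components, `[[`, "frequency_loading")
  f2 <- sapply(dec2$components, `[[`, "frequency_loading")
  m <- match_components(f1, f2)
  rows <- list()
  for (i in seq_along(dec1$components)) {
    c1 <- dec1$components[[i]]; c2 <- dec2$components[[m[i]]]
    for (mode in c("frequency", "sensor", "source")) {
      fld <- paste0(switch(mode, frequency = "frequency",
                           sensor = "sensor", source = "source"), "_loading")
      tcc <- tucker_congruence(c1[[fld]], c2[[fld]])
      rows[[length(rows) + 1L]] <- data.frame(
        component = c1$label, matched = c2$label, mode = mode, tcc = tcc,
        highly_similar = tcc > 0.85, nearly_identical = tcc > 0.95)
    }
  }
  do.call(rbind, rows)
}
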