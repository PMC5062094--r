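# ---- shared cluster-statistic machinery ------------------------------------

# t statistic of a Pearson correlation; |r| -> 1 capped to +/- 1e6
t_from_r <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  t[!is.finite(t)] <- sign(r[!is.finite(t)]) * 1e6
  t
}

# maximal runs of contiguous supra-threshold samples of one sign;
# NA values are sub-threshold and break adjacency
find_clusters <- function(tvals, thr) {
  out <- list()
  for (sgn in c(1, -1)) {
    m <- !is.na(tvals) & sgn * tvals > thr
    if (!any(m)) next
    d <- diff(c(FALSE, m, FALSE))
    starts <- which(d == 1); ends <- which(d == -1) - 1
    for (k in seq_along(starts)) {
      idx <- starts[k]:ends[k]
      out[[length(out) + 1]] <- data.frame(
        start_idx = starts[k], end_idx = ends[k],
        sum_t = sum(tvals[idx]), sign = sgn)
    }
  }
  if (!length(out)) {
    return(data.frame(start_idx = integer(0), end_idx = integer(0),
                      sum_t = numeric(0), sign = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start_idx), , drop = FALSE]
}

# per-column max positive and min negative cluster sums of a
# samples x permutations t matrix; 0 where a column has no cluster
# (the standard convention for permutation null distributions)
cluster_extremes_mat <- function(tm, thr) {
  nc <- ncol(tm)
  mx <- numeric(nc); mn <- numeric(nc)
  for (j in seq_len(nc)) {
    v <- tm[, j]
    v[is.na(v)] <- 0
    for (sgn in c(1, -1)) {
      m <- sgn * v > thr
      if (!any(m)) next
      d <- diff(c(FALSE, m, FALSE))
      starts <- which(d == 1); ends <- which(d == -1) - 1
      cs <- cumsum(v * m)
      sums <- cs[ends] - c(0, cs)[starts]
      if (sgn > 0) mx[j] <- max(sums) else mn[j] <- min(sums)
    }
  }
  list(max = mx, min = mn)
}

# Monte Carlo p for one observed cluster against its own-sign extreme
# distribution; ties count as "at least as extreme" (conservative), with
# a relative tolerance so that a permutation reproducing the observed
# statistic (e.g. the identity) ties despite floating-point noise
mc_p <- function(sum_t, sgn, null_max, null_min,
                 estimator = c("plus1", "proportion")) {
  estimator <- match.arg(estimator)
  tol <- 1e-8 * (1 + abs(sum_t))
  hits <- if (sgn > 0) sum(null_max >= sum_t - tol)
  else sum(null_min <= sum_t + tol)
  n <- length(null_max)
  if (estimator == "plus1") (hits + 1) / (n + 1) else hits / n
}

new_cluster_result <- function(clusters, time_ms, window, cluster_alpha,
                               n_perm, seed, n_trials, null_max, null_min,
                               estimator, kind) {
  status <- if (nrow(clusters)) "ok" else "no candidate clusters"
  structure(list(clusters = clusters, time_ms = time_ms, window = window,
                 cluster_alpha = cluster_alpha, n_perm = n_perm,
                 seed = seed, n = n_trials, null_max = null_max,
                 null_min = null_min, estimator = estimator, kind = kind,
                 status = status),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s, window %g..%g ms, %d permutation(s), n = %d\n",
              x$kind, x$window[1], x$window[2], x$n_perm, x$n))
  if (x$status != "ok") {
    cat(" ", x$status, "\n")
  } else {
    df <- x$clusters
    for (i in seq_len(nrow(df))) {
      cat(sprintf("  %s cluster %g..%g ms: sum(t) = %.1f, Monte Carlo p = %.4g, corrected p = %.4g\n",
                  if (df$sign[i] > 0) "positive" else "negative",
                  df$start_ms[i], df$end_ms[i], df$sum_t[i], df$p_mc[i],
                  df$p_corrected[i]))
    }
  }
  cat("  note: each cluster is tested against its own-sign extreme distribution (per-tail test)\n")
  invisible(x)
}

# enumerate all permutations of 1..n (n <= 10 guard lives in callers)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}
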