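#' Median split of trial ratings
#'
#' Trials rated above the median go to \code{"high"}, below to
#' \code{"low"}. Ties at the median are distributed in trial order,
#' each tied trial joining the currently smaller group (the first tie
#' joins \code{"low"} when the groups are equal), so the final
#' imbalance is at most one trial. The split depends only on rating
#' ranks, hence is invariant under strictly monotone transforms.
#'
#' @param ratings numeric ratings, at least 4, non-constant.
#' @return factor with levels \code{c("low", "high")}, one per trial.
#' @export
median_split <- function(ratings) {
  if (length(ratings) < 4) stopf("need at least 4 trials")
  if (anyNA(ratings)) stopf("ratings contain NA")
  if (stats::sd(ratings) == 0) stopf("constant ratings cannot be median split")
  med <- stats::median(ratings)
  grp <- ifelse(ratings > med, "high", ifelse(ratings < med, "low", NA))
  for (i in which(is.na(grp))) {
    n_hi <- sum(grp == "high", na.rm = TRUE)
    n_lo <- sum(grp == "low", na.rm = TRUE)
    grp[i] <- if (n_hi < n_lo) "high" else "low"
  }
  factor(grp, levels = c("low", "high"))
}

#' Assemble a group HER set from per-subject condition averages
#'
#' @param high,low subjects x time matrices of condition-average HER
#'   traces on a common time axis.
#' @param time_ms epoch time axis in ms.
#' @param scale rating-scale label.
#' @return object of class \code{group_herset}.
#' @export
group_herset <- function(high, low, time_ms, scale = "I") {
  if (!all(dim(high) == dim(low))) stopf("high/low trace matrices differ in shape")
  if (ncol(high) != length(time_ms)) stopf("time axis length mismatch")
  structure(list(high = high, low = low, time_ms = time_ms,
                 n_subjects = nrow(high), scale = scale),
            class = "group_herset")
}

#' @export
print.group_herset <- function(x, ...) {
  cat(sprintf("<group_herset> %d subject(s) x %d samples, scale '%s'\n",
              x$n_subjects, ncol(x$high), x$scale))
  invisible(x)
}

#' Group-level cluster-based paired t-test ("high" vs "low" HERs)
#'
#' Per-sample paired t across subjects on the high-minus-low
#' difference, clustered by temporal adjacency above the two-tailed
#' \code{cluster_alpha} threshold (df = n_subjects - 1), with a
#' permutation null built from random within-subject condition sign
#' flips (the standard paired construction; each subject's pair is
#' preserved). With \code{exact = TRUE}, all \code{2^n} sign patterns
#' are enumerated (n <= 16) and p is the exact proportion. A Bonferroni
#' factor \code{n_scales_tested} is applied to \code{p_corrected}.
#'
#' @param group a [group_herset()].
#' @param window ms pair to test (default \code{c(300, 600)}).
#' @param cluster_alpha sample-level two-tailed threshold (default 0.05).
#' @param n_perm random sign-flip permutations (default 10000).
#' @param seed RNG seed.
#' @param estimator see [cluster_permutation_correlation()].
#' @param exact enumerate all sign patterns.
#' @param n_scales_tested Bonferroni factor (default 1; use 2 when both
#'   rating scales are tested).
#' @return a \code{cluster_result}.
#' @export
group_cluster_ttest <- function(group, window = c(300, 600),
                                cluster_alpha = 0.05, n_perm = 10000,
                                seed = 1,
                                estimator = c("plus1", "proportion"),
                                exact = FALSE, n_scales_tested = 1) {
  stopifnot(inherits(group, "group_herset"))
  estimator <- match.arg(estimator)
  n <- group$n_subjects
  if (n < 5) stopf("need at least 5 subjects (have %d)", n)
  in_win <- group$time_ms >= window[1] & group$time_ms <= window[2]
  if (!any(in_win)) stopf("window outside the trace time axis")
  d <- (group$high - group$low)[, in_win, drop = FALSE]
  tw <- group$time_ms[in_win]
  thr <- stats::qt(1 - cluster_alpha / 2, df = n - 1)

  paired_t <- function(dm) {
    mu <- colMeans(dm)
    s <- apply(dm, 2, stats::sd)
    t <- mu / (s / sqrt(n))
    t[s == 0 & mu == 0] <- NA_real_
    t[s == 0 & mu != 0] <- sign(mu[s == 0 & mu != 0]) * 1e6
    t
  }
  t_obs <- paired_t(d)
  clusters <- find_clusters(t_obs, thr)

  if (exact) {
    if (n > 16) stopf("exact sign-flip enumeration limited to n <= 16")
    flips <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    flips <- t(flips)
    n_perm <- ncol(flips)
  } else {
    if (n_perm < 100) stopf("n_perm must be >= 100")
    flips <- with_seed(seed, {
      matrix(sample(c(1, -1), n * n_perm, replace = TRUE), n, n_perm)
    })
  }
  # sign flips keep per-sample sum(d^2); t recomputed from flipped means
  q <- colSums(d^2)
  mu_mat <- crossprod(d, flips) / n               # samples x n_perm
  var_mat <- (q - n * mu_mat^2) / (n - 1)
  tmat <- mu_mat / sqrt(pmax(var_mat, 0) / n)
  tmat[!is.finite(tmat)] <- 0
  ext <- cluster_extremes_mat(tmat, thr)

  if (nrow(clusters)) {
    est <- if (exact) "proportion" else estimator
    clusters$p_mc <- vapply(seq_len(nrow(clusters)), function(i) {
      mc_p(clusters$sum_t[i], clusters$sign[i], ext$max, ext$min, est)
    }, numeric(1))
    clusters$p_corrected <- pmin(1, clusters$p_mc * n_scales_tested)
    clusters$start_ms <- tw[clusters$start_idx]
    clusters$end_ms <- tw[clusters$end_idx]
  } else {
    clusters$p_mc <- numeric(0); clusters$p_corrected <- numeric(0)
    clusters$start_ms <- numeric(0); clusters$end_ms <- numeric(0)
  }
  new_cluster_result(clusters, tw, window, cluster_alpha, n_perm, seed, n,
                     ext$max, ext$min, if (exact) "exact" else estimator,
                     kind = "group paired t (sign flips)")
}
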