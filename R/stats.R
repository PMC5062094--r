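#' Per-timepoint correlation between single-trial HER amplitude and ratings
#'
#' At each epoch sample, the Pearson correlation across trials between
#' the (z-scored) HER amplitude and the (z-scored) rating, plus the
#' corresponding t statistic \code{t = r sqrt(n-2)/sqrt(1-r^2)}.
#' z-scoring does not change r and is applied for fidelity to the
#' standard formulation. Samples where the HER has zero variance yield
#' \code{NA} (propagated, never silently zero).
#'
#' @param her a [average_trial_her()] result, or a trials x time matrix
#'   (rownames = trial ids, attribute \code{time_ms} optional).
#' @param ratings numeric ratings; if named (or if \code{her} carries
#'   trial ids), aligned to trials by trial id, otherwise taken in
#'   order. Must have nonzero variance.
#' @param channel channel to analyse when \code{her} is a
#'   \code{trial_her} (default 1).
#' @return object of class \code{corr_timecourse}: \code{r}, \code{t},
#'   \code{n}, \code{time_ms}.
#' @export
correlation_timecourse <- function(her, ratings, channel = 1) {
  m <- as_her_matrix(her, channel)
  y <- align_ratings(ratings, rownames(m))
  n <- nrow(m)
  if (n < 4) stopf("need at least 4 trials (have %d)", n)
  if (stats::sd(y) == 0) stopf("ratings have zero variance")
  yz <- (y - mean(y)) / stats::sd(y)
  mu <- colMeans(m)
  sd_c <- sqrt(colSums((t(t(m) - mu))^2) / (n - 1))
  r <- as.numeric(crossprod(t(t(m) - mu) / (n - 1), yz))
  r <- r / sd_c
  r[sd_c == 0] <- NA_real_
  structure(list(r = r, t = t_from_r(r, n), n = n,
                 time_ms = attr(m, "time_ms") %||% seq_along(r)),
            class = "corr_timecourse")
}

#' @export
print.corr_timecourse <- function(x, ...) {
  cat(sprintf("<corr_timecourse> %d samples, n = %d trials, r in [%.3f, %.3f]\n",
              length(x$r), x$n, min(x$r, na.rm = TRUE), max(x$r, na.rm = TRUE)))
  invisible(x)
}

as_her_matrix <- function(her, channel = 1) {
  if (inherits(her, "trial_her")) return(her_matrix(her, channel))
  if (is.matrix(her)) return(her)
  stopf("'her' must be a trial_her object or a trials x time matrix")
}

align_ratings <- function(ratings, trial_ids) {
  if (!is.null(names(ratings)) && !is.null(trial_ids)) {
    idx <- match(trial_ids, names(ratings))
    if (anyNA(idx)) {
      stopf("ratings lack trial id(s): %s",
            paste(trial_ids[is.na(idx)], collapse = ", "))
    }
    ratings <- ratings[idx]
  } else if (length(ratings) != length(trial_ids) &&
             !is.null(trial_ids)) {
    stopf("%d ratings for %d trials and no trial ids to align by",
          length(ratings), length(trial_ids))
  }
  if (anyNA(ratings)) stopf("ratings contain NA for analyzable trials")
  as.numeric(ratings)
}

#' Cluster-based permutation test of the HER/rating correlation
#'
#' Samples of the correlation t time course inside \code{window} whose
#' two-tailed p falls below \code{cluster_alpha} are clustered by
#' temporal adjacency (same sign); each cluster is summarized by its
#' summed t. The ratings are then shuffled \code{n_perm} times with
#' respect to the HERs, and for every shuffle the maximum positive and
#' minimum negative cluster sums are recorded. An observed positive
#' cluster is referred to the maximum distribution, a negative one to
#' the minimum distribution (a per-tail test; no doubling). With
#' \code{exact = TRUE} all \code{n!} rating permutations are enumerated
#' instead (n <= 9) and p is the exact proportion, identity included.
#'
#' @param her [average_trial_her()] result or trials x time matrix.
#' @param ratings per-trial ratings (see [correlation_timecourse()]).
#' @param window ms pair to test (default \code{c(300, 600)}, the
#'   window free of cardiac-field artifact).
#' @param cluster_alpha two-tailed sample-level threshold (default 0.05).
#' @param n_perm number of random permutations (default 10000).
#' @param seed RNG seed (default 1).
#' @param channel channel to analyse (default 1).
#' @param estimator Monte Carlo p estimator: \code{"plus1"} (default,
#'   \code{(hits + 1)/(n_perm + 1)}, never zero) or
#'   \code{"proportion"} (\code{hits/n_perm}, the literal proportion).
#' @param exact enumerate all permutations instead of sampling.
#' @param tail_correction \code{"none"} (default): each cluster is
#'   tested against its own-sign extreme distribution at the full
#'   alpha, the literal reading of the standard two-tailed cluster
#'   procedure; note that deciding significance at \code{p_mc < alpha}
#'   then carries a familywise null rate of about \code{2 * alpha *
#'   (1 - alpha/2)} because both tails are tested. \code{"double"}:
#'   p-values are doubled (capped at 1), restoring a nominal
#'   two-tailed familywise alpha.
#' @return a \code{cluster_result}; its \code{clusters} data.frame has
#'   \code{start_ms}, \code{end_ms}, \code{sum_t}, \code{sign},
#'   \code{p_mc}, \code{p_corrected} (equal to \code{p_mc} until
#'   [bonferroni()] is applied). Status is
#'   \code{"no candidate clusters"} when no sample crosses the
#'   threshold.
#' @export
cluster_permutation_correlation <- function(her, ratings,
                                            window = c(300, 600),
                                            cluster_alpha = 0.05,
                                            n_perm = 10000, seed = 1,
                                            channel = 1,
                                            estimator = c("plus1", "proportion"),
                                            exact = FALSE,
                                            tail_correction = c("none", "double")) {
  estimator <- match.arg(estimator)
  tail_correction <- match.arg(tail_correction)
  m <- as_her_matrix(her, channel)
  y <- align_ratings(ratings, rownames(m))
  n <- nrow(m)
  if (n < 4) stopf("need at least 4 trials (have %d)", n)
  if (!exact && n_perm < 100) stopf("n_perm must be >= 100")
  time_ms <- attr(m, "time_ms") %||% seq_len(ncol(m))
  in_win <- time_ms >= window[1] & time_ms <= window[2]
  if (!any(in_win)) stopf("window [%g, %g] ms is outside the epoch time axis",
                          window[1], window[2])
  mw <- m[, in_win, drop = FALSE]
  tw <- time_ms[in_win]
  thr <- stats::qt(1 - cluster_alpha / 2, df = n - 2)

  # observed
  obs <- correlation_timecourse(mw, stats::setNames(y, rownames(mw)))
  clusters <- find_clusters(obs$t, thr)

  # permutation null: z-score once, correlation as a cross product
  keep_sd <- apply(mw, 2, stats::sd)
  xz <- scale(mw)                      # columns with sd 0 become NaN
  yz <- (y - mean(y)) / stats::sd(y)
  if (exact) {
    if (n > 9) stopf("exact enumeration limited to n <= 9 trials")
    perms <- t(all_permutations(n))
    n_perm <- ncol(perms)
  } else {
    perms <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
    })
  }
  ym <- matrix(yz[perms], n, n_perm)
  rmat <- crossprod(xz, ym) / (n - 1)
  rmat[keep_sd == 0, ] <- NA_real_
  tmat <- matrix(t_from_r(as.numeric(rmat), n), nrow(rmat), ncol(rmat))
  ext <- cluster_extremes_mat(tmat, thr)

  if (nrow(clusters)) {
    est <- if (exact) "proportion" else estimator
    clusters$p_mc <- vapply(seq_len(nrow(clusters)), function(i) {
      mc_p(clusters$sum_t[i], clusters$sign[i], ext$max, ext$min, est)
    }, numeric(1))
    if (tail_correction == "double") {
      clusters$p_mc <- pmin(1, 2 * clusters$p_mc)
    }
    clusters$p_corrected <- clusters$p_mc
    clusters$start_ms <- tw[clusters$start_idx]
    clusters$end_ms <- tw[clusters$end_idx]
  } else {
    clusters$p_mc <- numeric(0); clusters$p_corrected <- numeric(0)
    clusters$start_ms <- numeric(0); clusters$end_ms <- numeric(0)
  }
  new_cluster_result(clusters, tw, window, cluster_alpha, n_perm, seed, n,
                     ext$max, ext$min, if (exact) "exact" else estimator,
                     kind = "single-trial correlation")
}

#' Bonferroni correction
#'
#' \code{min(1, p * n_tests)}, used to correct Monte Carlo cluster
#' p-values for the number of recording sites (or rating scales)
#' tested.
#'
#' @param p Monte Carlo p-value(s), or a \code{cluster_result}.
#' @param n_tests number of tests (>= 1).
#' @return corrected p-value(s), or the \code{cluster_result} with
#'   \code{p_corrected} updated.
#' @export
bonferroni <- function(p, n_tests) {
  if (n_tests < 1) stopf("n_tests must be >= 1")
  if (inherits(p, "cluster_result")) {
    p$clusters$p_corrected <- pmin(1, p$clusters$p_mc * n_tests)
    return(p)
  }
  pmin(1, p * n_tests)
}

#' Heart-rate confound check
#'
#' Pearson correlation between the per-trial pre-stimulus interbeat
#' interval (between the two selected R-peaks) and the ratings, with
#' \code{t = r sqrt(df)/sqrt(1 - r^2)}, \code{df = n - 2} and a
#' two-sided p. A null result supports a neural rather than
#' cardiac-rhythm interpretation of HER/rating coupling.
#'
#' @param rr per-trial RR interval in seconds (see [prestim_rr()]).
#' @param ratings per-trial ratings aligned with \code{rr} (by name if
#'   both are named).
#' @return list with \code{r}, \code{t}, \code{df}, \code{p}.
#' @export
heart_rate_control <- function(rr, ratings) {
  if (!is.null(names(rr)) && !is.null(names(ratings))) {
    ratings <- align_ratings(ratings, names(rr))
  }
  n <- length(rr)
  if (n < 4) stopf("need at least 4 trials (have %d)", n)
  if (length(ratings) != n) stopf("rr and ratings lengths differ")
  r <- stats::cor(rr, ratings)
  df <- n - 2
  t <- r * sqrt(df) / sqrt(max(1 - r^2, .Machine$double.eps))
  list(r = r, t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pre-stimulus RR interval per trial
#'
#' The interval between the two R-peaks selected for HER computation
#' (the last two preceding the stimulus by at least \code{min_lead} ms).
#'
#' @param peaks an [rpeak_series()].
#' @param trials trial table.
#' @param min_lead ms, default 700.
#' @return named numeric vector (names = trial ids); trials without two
#'   qualifying peaks are omitted.
#' @export
prestim_rr <- function(peaks, trials, min_lead = 700) {
  check_trial_table(trials)
  out <- numeric(0)
  for (i in seq_len(nrow(trials))) {
    if (trials$skipped[i] == 1) next
    ok <- peaks$times[peaks$times <= trials$stim_onset_s[i] - min_lead / 1000]
    if (length(ok) < 2) next
    pk <- utils::tail(ok, 2)
    out[as.character(trials$trial_id[i])] <- pk[2] - pk[1]
  }
  out
}
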