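# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: plain loops and stats:: primitives only.

# per-sample Pearson correlation, naive loop
oracle_corr_timecourse <- function(m, y) {
  vapply(seq_len(ncol(m)), function(j) stats::cor(m[, j], y), numeric(1))
}

# elementwise scan for maximal same-sign supra-threshold runs
oracle_find_clusters <- function(tv, thr) {
  out <- data.frame(start = integer(0), end = integer(0), sum_t = numeric(0),
                    sign = numeric(0))
  cur_sign <- 0; cur_start <- NA
  flush <- function(i) {
    if (cur_sign != 0) {
      idx <- cur_start:(i - 1)
      out[nrow(out) + 1, ] <<- list(cur_start, i - 1L, sum(tv[idx]), cur_sign)
    }
  }
  for (i in seq_along(tv)) {
    s <- if (is.na(tv[i]) || abs(tv[i]) <= thr) 0 else sign(tv[i])
    if (s != cur_sign) { flush(i); cur_sign <- s; cur_start <- i }
  }
  flush(length(tv) + 1L)
  out[order(out$start), , drop = FALSE]
}

oracle_cluster_extremes <- function(tv, thr) {
  cl <- oracle_find_clusters(tv, thr)
  list(max = if (any(cl$sign > 0)) max(cl$sum_t[cl$sign > 0]) else 0,
       min = if (any(cl$sign < 0)) min(cl$sum_t[cl$sign < 0]) else 0)
}

# sliding-window dynamic range, looped at every start position
oracle_sliding_range <- function(x, width) {
  n <- length(x)
  if (width >= n) return(max(x) - min(x))
  mx <- -Inf
  for (i in seq_len(n - width + 1)) {
    w <- x[i:(i + width - 1)]
    mx <- max(mx, max(w) - min(w))
  }
  mx
}

# exact rating-permutation p-values by full enumeration (naive path)
oracle_exact_perm <- function(m, y, alpha = 0.05) {
  n <- nrow(m)
  thr <- stats::qt(1 - alpha / 2, n - 2)
  t_of <- function(yy) {
    r <- oracle_corr_timecourse(m, yy)
    r * sqrt(n - 2) / sqrt(1 - r^2)
  }
  obs <- oracle_find_clusters(t_of(y), thr)
  perms <- oracle_all_perms(n)
  mx <- numeric(nrow(perms)); mn <- numeric(nrow(perms))
  for (i in seq_len(nrow(perms))) {
    e <- oracle_cluster_extremes(t_of(y[perms[i, ]]), thr)
    mx[i] <- e$max; mn[i] <- e$min
  }
  obs$p <- vapply(seq_len(nrow(obs)), function(k) {
    if (obs$sign[k] > 0) mean(mx >= obs$sum_t[k]) else mean(mn <= obs$sum_t[k])
  }, numeric(1))
  obs
}

oracle_all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# exact sign-flip p-values for the paired group test
oracle_exact_signflip <- function(d, alpha = 0.05) {
  n <- nrow(d)
  thr <- stats::qt(1 - alpha / 2, n - 1)
  t_of <- function(dd) {
    vapply(seq_len(ncol(dd)), function(j) {
      v <- dd[, j]
      mean(v) / (stats::sd(v) / sqrt(n))
    }, numeric(1))
  }
  obs <- oracle_find_clusters(t_of(d), thr)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  mx <- numeric(nrow(signs)); mn <- numeric(nrow(signs))
  for (i in seq_len(nrow(signs))) {
    e <- oracle_cluster_extremes(t_of(d * signs[i, ]), thr)
    mx[i] <- e$max; mn[i] <- e$min
  }
  obs$p <- vapply(seq_len(nrow(obs)), function(k) {
    if (obs$sign[k] > 0) mean(mx >= obs$sum_t[k]) else mean(mn <= obs$sum_t[k])
  }, numeric(1))
  obs
}

# brute-force pre-stimulus peak-pair selection
oracle_select_peaks <- function(peak_times, stim, min_lead_s = 0.7, k = 2) {
  ok <- sort(peak_times[peak_times <= stim - min_lead_s])
  if (length(ok) < k) return(numeric(0))
  ok[(length(ok) - k + 1):length(ok)]
}

# small fast session configuration for unit tests (short fixations,
# reduced sample rate; the stated-world defaults are exercised in
# test-acceptance.R)
quick_cfg <- function(...) {
  args <- list(n_trials = 12, fixation_range = c(4, 6), sample_rate = 250,
               seed = 42)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

her_pipeline_from_truth <- function(ses, filter = TRUE, channel = 1) {
  rec <- ses$recording
  if (filter) rec <- bandpass(rec)
  pk <- rpeak_series(ses$truth$true_r_times)
  ep <- reject_artifacts(extract_her_epochs(rec, pk, ses$trials))
  average_trial_her(ep)
}

session_ratings <- function(ses, scale = "I") {
  stats::setNames(ses$trials[[paste0(scale, "_rating")]], ses$trials$trial_id)
}
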