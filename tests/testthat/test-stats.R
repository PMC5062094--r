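random_her <- function(n = 30, s = 40, seed = 1, time0 = 300) {
  set.seed(seed)
  m <- matrix(rnorm(n * s), n, s)
  rownames(m) <- seq_len(n)
  attr(m, "time_ms") <- seq(time0, by = 1, length.out = s)
  m
}

test_that("correlation time course matches the per-sample oracle to 1e-10", {
  m <- random_her(30, 60, seed = 2)
  y <- runif(30)
  ct <- correlation_timecourse(m, y)
  expect_lt(max(abs(ct$r - oracle_corr_timecourse(m, y))), 1e-10)
  # t from r closed form, e.g. r = 0.5, n = 30 -> t ~ 3.055
  expect_equal(ct$t, ct$r * sqrt(28) / sqrt(1 - ct$r^2), tolerance = 1e-12)
  expect_equal(0.5 * sqrt(28) / sqrt(0.75), 3.055, tolerance = 1e-3)
})

test_that("perfect correlation is capped, zero-variance samples propagate as NA", {
  m <- random_her(20, 5, seed = 3)
  y <- runif(20)
  m[, 3] <- y               # copied ratings: r = 1 exactly
  m[, 5] <- 7               # constant: r undefined
  ct <- correlation_timecourse(m, y)
  expect_equal(ct$r[3], 1)
  expect_gte(ct$t[3], 1e6)
  expect_true(is.na(ct$r[5]) && is.na(ct$t[5]))
  expect_error(correlation_timecourse(m, rep(0.4, 20)), "zero variance")
})

test_that("r is invariant to positive affine rescaling; negation flips signs", {
  m <- random_her(25, 30, seed = 4)
  y <- runif(25)
  a <- correlation_timecourse(m, y)
  b <- correlation_timecourse(m * 37 + 5, 0.2 * y + 3)
  expect_equal(a$r, b$r, tolerance = 1e-12)
  neg <- correlation_timecourse(m, -y)
  expect_equal(neg$r, -a$r, tolerance = 1e-12)
})

test_that("ratings align to trials by trial id and mismatches error", {
  m <- random_her(10, 4, seed = 5)
  y <- setNames(runif(10), rownames(m))
  shuffled <- y[sample(names(y))]
  expect_equal(correlation_timecourse(m, shuffled)$r,
               correlation_timecourse(m, y)$r)
  expect_error(correlation_timecourse(m, shuffled[-1]), "lack trial id")
})

test_that("cluster formation matches the brute-force oracle on random traces", {
  set.seed(6)
  for (k in 1:100) {
    tv <- rnorm(50, sd = 2)
    if (k %% 3 == 0) tv[sample(50, 5)] <- NA
    thr <- runif(1, 0.5, 2.5)
    got <- hertools:::find_clusters(tv, thr)
    want <- oracle_find_clusters(tv, thr)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start_idx, want$start)
    expect_equal(got$end_idx, want$end)
    expect_equal(got$sum_t, want$sum_t, tolerance = 1e-12)
    ext <- hertools:::cluster_extremes_mat(matrix(tv), thr)
    o <- oracle_cluster_extremes(tv, thr)
    expect_equal(c(ext$max, ext$min), c(o$max, o$min), tolerance = 1e-12)
  }
})

test_that("Monte Carlo p converges to the exact enumeration on small n", {
  m <- random_her(6, 25, seed = 7)
  y <- runif(6)
  res_exact <- cluster_permutation_correlation(m, y, window = c(300, 324),
                                               exact = TRUE)
  want <- oracle_exact_perm(m, y)
  expect_equal(nrow(res_exact$clusters), nrow(want))
  expect_equal(res_exact$clusters$p_mc, want$p, tolerance = 1e-12)
  expect_equal(res_exact$n_perm, factorial(6))
})

test_that("permutation p is deterministic given a seed and stable within MC error", {
  m <- random_her(20, 30, seed = 8)
  y <- 0.6 * m[, 12] + 0.4 * runif(20)   # moderate true coupling
  a <- cluster_permutation_correlation(m, y, window = c(300, 329),
                                       n_perm = 500, seed = 42)
  b <- cluster_permutation_correlation(m, y, window = c(300, 329),
                                       n_perm = 500, seed = 42)
  expect_identical(a$clusters, b$clusters)
  c2 <- cluster_permutation_correlation(m, y, window = c(300, 329),
                                        n_perm = 4000, seed = 43)
  i <- which.max(abs(a$clusters$sum_t)); j <- which.max(abs(c2$clusters$sum_t))
  p1 <- a$clusters$p_mc[i]; p2 <- c2$clusters$p_mc[j]
  se <- sqrt(p1 * (1 - p1) / 500) + sqrt(p2 * (1 - p2) / 4000)
  expect_lt(abs(p1 - p2), 4 * se + 1e-6)
})

test_that("sign coherence: negating ratings mirrors clusters and preserves p", {
  m <- random_her(24, 30, seed = 9)
  y <- 0.5 * m[, 10] + 0.5 * runif(24)
  a <- cluster_permutation_correlation(m, y, window = c(300, 329),
                                       n_perm = 300, seed = 7)
  b <- cluster_permutation_correlation(m, -y, window = c(300, 329),
                                       n_perm = 300, seed = 7)
  expect_equal(b$clusters$sum_t, -a$clusters$sum_t, tolerance = 1e-9)
  expect_equal(b$clusters$sign, -a$clusters$sign)
  # same permutation draws map through negation: max/min distributions swap
  expect_equal(sort(b$null_max), sort(-a$null_min), tolerance = 1e-9)
  expect_equal(b$clusters$p_mc, a$clusters$p_mc, tolerance = 1e-12)
})

test_that("no supra-threshold sample yields the no-candidate status", {
  m <- random_her(15, 10, seed = 10)
  m[] <- rep(rnorm(15), 10)          # identical columns
  y <- runif(15)
  m_flat <- random_her(15, 10, seed = 11) * 0.0001
  m_flat[, 1] <- seq_len(15) * 1e-8  # tiny but nonzero variance, near-zero r
  res <- cluster_permutation_correlation(m_flat, y, window = c(300, 309),
                                         n_perm = 100, cluster_alpha = 1e-12)
  expect_equal(res$status, "no candidate clusters")
  expect_equal(nrow(res$clusters), 0)
})

test_that("bonferroni correction: worked examples and cluster_result method", {
  expect_equal(bonferroni(0.023, 2), 0.046)
  expect_equal(bonferroni(0.8, 2), 1)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_error(bonferroni(0.05, 0), "n_tests")
  m <- random_her(20, 30, seed = 12)
  y <- 0.8 * m[, 15] + 0.2 * runif(20)
  res <- cluster_permutation_correlation(m, y, window = c(300, 329),
                                         n_perm = 200, seed = 1)
  res2 <- bonferroni(res, 2)
  expect_equal(res2$clusters$p_corrected,
               pmin(1, res$clusters$p_mc * 2))
})

test_that("heart-rate control reproduces the closed form", {
  expect_equal(heart_rate_control(1:10 * 0.1, 1:10 * 0.3 + 2)$r, 1)

  # r = 0.12 at df = 25: t ~ 0.604, p ~ 0.55 two-sided
  r <- 0.12; df <- 25
  t_cf <- r * sqrt(df) / sqrt(1 - r^2)
  expect_equal(t_cf, 0.604, tolerance = 1e-3)
  expect_equal(2 * pt(-abs(t_cf), df), 0.55, tolerance = 0.01)
  # package path on data constructed to have that exact r
  set.seed(13)
  x <- rnorm(27); y <- rnorm(27)
  y <- residuals(lm(y ~ x)); y <- y / sd(y)
  x <- (x - mean(x)) / sd(x)
  z <- r * x + sqrt(1 - r^2) * y      # cor(z, x) == r exactly
  out <- heart_rate_control(x, z)
  expect_equal(out$r, r, tolerance = 1e-10)
  expect_equal(out$t, t_cf, tolerance = 1e-6)
  expect_equal(out$df, 25)

  expect_error(heart_rate_control(1:3, 1:3), "at least 4")
})

test_that("no RR/rating coupling in the generator: null heart-rate control", {
  ses <- simulate_session(quick_cfg(n_trials = 400, fixation_range = c(3, 4),
                                    coupling_beta = 1, seed = 15))
  pk <- rpeak_series(ses$truth$true_r_times)
  rr <- prestim_rr(pk, ses$trials)
  out <- heart_rate_control(rr, session_ratings(ses)[names(rr)])
  expect_lt(abs(out$r), 0.1)
  expect_gt(out$p, 0.05)
})

test_that("prestim_rr selects the same pair as the epoch extractor", {
  ses <- simulate_session(quick_cfg(seed = 16))
  pk <- rpeak_series(ses$truth$true_r_times)
  rr <- prestim_rr(pk, ses$trials)
  for (i in seq_len(nrow(ses$trials))) {
    sel <- oracle_select_peaks(pk$times, ses$trials$stim_onset_s[i])
    expect_equal(unname(rr[as.character(ses$trials$trial_id[i])]),
                 diff(sel))
  }
})
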